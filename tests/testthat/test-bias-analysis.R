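fake_deg <- function(genes, sig) {
  tibble::tibble(gene_id = genes,
                 fold_change = ifelse(sig, 10, 1.1),
                 q_value = ifelse(sig, 1e-6, 0.8),
                 is_deg = sig)
}

test_that("classify_trio matches the truth-table oracle on all combinations", {
  positions <- c(below = 0.5, inside = 5, above = 40)  # parents at 2 and 10
  combos <- expand.grid(sig1 = c(TRUE, FALSE), sig2 = c(TRUE, FALSE),
                        pos = names(positions), stringsAsFactors = FALSE)
  genes <- sprintf("g%02d", seq_len(nrow(combos)))
  expr <- cbind(P1 = rep(2, nrow(combos)), P2 = rep(10, nrow(combos)),
                F1 = positions[combos$pos])
  rownames(expr) <- genes
  deg1 <- fake_deg(genes, combos$sig1)
  deg2 <- fake_deg(genes, combos$sig2)
  got <- classify_trio(deg1, deg2, expr)
  expected <- vapply(seq_len(nrow(combos)), function(i) {
    oracle_trio_category(combos$sig1[i], combos$sig2[i],
                         combos$sig1[i], combos$sig2[i],
                         if (combos$pos[i] == "inside") "inside" else "outside")
  }, character(1))
  expect_equal(got$category[match(genes, got$gene_id)], expected)
  # partition: every tested gene gets exactly one category
  expect_equal(nrow(got), length(genes))
  expect_true(all(got$category %in% c("equal_P1", "equal_P2", "over_parents",
                                      "between_parents", "non_deg")))
})

test_that("boundary-equal F1 values fall between parents, not over", {
  genes <- c("edge_lo", "edge_hi")
  expr <- cbind(P1 = c(2, 2), P2 = c(10, 10), F1 = c(2, 10))
  rownames(expr) <- genes
  got <- classify_trio(fake_deg(genes, TRUE), fake_deg(genes, TRUE), expr)
  expect_true(all(got$category == "between_parents"))
})

test_that("published pathway rows classify and orient as expected", {
  expr <- table2_expression(as_matrix = TRUE)
  # OsGA20ox2 in GL x TQ: parents 12.92 / 3.15, F1 9.36 -> inside the range
  tri <- expr[, c("GL", "TQ", "GLxTQ")]
  colnames(tri) <- c("P1", "P2", "F1")
  got <- classify_trio(fake_deg(rownames(tri), TRUE),
                       fake_deg(rownames(tri), TRUE), tri)
  expect_equal(got$category[got$gene_id == "OsGA20ox2"], "between_parents")
  # OsPRR1: F1 122.26 closer to TQ (92.53) than GL (35.49)
  expect_equal(closer_parent(35.49, 92.53, 122.26), "P2")
  expect_equal(got$closer_parent[got$gene_id == "OsPRR1"], "P2")
})

test_that("closer_parent handles ties, zeros and undefined input", {
  expect_equal(closer_parent(5, 9, 5), "P1")
  expect_equal(closer_parent(4, 4, 7), "tie")
  expect_equal(closer_parent(0, 0, 0), "undefined")
  # geometric tie: F1 at the log-midpoint of the parents
  expect_equal(closer_parent(2, 8, 4), "tie")
  # a zero parent gets the epsilon replacement, keeping ratios finite
  expect_equal(closer_parent(0, 100, 90), "P2")
  expect_error(closer_parent(-1, 1, 1), "non-negative")
})

test_that("count_higher_in_all reproduces the pathway direction count", {
  expr <- table2_expression(as_matrix = TRUE)
  ga <- names(attr(expr, "pathway"))[attr(expr, "pathway") == "GA"]
  n <- count_higher_in_all(expr, ga,
                           c("TQ", "93-11", "GLxTQ", "GLx93-11"), "GL")
  expect_equal(as.integer(n), 3L)
  expect_setequal(attr(n, "genes"), c("OsCPS1", "OsKAO", "OsGA2ox6"))
  # no strict exceedance of self
  expect_equal(as.integer(count_higher_in_all(expr, ga, c("TQ", "GL"), "GL")),
               0L)
  # all-zero rows are never counted
  zero <- matrix(0, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "r")))
  expect_equal(as.integer(count_higher_in_all(zero, c("a", "b"),
                                              c("s1", "s2"), "r")), 0L)
  expect_error(count_higher_in_all(expr, character(0), "TQ", "GL"), "empty")
  expect_error(count_higher_in_all(expr, ga, "nope", "GL"), "unknown sample")
})

test_that("similarity and bias summary arithmetic", {
  genes <- sprintf("g%02d", 1:10)
  deg <- fake_deg(genes, c(rep(TRUE, 3), rep(FALSE, 7)))
  sim <- similarity_to_parent(deg, genes)
  expect_equal(sim$fraction, 0.7)
  expect_equal(sim$n_expressed, 10)
  expect_error(similarity_to_parent(deg, character(0)), "empty")
  # no DEGs at all: similarity 1 to both parents
  expect_equal(similarity_to_parent(fake_deg(genes, FALSE), genes)$fraction, 1)

  cls <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:12),
    category = c(rep("equal_P1", 6), rep("equal_P2", 2), "over_parents",
                 "between_parents", "non_deg", "non_deg")
  )
  bs <- bias_summary(cls, n_expressed = 20)
  expect_equal(bs$frac_equal_parent, 0.8)
  expect_equal(bs$frac_equal_bias_P1, 0.75)
  expect_equal(bs$frac_equal_bias_P2, 0.25)
  expect_equal(bs$frac_over, 0.1)
  expect_equal(bs$frac_between, 0.1)
  expect_equal(bs$frac_deg, 0.5)
  expect_equal(bs$frac_equal_bias_P1 + bs$frac_equal_bias_P2, 1)

  # non_deg-only input: frac_deg 0, category fractions undefined
  only_null <- tibble::tibble(gene_id = genes, category = "non_deg")
  bs0 <- bias_summary(only_null)
  expect_equal(bs0$frac_deg, 0)
  expect_true(is.na(bs0$frac_equal_parent))
  expect_true(is.na(bs0$frac_equal_bias_P1))
})

test_that("category counts partition the DEG trio genes on simulated data", {
  sim <- simulate_trio_counts(n_genes = 400, seed = 9)
  expr <- rpkm_matrix(sim$counts, sim$lib_sizes, sim$models)
  deg1 <- call_degs(sim$counts, sim$lib_sizes, "F1", "P1")
  deg2 <- call_degs(sim$counts, sim$lib_sizes, "F1", "P2")
  cls <- classify_trio(deg1, deg2, expr)
  n_deg_union <- length(union(deg1$gene_id[deg1$is_deg],
                              deg2$gene_id[deg2$is_deg]))
  tab <- table(cls$category)
  expect_equal(sum(tab[setdiff(names(tab), "non_deg")]), n_deg_union)
  expect_equal(nrow(cls), length(union(deg1$gene_id, deg2$gene_id)))
})

test_that("clustering topology follows the correlation structure", {
  # duplicate samples merge first at height 0
  set.seed(5)
  base <- matrix(2^rnorm(200, 3, 1), 100, 2)
  expr <- cbind(A = base[, 1], B = base[, 1], C = base[, 2])
  rownames(expr) <- sprintf("g%03d", 1:100)
  hc <- cluster_samples(expr)
  first_pair <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first_pair, c("A", "B"))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)

  # ((A,B),C) when d(A,B) << d(A,C) = d(B,C)
  set.seed(6)
  sig <- rnorm(200)
  m <- cbind(A = sig + rnorm(200, 0, 0.1), B = sig + rnorm(200, 0, 0.1),
             C = rnorm(200))
  m <- 2^m; rownames(m) <- sprintf("g%03d", 1:200)
  hc2 <- cluster_samples(m)
  expect_equal(sort(hc2$labels[-hc2$merge[1, ]]), c("A", "B"))

  const <- cbind(A = rep(1, 5), B = 1:5)
  rownames(const) <- letters[1:5]
  expect_error(cluster_samples(const), "zero-variance sample.*A")
  expect_error(cluster_samples(m[, 1, drop = FALSE]), "2 samples")

  # newick serialisation round-trips through ape
  nwk <- as_newick(hc2)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
})
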