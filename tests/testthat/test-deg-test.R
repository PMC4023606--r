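# Independent oracle: the Audic-Claverie conditional law of y given x is
# negative binomial with size x + 1 and success probability N1/(N1+N2).
nb_prob <- function(x, y, n1, n2) dnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
nb_two_sided <- function(x, y, n1, n2) {
  lower <- pnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
  upper <- 1 - pnbinom(y - 1, size = x + 1, prob = n1 / (n1 + n2))
  min(1, 2 * min(lower, upper))
}

test_that("ac_probability matches closed-form anchors and the NB oracle", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5, tolerance = 1e-12)
  # distribution over y sums to 1 (truncated tail below 1e-10)
  expect_equal(sum(ac_probability(5, 0:500, 1e6, 1e6)), 1, tolerance = 1e-10)
  set.seed(1)
  for (i in 1:25) {
    x <- rpois(1, 40); y <- rpois(1, 40)
    n1 <- runif(1, 1e5, 1e8); n2 <- runif(1, 1e5, 1e8)
    # count-swap symmetry is exact for equal library sizes ...
    expect_equal(ac_probability(x, y, n1, n1), ac_probability(y, x, n1, n1),
                 tolerance = 1e-12)
    # ... and picks up the library ratio otherwise
    expect_equal(ac_probability(x, y, n1, n2),
                 (n1 / n2) * ac_probability(y, x, n2, n1),
                 tolerance = 1e-9)
    expect_equal(ac_probability(x, y, n1, n2), nb_prob(x, y, n1, n2),
                 tolerance = 1e-12)
  }
  expect_error(ac_probability(-1, 0, 1, 1), "counts")
  expect_error(ac_probability(1, 1, 0, 1), "positive")
})

test_that("two-sided p-value has correct tails and symmetry", {
  expect_equal(ac_two_sided_p(5, 5, 1e6, 1e6), 1)
  expect_equal(ac_two_sided_p(120, 120, 3e6, 3e6), 1)
  expect_lt(ac_two_sided_p(50, 0, 1e6, 1e6), 1e-10)
  set.seed(2)
  for (i in 1:25) {
    x <- rpois(1, 60); y <- rpois(1, 90)
    n1 <- runif(1, 1e6, 5e7); n2 <- runif(1, 1e6, 5e7)
    expect_equal(ac_two_sided_p(x, y, n1, n2), nb_two_sided(x, y, n1, n2),
                 tolerance = 1e-9)
    # p is non-increasing as y departs upward from its conditional
    # expectation (x + 1) * n2 / n1
    y0 <- ceiling((x + 1) * n2 / n1) + 2
    ps <- ac_two_sided_p(x, y0 + c(0, 5, 20, 80), n1, n2)
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("BH adjustment matches a from-scratch step-up computation", {
  expect_equal(bh_fdr(rep(0.03, 6)), rep(0.03, 6))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # independent step-up oracle
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(1, q_sorted)[order(o)]
  }
  set.seed(3)
  for (i in 1:10) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p), step_up(p), tolerance = 1e-12)
    perm <- sample(50)
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("call_degs applies the strict fold rule and zero-handling", {
  counts <- make_counts(c(100, 0, 50, 0, 400,
                          200, 0, 50, 30, 100), samples = c("A", "B"))
  libs <- c(A = 1e6, B = 1e6)
  deg <- call_degs(counts, libs, "A", "B")
  # both-zero gene excluded from testing
  expect_equal(nrow(deg), 4)
  expect_false("g002" %in% deg$gene_id)
  # ratio exactly 2.0 is NOT "more than 2-fold", whatever its q
  g1 <- deg[deg$gene_id == "g001", ]
  expect_equal(g1$fold_change, 2)
  expect_lt(g1$q_value, 0.05)
  expect_false(g1$is_deg)
  # one zero, one positive: infinite fold change passes the FC criterion
  g4 <- deg[deg$gene_id == "g004", ]
  expect_true(is.infinite(g4$fold_change))
  expect_true(g4$is_deg)
  expect_equal(g4$direction, "b_higher")
  # equal normalized counts: no direction, not a DEG
  g3 <- deg[deg$gene_id == "g003", ]
  expect_equal(g3$direction, "none")
  expect_false(g3$is_deg)

  # identical columns yield zero DEGs
  same <- make_counts(c(10, 25, 3, 10, 25, 3), samples = c("A", "B"))
  expect_equal(sum(call_degs(same, libs, "A", "B")$is_deg), 0)

  expect_error(call_degs(counts, libs, "A", "A"), "differ")
  expect_error(call_degs(counts, libs, "A", "C"), "unknown sample")
  expect_error(call_degs(counts, c(A = 1e6), "A", "B"), "library size")
})

test_that("raw-p mode flags at least as many genes as FDR mode", {
  set.seed(4)
  mu <- exp(rnorm(300, log(40), 1))
  counts <- make_counts(c(rpois(300, mu), rpois(300, mu * 2)),
                        samples = c("A", "B"))
  libs <- c(A = 1e7, B = 1e7)
  d_q <- call_degs(counts, libs, "A", "B", use_q = TRUE)
  d_p <- call_degs(counts, libs, "A", "B", use_q = FALSE)
  expect_gte(sum(d_p$is_deg), sum(d_q$is_deg))
})
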