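test_that("cross_means aggregates two-stage and pools reciprocals", {
  ph <- tibble::tibble(
    parent_a = c("A", "A", "A", "B", "C", "A", "B", "A"),
    parent_b = c("B", "B", "B", "C", "B", "C", "A", "A"),
    env = c("E1", "E1", "E2", "E1", "E1", "E1", "E1", "E1"),
    rep = c(1, 2, 1, 1, 1, 1, 3, 1),
    trait = "t",
    value = c(10, 20, 30, 5, 6, 7, 40, 3)
  )
  m <- cross_means(ph, "t")
  # A-B: env E1 mean of (10, 20, 40) = 70/3 (reciprocal B-A pooled),
  # env E2 mean 30; two-stage mean = (70/3 + 30) / 2
  expect_equal(m$cells["A", "B"], (70 / 3 + 30) / 2)
  expect_equal(m$cells["B", "C"], 5.5)  # (5 + 6) / 2 within one env
  expect_equal(m$cells["A", "C"], 7)
  expect_equal(m$cells["A", "A"], 3)
  expect_false(m$has_diagonal)          # B-B and C-C absent
  expect_identical(m$cells, t(m$cells))

  # spec worked case: reps (10, 20) in env A, (30) in env B -> 22.5
  ph2 <- tibble::tibble(parent_a = "A", parent_b = "B",
                        env = c("envA", "envA", "envB"), rep = c(1, 2, 1),
                        trait = "t", value = c(10, 20, 30))
  ph2 <- dplyr::bind_rows(ph2, tibble::tibble(
    parent_a = c("A", "B", "C", "C"), parent_b = c("C", "C", "A", "B"),
    env = "envA", rep = 1, trait = "t", value = 1))
  expect_equal(cross_means(ph2, "t")$cells["A", "B"], 22.5)

  expect_error(cross_means(ph[ph$parent_b != "C" & ph$parent_a != "C", ], "t"),
               "at least 3")
  ph3 <- ph[!(ph$parent_a == "A" & ph$parent_b == "C"), ]
  expect_error(cross_means(ph3, "t"), "missing cross A x C")
})

test_that("Method 2 matches the hand-derived p=3 solution and symmetries", {
  x <- matrix(c(12, 11, 10, 11, 10, 9, 10, 9, 8), 3, 3, byrow = TRUE)
  fit <- gca_method2(diallel_means(x))
  expect_equal(fit$mu, 10, tolerance = 1e-12)
  expect_equal(unname(fit$g), c(1, 0, -1), tolerance = 1e-12)
  expect_true(all(abs(fit$s) < 1e-12))

  # constant table: mu = c, everything else 0
  fitc <- gca_method2(diallel_means(matrix(7, 4, 4)))
  expect_equal(fitc$mu, 7)
  expect_true(all(abs(fitc$g) < 1e-12) && all(abs(fitc$s) < 1e-12))

  # location invariance
  set.seed(1)
  dm <- random_diallel_table(5)
  f0 <- gca_method2(dm)
  fk <- gca_method2(diallel_means(dm$cells + 3.5))
  expect_equal(fk$mu, f0$mu + 3.5, tolerance = 1e-10)
  expect_equal(fk$g, f0$g, tolerance = 1e-10)
  expect_equal(fk$s, f0$s, tolerance = 1e-10)

  # missing diagonal is a method mismatch
  x_na <- dm$cells; diag(x_na) <- NA
  expect_error(gca_method2(diallel_means(x_na)), "Method 2")
})

test_that("Method 4 matches the closed formula and is label-equivariant", {
  x <- matrix(NA_real_, 3, 3)
  x[1, 2] <- x[2, 1] <- 11; x[1, 3] <- x[3, 1] <- 10; x[2, 3] <- x[3, 2] <- 9
  fit <- gca_method4(diallel_means(x))
  expect_equal(fit$mu, 10, tolerance = 1e-12)
  expect_equal(unname(fit$g), c(1, 0, -1), tolerance = 1e-12)

  fitc <- gca_method4(diallel_means({m <- matrix(4, 5, 5); diag(m) <- NA; m}))
  expect_equal(fitc$mu, 4)
  expect_true(all(abs(fitc$g) < 1e-12))

  # permuting parent labels permutes g identically
  set.seed(2)
  dm <- random_diallel_table(6, with_diagonal = FALSE)
  perm <- sample(6)
  cells_p <- dm$cells[perm, perm]
  dimnames(cells_p) <- dimnames(dm$cells)
  f1 <- gca_method4(dm)
  f2 <- gca_method4(diallel_means(cells_p))
  expect_equal(unname(f2$g), unname(f1$g[perm]), tolerance = 1e-10)
})

test_that("zero-sum invariants hold after every estimation", {
  set.seed(3)
  for (p in c(3, 5, 8)) {
    f2 <- gca_method2(random_diallel_table(p))
    expect_lt(abs(sum(f2$g)), 1e-9)
    f4 <- gca_method4(random_diallel_table(p, with_diagonal = FALSE))
    expect_lt(abs(sum(f4$g)), 1e-9)
    # Method 4 SCA row sums vanish
    expect_true(all(abs(rowSums(f4$s, na.rm = TRUE)) < 1e-9))
  }
})

test_that("closed forms agree with the constrained least-squares oracle", {
  set.seed(4)
  for (i in 1:25) {
    p <- sample(3:8, 1)
    dm <- random_diallel_table(p)
    f <- gca_method2(dm); o <- gca_least_squares(dm, 2)
    expect_lt(abs(f$mu - o$mu), 1e-8)
    expect_lt(max(abs(f$g - o$g)), 1e-8)
    expect_lt(max(abs(f$s - o$s)), 1e-8)
    dm4 <- random_diallel_table(p, with_diagonal = FALSE)
    f <- gca_method4(dm4); o <- gca_least_squares(dm4, 4)
    expect_lt(abs(f$mu - o$mu), 1e-8)
    expect_lt(max(abs(f$g - o$g)), 1e-8)
    expect_lt(max(abs(f$s - o$s), na.rm = TRUE), 1e-8)
  }
})

test_that("parent-F1 correlation matches direct formula evaluation", {
  r <- parent_f1_correlation(c(1, 2, 3), c(3, 5, 7))
  expect_equal(r$r, 1.0, tolerance = 1e-12)

  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  got <- parent_f1_correlation(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_direct * sqrt(2) / sqrt(1 - r_direct^2)
  p_direct <- 2 * stats::pt(-abs(t_stat), df = 2)
  expect_equal(got$r, r_direct, tolerance = 1e-12)
  expect_equal(got$p_value, p_direct, tolerance = 1e-12)
  expect_equal(got$n, 4L)

  expect_error(parent_f1_correlation(c(1, 2, 3), c(5, 5, 5)), "variance")
  expect_error(parent_f1_correlation(1:3, 1:4), "equal length")
})

test_that("focal-parent pairing recovers a strong built-in correlation", {
  # phenotypes dominated by additive GCA: F1(focal, j) tracks parent j
  g <- c(2, 1, 0, -1, -2)
  ph <- simulate_diallel_phenotypes(
    p = 5, mu = c(t1 = 50, t2 = 100, t3 = 20), g = cbind(g, 2 * g, 0.5 * g),
    sca_sd = 0.05, error_sd = 0.1, n_env = 3, n_rep = 3, seed = 21)
  res <- focal_parent_correlation(ph, "P1", scheme = "pooled_z")
  expect_equal(res$n, 12L)  # 4 co-parents x 3 traits
  expect_gt(res$r, 0.9)
  per <- focal_parent_correlation(ph, "P1", scheme = "per_trait")
  expect_equal(nrow(per), 3L)
  expect_true(all(per$n == 4L))
  expect_error(focal_parent_correlation(ph, "nope"), "unknown parent")
})
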