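#' Aggregate half-diallel phenotype records into cell means
#'
#' Collapses a long-format phenotype table (one record per plot) into the
#' symmetric cell-mean table a diallel analysis runs on. Aggregation is
#' two-stage and unweighted: plot records are first averaged within each
#' environment, then environment means are averaged, so environments with
#' unequal replication carry equal weight. Reciprocal records (i, j) and
#' (j, i) are pooled into one cell.
#'
#' @param phenotypes Data frame with columns `parent_a`, `parent_b`, `env`,
#'   `rep`, `trait`, `value` (as written by
#'   [simulate_diallel_phenotypes()]).
#' @param trait Which trait to aggregate.
#' @param require_diagonal Fail if any parental self cell is absent
#'   (required for Griffing Method 2).
#'
#' @return An object of class `diallel_means`: a list with `p`, `parents`,
#'   `cells` (symmetric `p x p` matrix, `NA` diagonal allowed), `trait`,
#'   and `has_diagonal`.
#' @export
cross_means <- function(phenotypes, trait = NULL, require_diagonal = FALSE) {
  stopifnot(all(c("parent_a", "parent_b", "env", "trait", "value") %in%
                  names(phenotypes)))
  if (is.null(trait)) {
    trait <- unique(phenotypes$trait)
    if (length(trait) > 1L) {
      stop("multiple traits present; supply `trait`", call. = FALSE)
    }
  }
  ph <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  if (nrow(ph) == 0L) stop(sprintf("no records for trait '%s'", trait),
                           call. = FALSE)
  # canonical cell key: unordered parent pair
  a <- pmin(ph$parent_a, ph$parent_b)
  b <- pmax(ph$parent_a, ph$parent_b)
  cell <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(a = a, b = b, env = ph$env, value = ph$value),
                    .data$a, .data$b, .data$env),
    value = mean(.data$value), .groups = "drop_last"
  )
  cell <- dplyr::summarise(cell, value = mean(.data$value), .groups = "drop")

  parents <- sort(unique(c(cell$a, cell$b)))
  p <- length(parents)
  if (p < 3) stop("a diallel needs at least 3 parents", call. = FALSE)
  cells <- matrix(NA_real_, p, p, dimnames = list(parents, parents))
  cells[cbind(match(cell$a, parents), match(cell$b, parents))] <- cell$value
  cells[lower.tri(cells)] <- t(cells)[lower.tri(cells)]

  off <- which(upper.tri(cells) & is.na(cells), arr.ind = TRUE)
  if (nrow(off) > 0L) {
    stop(sprintf("incomplete diallel: missing cross %s x %s for trait '%s'",
                 parents[off[1, 1]], parents[off[1, 2]], trait), call. = FALSE)
  }
  has_diag <- !anyNA(diag(cells))
  if (require_diagonal && !has_diag) {
    stop("parental self cells are missing but required", call. = FALSE)
  }
  structure(list(p = p, parents = parents, cells = cells, trait = trait,
                 has_diagonal = has_diag),
            class = "diallel_means")
}

#' Construct a diallel cell-mean table directly
#'
#' @param cells Symmetric numeric matrix of cell means; diagonal holds
#'   parental selfs and may be `NA` for a crosses-only (Method 4) design.
#' @param trait Optional trait label.
#' @return A `diallel_means` object; see [cross_means()].
#' @export
diallel_means <- function(cells, trait = NA_character_) {
  stopifnot(is.matrix(cells), nrow(cells) == ncol(cells))
  p <- nrow(cells)
  if (p < 3) stop("a diallel needs at least 3 parents", call. = FALSE)
  if (is.null(rownames(cells))) {
    dimnames(cells) <- list(paste0("P", 1:p), paste0("P", 1:p))
  }
  up <- cells[upper.tri(cells)]
  lo <- t(cells)[upper.tri(cells)]
  if (anyNA(up) || max(abs(up - lo)) > 1e-8) {
    stop("`cells` must be symmetric with complete off-diagonal", call. = FALSE)
  }
  structure(list(p = p, parents = rownames(cells), cells = cells,
                 trait = trait, has_diagonal = !anyNA(diag(cells))),
            class = "diallel_means")
}

new_combining_ability <- function(mu, g, s, method) {
  structure(list(mu = mu, g = g, s = s, method = method),
            class = "combining_ability")
}

#' @export
print.combining_ability <- function(x, ...) {
  cat(sprintf("Griffing Method %d combining-ability estimates\n", x$method))
  cat(sprintf("  grand mean: %.4g\n", x$mu))
  cat("  GCA effects:\n")
  print(round(x$g, 4))
  invisible(x)
}

#' Griffing Method 2 combining-ability estimates
#'
#' Fixed-effect (Model I) analysis of a half-diallel that includes the
#' parents and one set of F1 crosses. With `x..` the total over the
#' `p(p+1)/2` cells and `x_i.` the row total over all `j` (the self
#' counted once), the closed-form estimates are
#' \deqn{\hat\mu = 2 x.. / (p(p+1)),}
#' \deqn{\hat g_i = [x_{i.} + x_{ii} - 2 x.. / p] / (p+2),}
#' \deqn{\hat s_{ij} = x_{ij} - (x_{i.} + x_{ii} + x_{j.} + x_{jj})/(p+2)
#'   + 2 x.. / ((p+1)(p+2)),}
#' which solve the saturated model \eqn{x_{ij} = \mu + g_i + g_j + s_{ij}}
#' (selfs \eqn{x_{ii} = \mu + 2 g_i + s_{ii}}) under the constraints
#' \eqn{\sum_i g_i = 0} and \eqn{\sum_j s_{ij} + s_{ii} = 0} for every `i`.
#' [gca_least_squares()] provides an independent numerical check.
#'
#' @param means A `diallel_means` object with a complete diagonal.
#' @return A `combining_ability` object with elements `mu`, `g` (named,
#'   summing to zero), `s` (symmetric matrix), `method = 2`.
#' @references Griffing, B. (1956). Concept of general and specific
#'   combining ability in relation to diallel crossing systems.
#'   *Australian Journal of Biological Sciences* 9, 463-493.
#' @export
gca_method2 <- function(means) {
  stopifnot(inherits(means, "diallel_means"))
  if (!means$has_diagonal) {
    stop("Method 2 requires parental selfs on the diagonal; use gca_method4()",
         call. = FALSE)
  }
  x <- means$cells
  p <- means$p
  xdd <- sum(x[upper.tri(x, diag = TRUE)])
  xi <- rowSums(x)                       # self counted once per row
  mu <- 2 * xdd / (p * (p + 1))
  g <- (xi + diag(x) - 2 * xdd / p) / (p + 2)
  s <- x - outer(xi + diag(x), xi + diag(x), "+") / (p + 2) +
    2 * xdd / ((p + 1) * (p + 2))
  names(g) <- means$parents
  dimnames(s) <- dimnames(x)
  new_combining_ability(mu, g, s, 2L)
}

#' Griffing Method 4 combining-ability estimates
#'
#' Fixed-effect (Model I) analysis of a crosses-only half-diallel (no
#' parental selfs, no reciprocals). With `x_i. = sum_{j != i} x_ij` and
#' `x.. = sum_{i<j} x_ij`,
#' \deqn{\hat g_i = (p \, x_{i.} - 2 x..) / (p (p-2)),}
#' \deqn{\hat\mu = 2 x.. / (p (p-1)),}
#' \deqn{\hat s_{ij} = x_{ij} - \hat\mu - \hat g_i - \hat g_j,}
#' so that \eqn{\sum_i \hat g_i = 0} and every SCA row sum
#' \eqn{\sum_{j \ne i} \hat s_{ij}} vanishes.
#'
#' @inheritParams gca_method2
#' @return A `combining_ability` object with `method = 4`; `s` has an `NA`
#'   diagonal.
#' @inherit gca_method2 references
#' @export
gca_method4 <- function(means) {
  stopifnot(inherits(means, "diallel_means"))
  x <- means$cells
  p <- means$p
  if (p < 3) stop("Method 4 requires p >= 3", call. = FALSE)
  diag(x) <- 0
  xi <- rowSums(x)
  xdd <- sum(x[upper.tri(x)])
  mu <- 2 * xdd / (p * (p - 1))
  g <- (p * xi - 2 * xdd) / (p * (p - 2))
  s <- x - mu - outer(g, g, "+")
  diag(s) <- NA_real_
  names(g) <- means$parents
  dimnames(s) <- dimnames(x)
  new_combining_ability(mu, g, s, 4L)
}

#' Constrained least-squares solution of the Griffing model
#'
#' Solves the full design-matrix system for \eqn{(\mu, g, s)} under the
#' zero-sum constraints numerically, without using the closed-form
#' estimators. The saturated model plus constraints form a square linear
#' system (one equation per cell, one per constraint), solved by QR. Used
#' as an independent oracle for [gca_method2()] and [gca_method4()] in the
#' test-suite; exported so users can cross-check any table.
#'
#' Constraints: \eqn{\sum_i g_i = 0} and, per parent `i`,
#' \eqn{\sum_j s_{ij} + s_{ii} = 0} for Method 2 (the self entering twice,
#' as it does in the model expectation), or \eqn{\sum_{j \ne i} s_{ij} = 0}
#' for Method 4.
#'
#' @inheritParams gca_method2
#' @param method Griffing method, 2 (parents + crosses) or 4 (crosses only).
#' @return A `combining_ability` object.
#' @export
gca_least_squares <- function(means, method = c(2, 4)) {
  stopifnot(inherits(means, "diallel_means"))
  method <- as.integer(match.arg(as.character(method[1]), c("2", "4")))
  p <- means$p
  x <- means$cells
  diag_used <- method == 2L
  if (method == 2L && !means$has_diagonal) {
    stop("Method 2 requires parental selfs", call. = FALSE)
  }
  cells <- which(upper.tri(x, diag = diag_used), arr.ind = TRUE)
  n_cell <- nrow(cells)
  s_index <- function(i, j) match(paste(pmin(i, j), pmax(i, j)),
                                  paste(cells[, 1], cells[, 2]))
  n_par <- 1L + p + n_cell                 # mu, g_1..g_p, s per cell
  A <- matrix(0, n_cell + 1L + p, n_par)
  y <- numeric(n_cell + 1L + p)
  for (k in seq_len(n_cell)) {
    i <- cells[k, 1]; j <- cells[k, 2]
    A[k, 1L] <- 1
    A[k, 1L + i] <- A[k, 1L + i] + 1
    A[k, 1L + j] <- A[k, 1L + j] + 1
    A[k, 1L + p + k] <- 1
    y[k] <- x[i, j]
  }
  A[n_cell + 1L, 1L + seq_len(p)] <- 1     # sum g = 0
  for (i in seq_len(p)) {                  # SCA row-sum constraints
    row <- n_cell + 1L + i
    js <- setdiff(seq_len(p), i)
    for (j in js) A[row, 1L + p + s_index(i, j)] <- 1
    if (diag_used) {
      A[row, 1L + p + s_index(i, i)] <- 2  # s_ii enters the row sum twice
    }
  }
  beta <- qr.solve(A, y)
  mu <- beta[1L]
  g <- beta[1L + seq_len(p)]
  s <- matrix(NA_real_, p, p, dimnames = dimnames(x))
  for (k in seq_len(n_cell)) {
    i <- cells[k, 1]; j <- cells[k, 2]
    s[i, j] <- s[j, i] <- beta[1L + p + k]
  }
  names(g) <- means$parents
  new_combining_ability(mu, g, s, method)
}

#' Pearson correlation between parent and F1 phenotypes
#'
#' Computes the Pearson correlation of paired parent and F1 phenotype
#' values with the two-sided p-value from
#' \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} on `n - 2` degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param parent_values,f1_values Paired numeric vectors of equal length
#'   (n >= 3).
#' @return A list with `r`, `p_value`, `n`.
#' @export
parent_f1_correlation <- function(parent_values, f1_values) {
  if (length(parent_values) != length(f1_values)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- is.finite(parent_values) & is.finite(f1_values)
  x <- parent_values[ok]; y <- f1_values[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in one vector", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Parent-vs-F1 phenotype correlation for one focal parent
#'
#' For a focal parent, pairs each of its crosses' F1 phenotype with the
#' co-parent's own phenotype, per trait, and correlates. With
#' `scheme = "pooled_z"` (default) trait values are z-standardised within
#' trait across the involved genotypes and all traits are pooled into one
#' correlation (n = crosses x traits pairs); `"per_trait"` returns one
#' correlation per trait.
#'
#' @param phenotypes Long phenotype table (see [cross_means()]).
#' @param focal_parent Parent whose crosses are evaluated.
#' @param scheme Pairing scheme: `"pooled_z"` or `"per_trait"`.
#' @return For `"pooled_z"`, a list with `r`, `p_value`, `n`; for
#'   `"per_trait"`, a tibble with one row per trait.
#' @export
focal_parent_correlation <- function(phenotypes, focal_parent,
                                     scheme = c("pooled_z", "per_trait")) {
  scheme <- match.arg(scheme)
  a <- pmin(phenotypes$parent_a, phenotypes$parent_b)
  b <- pmax(phenotypes$parent_a, phenotypes$parent_b)
  ph <- tibble::tibble(a = a, b = b, trait = phenotypes$trait,
                       value = phenotypes$value)
  gm <- dplyr::summarise(dplyr::group_by(ph, .data$a, .data$b, .data$trait),
                         value = mean(.data$value), .groups = "drop")
  parents <- sort(unique(c(gm$a, gm$b)))
  if (!focal_parent %in% parents) {
    stop(sprintf("unknown parent '%s'", focal_parent), call. = FALSE)
  }
  co <- setdiff(parents, focal_parent)
  traits <- unique(gm$trait)
  lookup <- function(i, j, tr) {
    gm$value[gm$a == pmin(i, j) & gm$b == pmax(i, j) & gm$trait == tr]
  }
  pairs <- dplyr::bind_rows(lapply(traits, function(tr) {
    tibble::tibble(
      trait = tr,
      co_parent = co,
      parent_value = vapply(co, function(j) lookup(j, j, tr), numeric(1)),
      f1_value = vapply(co, function(j) lookup(focal_parent, j, tr), numeric(1))
    )
  }))
  if (scheme == "per_trait") {
    out <- lapply(split(pairs, pairs$trait), function(d) {
      ct <- parent_f1_correlation(d$parent_value, d$f1_value)
      tibble::tibble(trait = d$trait[1], r = ct$r, p_value = ct$p_value,
                     n = ct$n)
    })
    return(dplyr::bind_rows(out))
  }
  z <- function(v) (v - mean(v)) / stats::sd(v)
  pairs <- dplyr::mutate(dplyr::group_by(pairs, .data$trait),
                         parent_z = z(.data$parent_value),
                         f1_z = z(.data$f1_value))
  pairs <- dplyr::ungroup(pairs)
  parent_f1_correlation(pairs$parent_z, pairs$f1_z)
}
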