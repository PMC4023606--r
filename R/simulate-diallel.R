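#' Simulate phenotypes for a half-diallel cross
#'
#' Generates a long-format phenotype table for a half-diallel mating design
#' (all pairwise crosses among `p` parents, no reciprocals, selfs included)
#' under the Griffing fixed-effect model. The expectation of a cross
#' \eqn{i \times j} is \eqn{\mu + g_i + g_j + s_{ij}} and of a parent self
#' \eqn{\mu + 2 g_i + s_{ii}}, where \eqn{g} are the true general combining
#' ability (GCA) effects and \eqn{s} the specific combining ability (SCA)
#' deviations. SCA effects are drawn once per cross and trait
#' (\eqn{N(0, \code{sca_sd})}); independent plot error
#' (\eqn{N(0, \code{error_sd})}) is added to every replicate record.
#'
#' The supplied `g` is recentred to sum to zero per trait, matching the
#' identifiability constraint of the estimators in [gca_method2()] /
#' [gca_method4()], so that noise-free output returns `g` exactly when
#' re-estimated.
#'
#' @param p Number of parents (>= 3).
#' @param mu Grand mean, one value per trait; names become trait labels
#'   (unnamed input is labelled `trait1`, `trait2`, ...).
#' @param g True GCA effects: a length-`p` vector (shared across traits) or
#'   a `p x length(mu)` matrix with one column per trait. Trait units.
#' @param sca_sd Standard deviation of SCA effects (>= 0).
#' @param error_sd Plot-error standard deviation (>= 0).
#' @param n_env Number of environments (>= 1).
#' @param n_rep Replicates (plots) per environment (>= 1).
#' @param parents Optional character vector of parent names (length `p`).
#' @param include_selfs Include parental selfs (required downstream by
#'   Griffing Method 2; set `FALSE` for a crosses-only, Method 4 design).
#' @param seed Random seed; the same seed always yields the same table.
#'
#' @return A tibble with columns `parent_a`, `parent_b` (equal for selfs;
#'   `parent_a` < `parent_b` for crosses), `env`, `rep`, `trait`, `value`.
#' @seealso [cross_means()], [gca_method2()], [gca_method4()]
#' @examples
#' ph <- simulate_diallel_phenotypes(p = 3, mu = 10, g = c(1, 0, -1),
#'                                   sca_sd = 0, error_sd = 0, seed = 1)
#' subset(ph, parent_a != parent_b)
#' @export
simulate_diallel_phenotypes <- function(p, mu, g, sca_sd = 0, error_sd = 0,
                                        n_env = 1, n_rep = 1, parents = NULL,
                                        include_selfs = TRUE, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || p < 3) {
    stop("`p` must be a single integer >= 3", call. = FALSE)
  }
  p <- as.integer(p)
  stop_if_not_positive(sca_sd, "sca_sd", strict = FALSE)
  stop_if_not_positive(error_sd, "error_sd", strict = FALSE)
  if (n_env < 1 || n_rep < 1) {
    stop("`n_env` and `n_rep` must be >= 1", call. = FALSE)
  }
  n_trait <- length(mu)
  traits <- names(mu)
  if (is.null(traits)) traits <- paste0("trait", seq_len(n_trait))
  if (is.matrix(g)) {
    if (nrow(g) != p || ncol(g) != n_trait) {
      stop("`g` matrix must be p x length(mu)", call. = FALSE)
    }
  } else {
    if (length(g) != p) stop("`g` must have length p", call. = FALSE)
    g <- matrix(g, nrow = p, ncol = n_trait)
  }
  g <- sweep(g, 2, colMeans(g))  # identifiability: sum_i g_i = 0 per trait
  if (is.null(parents)) parents <- paste0("P", seq_len(p))
  if (length(parents) != p) stop("`parents` must have length p", call. = FALSE)

  idx <- which(upper.tri(diag(p), diag = include_selfs), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]

  with_seed(seed, {
    out <- vector("list", n_trait)
    for (t in seq_len(n_trait)) {
      s <- rnorm(nrow(idx), 0, sca_sd)
      cell_mean <- mu[[t]] + g[idx[, 1], t] + g[idx[, 2], t] + s
      grid <- tidyr::expand_grid(
        cell = seq_len(nrow(idx)),
        env  = paste0("E", seq_len(n_env)),
        rep  = seq_len(n_rep)
      )
      grid$parent_a <- parents[idx[grid$cell, 1]]
      grid$parent_b <- parents[idx[grid$cell, 2]]
      grid$trait <- traits[[t]]
      grid$value <- cell_mean[grid$cell] + rnorm(nrow(grid), 0, error_sd)
      out[[t]] <- grid[, c("parent_a", "parent_b", "env", "rep", "trait", "value")]
    }
    dplyr::bind_rows(out)
  })
}
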