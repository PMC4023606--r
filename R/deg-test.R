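#' Audic-Claverie probability of a count pair
#'
#' Probability of observing `y` reads for a gene in a library of size `N2`
#' given `x` reads in a library of size `N1`, under the Audic-Claverie
#' model for unreplicated tag/read counts:
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x! \, y! \, (1 + N_2/N_1)^{x+y+1}}.}
#' Evaluated in log space with `lgamma` for numerical stability; vectorised
#' over `x` and `y`.
#'
#' @param x,y Non-negative integer counts.
#' @param n1,n2 Library sizes (> 0).
#' @return Probability value(s) in (0, 1].
#' @references Audic, S. and Claverie, J.-M. (1997). The significance of
#'   digital gene expression profiles. *Genome Research* 7, 986-995.
#' @export
ac_probability <- function(x, y, n1, n2) {
  stop_if_not_count(x, "x"); stop_if_not_count(y, "y")
  stop_if_not_positive(n1, "n1"); stop_if_not_positive(n2, "n2")
  exp(ac_log_probability(x, y, n1, n2))
}

ac_log_probability <- function(x, y, n1, n2) {
  r <- n2 / n1
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

#' Two-sided Audic-Claverie p-value
#'
#' Two-sided p-value for the difference between two library counts,
#' computed as twice the smaller conditional tail probability, capped at 1:
#' `p = min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`, with tails summed
#' from [ac_probability()] terms in log space.
#'
#' @inheritParams ac_probability
#' @return p-value(s) in (0, 1]. Vectorised over `x`, `y`.
#' @export
ac_two_sided_p <- function(x, y, n1, n2) {
  stop_if_not_count(x, "x"); stop_if_not_count(y, "y")
  stop_if_not_positive(n1, "n1"); stop_if_not_positive(n2, "n2")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) {
    lp <- ac_log_probability(x[i], 0:y[i], n1[i], n2[i])
    p_y <- exp(lp[length(lp)])
    lower <- exp(logsumexp(lp))
    # P(Y >= y) inclusive; the max() guards against cancellation when the
    # lower tail is ~1 (the point mass is always a lower bound on the tail).
    upper <- max(1 - lower + p_y, p_y)
    min(1, 2 * min(lower, upper))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]); input
#' order is preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in (0, 1\].
#' @references Benjamini, Y. and Hochberg, Y. (1995). Controlling the false
#'   discovery rate. *JRSS B* 57, 289-300.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' For every gene, computes the library-size-normalised fold change and the
#' two-sided Audic-Claverie p-value between two samples, applies
#' Benjamini-Hochberg FDR across all tested genes of the pair, and flags a
#' gene as differentially expressed when the fold change strictly exceeds
#' `fc_threshold` and the q-value (or raw p-value with `use_q = FALSE`)
#' falls below `sig_threshold`.
#'
#' Zero handling: genes with zero counts in both samples are excluded from
#' testing; a gene with one zero and one positive count has infinite fold
#' change and so passes the fold-change criterion. No pseudocount is added.
#'
#' @param counts Integer count matrix (genes x samples, with dimnames).
#' @param lib_sizes Named library sizes covering both samples.
#' @param sample_a,sample_b Column names of the two samples (distinct).
#' @param fc_threshold Fold-change threshold; strict `>` ("more than
#'   n-fold"). Default 2.
#' @param sig_threshold Significance threshold on q (default 0.05).
#' @param use_q Test on BH q-values (default) or on raw p-values.
#' @return A tibble with one row per tested gene: `gene_id`, `count_a`,
#'   `count_b`, `norm_a`, `norm_b` (counts per library size), `fold_change`
#'   (>= 1, ratio larger/smaller), `direction` (`a_higher`, `b_higher`,
#'   `none`), `p_value`, `q_value`, `is_deg`.
#' @export
call_degs <- function(counts, lib_sizes, sample_a, sample_b,
                      fc_threshold = 2, sig_threshold = 0.05, use_q = TRUE) {
  if (identical(sample_a, sample_b)) {
    stop("the two samples must differ", call. = FALSE)
  }
  for (s in c(sample_a, sample_b)) {
    if (!s %in% colnames(counts)) {
      stop(sprintf("unknown sample '%s'", s), call. = FALSE)
    }
  }
  missing_lib <- setdiff(c(sample_a, sample_b), names(lib_sizes))
  if (length(missing_lib)) {
    stop(sprintf("no library size for sample(s): %s",
                 paste(missing_lib, collapse = ", ")), call. = FALSE)
  }
  xa <- counts[, sample_a]
  xb <- counts[, sample_b]
  keep <- xa + xb > 0
  xa <- xa[keep]; xb <- xb[keep]
  ids <- rownames(counts)[keep]
  na <- lib_sizes[[sample_a]]; nb <- lib_sizes[[sample_b]]
  norm_a <- xa / na
  norm_b <- xb / nb
  fc <- pmax(norm_a, norm_b) / pmin(norm_a, norm_b)  # Inf when one is 0
  direction <- ifelse(norm_a > norm_b, "a_higher",
                      ifelse(norm_b > norm_a, "b_higher", "none"))
  p <- ac_two_sided_p(xa, xb, na, nb)
  q <- bh_fdr(p)
  sig <- if (use_q) q < sig_threshold else p < sig_threshold
  tibble::tibble(
    gene_id = ids,
    count_a = unname(xa), count_b = unname(xb),
    norm_a = unname(norm_a), norm_b = unname(norm_b),
    fold_change = unname(fc),
    direction = unname(direction),
    p_value = unname(p), q_value = unname(q),
    is_deg = unname(fc > fc_threshold & sig)
  )
}
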