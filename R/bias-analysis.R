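#' Fraction of expressed genes similar to a parent
#'
#' A gene is "similar" to a parent when the F1-vs-parent comparison did not
#' call it differentially expressed. The fraction is computed over an
#' explicit expressed-gene universe; genes of that universe absent from the
#' DEG table (untestable, e.g. zero in both libraries) count as similar.
#' The per-parent fractions of a trio may sum above 1, since a gene can be
#' similar to both parents.
#'
#' @param deg_calls DEG table from [call_degs()] for the F1-vs-parent pair.
#' @param expressed Character vector of gene ids defining the denominator
#'   (typically genes expressed in the F1).
#' @return A list with `fraction`, `n_similar`, `n_expressed`.
#' @export
similarity_to_parent <- function(deg_calls, expressed) {
  if (length(expressed) == 0L) {
    stop("empty expressed-gene set", call. = FALSE)
  }
  deg_ids <- deg_calls$gene_id[deg_calls$is_deg]
  n_sim <- sum(!expressed %in% deg_ids)
  list(fraction = n_sim / length(expressed),
       n_similar = n_sim, n_expressed = length(expressed))
}

#' Classify each gene's F1 expression relative to the two parents
#'
#' Assigns every tested gene of a parent/parent/F1 trio to one of five
#' categories. A gene enters the differential trichotomy when it is a DEG
#' (fold-change and significance rule of [call_degs()]) against at least
#' one parent; genes that are DEGs against neither parent are `non_deg`.
#' Within the trichotomy, a statistically significant difference against a
#' parent is `q_value < sig_threshold` for that comparison:
#'
#' * significant against exactly one parent — `equal_P1` / `equal_P2`,
#'   named for the parent the F1 does *not* differ from;
#' * significant against both — `over_parents` when the F1's normalised
#'   expression lies strictly outside the parental range,
#'   `between_parents` otherwise (boundary-equal values fall between).
#'
#' The distinction between the DEG rule (which gates entry) and plain
#' statistical significance (which localises the difference) matters for
#' mid-parent genes: an F1 at the arithmetic mid-parent value is never more
#' than 2-fold below the high parent, yet can differ significantly from
#' both parents.
#'
#' @param deg_p1,deg_p2 DEG tables from [call_degs()] for F1-vs-P1 and
#'   F1-vs-P2 (same fold-change/significance settings).
#' @param expr RPKM matrix (genes x samples) covering all tested genes.
#' @param f1,p1,p2 Column names of the three samples in `expr`.
#' @param sig_threshold q-value threshold defining a significant
#'   per-parent difference; use the `sig_threshold` given to [call_degs()].
#' @return A tibble with `gene_id`, `category` (one of `equal_P1`,
#'   `equal_P2`, `over_parents`, `between_parents`, `non_deg`) and
#'   `closer_parent` (`P1`, `P2`, `tie`, `undefined`).
#' @export
classify_trio <- function(deg_p1, deg_p2, expr, f1 = "F1", p1 = "P1",
                          p2 = "P2", sig_threshold = 0.05) {
  genes <- union(deg_p1$gene_id, deg_p2$gene_id)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop(sprintf("no expression value for tested gene(s): %s",
                 paste(utils::head(missing, 3), collapse = ", ")),
         call. = FALSE)
  }
  for (s in c(f1, p1, p2)) {
    if (!s %in% colnames(expr)) {
      stop(sprintf("unknown sample '%s' in `expr`", s), call. = FALSE)
    }
  }
  get <- function(tab, col) {
    v <- tab[[col]][match(genes, tab$gene_id)]
    if (is.logical(tab[[col]])) v[is.na(v)] <- FALSE
    v
  }
  deg1 <- get(deg_p1, "is_deg"); deg2 <- get(deg_p2, "is_deg")
  q1 <- get(deg_p1, "q_value"); q2 <- get(deg_p2, "q_value")
  sig1 <- !is.na(q1) & q1 < sig_threshold
  sig2 <- !is.na(q2) & q2 < sig_threshold

  e_f1 <- expr[genes, f1]
  e_p1 <- expr[genes, p1]
  e_p2 <- expr[genes, p2]
  lo <- pmin(e_p1, e_p2); hi <- pmax(e_p1, e_p2)
  outside <- e_f1 < lo | e_f1 > hi            # strict: boundary is inside

  category <- rep("non_deg", length(genes))
  in_trich <- deg1 | deg2
  # localise the difference by statistical significance; if the raw-p mode
  # of call_degs left both q's non-significant, fall back to the DEG flags
  s1 <- ifelse(in_trich & !sig1 & !sig2, deg1, sig1)
  s2 <- ifelse(in_trich & !sig1 & !sig2, deg2, sig2)
  category[in_trich & s1 & !s2] <- "equal_P2"
  category[in_trich & !s1 & s2] <- "equal_P1"
  category[in_trich & s1 & s2] <- ifelse(outside[in_trich & s1 & s2],
                                         "over_parents", "between_parents")

  tibble::tibble(
    gene_id = genes,
    category = category,
    closer_parent = closer_parent(e_p1, e_p2, e_f1)
  )
}

#' Which parent is an F1's expression closer to?
#'
#' Chooses the parent minimising the absolute log2 ratio
#' `|log2((F1 + e) / (P + e))|`, where `e` is 0 except for exact zeros,
#' which are replaced by `zero_eps` (default: half the smallest nonzero
#' value among the inputs) so that log ratios stay defined. Returns `tie`
#' when the two distances are equal and `undefined` when all three values
#' are zero.
#'
#' @param p1,p2,f1 Non-negative expression values (vectorised).
#' @param zero_eps Replacement for exact zeros inside ratios; `NULL` means
#'   half the smallest nonzero input value.
#' @return Character vector over `{"P1", "P2", "tie", "undefined"}`.
#' @export
closer_parent <- function(p1, p2, f1, zero_eps = NULL) {
  n <- max(length(p1), length(p2), length(f1))
  p1 <- rep_len(p1, n); p2 <- rep_len(p2, n); f1 <- rep_len(f1, n)
  if (any(c(p1, p2, f1) < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  if (is.null(zero_eps)) {
    pos <- c(p1, p2, f1); pos <- pos[pos > 0]
    zero_eps <- if (length(pos)) min(pos) / 2 else 1
  }
  adj <- function(v) ifelse(v == 0, zero_eps, v)
  d1 <- abs(log2(adj(f1) / adj(p1)))
  d2 <- abs(log2(adj(f1) / adj(p2)))
  out <- ifelse(d1 < d2, "P1", ifelse(d2 < d1, "P2", "tie"))
  out[p1 == 0 & p2 == 0 & f1 == 0] <- "undefined"
  out
}

#' Count genes higher in every comparison sample than in a reference
#'
#' Counts the genes whose expression in *each* of the comparison samples
#' strictly exceeds its expression in the reference sample.
#'
#' @param expr Expression matrix (genes x samples) with dimnames.
#' @param genes Gene ids to consider (non-empty, all present in `expr`).
#' @param comparison_samples Column names that must all exceed the
#'   reference.
#' @param reference Reference column name.
#' @return Integer count; the qualifying gene ids are attached as
#'   attribute `"genes"`.
#' @export
count_higher_in_all <- function(expr, genes, comparison_samples, reference) {
  if (length(genes) == 0L) stop("empty gene set", call. = FALSE)
  bad <- setdiff(c(comparison_samples, reference), colnames(expr))
  if (length(bad)) {
    stop(sprintf("unknown sample(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop(sprintf("unknown gene(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  sub <- expr[genes, , drop = FALSE]
  hit <- apply(sub[, comparison_samples, drop = FALSE] >
                 sub[, reference], 1, all)
  structure(sum(hit), genes = genes[hit])
}

#' Aggregate a trio classification into bias fractions
#'
#' Summarises [classify_trio()] output into the fractions used to describe
#' parental expression bias, with every denominator reported next to its
#' fraction:
#'
#' * `frac_deg` — DEG trio genes over the expressed universe
#'   (`n_expressed`, which defaults to the number of classified genes);
#' * `frac_equal_parent`, `frac_over`, `frac_between` — category fractions
#'   over DEG trio genes;
#' * `frac_equal_bias_P1`, `frac_equal_bias_P2` — split of the
#'   equal-parent genes between the two parents (they sum to 1).
#'
#' Fractions with a zero denominator are returned as `NA` rather than
#' failing.
#'
#' @param classification Tibble from [classify_trio()].
#' @param similarity_p1,similarity_p2 Optional outputs of
#'   [similarity_to_parent()] to carry through into the summary.
#' @param n_expressed Size of the expressed-gene universe for `frac_deg`.
#' @param hybrid_id Optional label for the hybrid.
#' @return A list of class `bias_summary`.
#' @export
bias_summary <- function(classification, similarity_p1 = NULL,
                         similarity_p2 = NULL, n_expressed = NULL,
                         hybrid_id = NULL) {
  stopifnot(all(c("gene_id", "category") %in% names(classification)))
  n_tested <- nrow(classification)
  if (is.null(n_expressed)) n_expressed <- n_tested
  tab <- table(factor(classification$category,
                      levels = c("equal_P1", "equal_P2", "over_parents",
                                 "between_parents", "non_deg")))
  n_equal <- tab[["equal_P1"]] + tab[["equal_P2"]]
  n_deg <- n_tested - tab[["non_deg"]]
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    hybrid_id = hybrid_id,
    n_expressed = n_expressed,
    n_tested = n_tested,
    n_deg = n_deg,
    n_equal_parent = n_equal,
    frac_deg = frac(n_deg, n_expressed),
    frac_equal_parent = frac(n_equal, n_deg),
    frac_over = frac(tab[["over_parents"]], n_deg),
    frac_between = frac(tab[["between_parents"]], n_deg),
    frac_equal_bias_P1 = frac(tab[["equal_P1"]], n_equal),
    frac_equal_bias_P2 = frac(tab[["equal_P2"]], n_equal),
    frac_similar_P1 = if (!is.null(similarity_p1)) similarity_p1$fraction,
    frac_similar_P2 = if (!is.null(similarity_p2)) similarity_p2$fraction
  ), class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("Parental bias summary%s\n",
              if (!is.null(x$hybrid_id)) paste0(" for ", x$hybrid_id) else ""))
  cat(sprintf("  DEG fraction:        %.3f (%d / %d expressed)\n",
              x$frac_deg, x$n_deg, x$n_expressed))
  cat(sprintf("  equal to one parent: %.3f  over: %.3f  between: %.3f (of %d DEGs)\n",
              x$frac_equal_parent, x$frac_over, x$frac_between, x$n_deg))
  cat(sprintf("  equal-parent split:  P1 %.3f / P2 %.3f (of %d genes)\n",
              x$frac_equal_bias_P1, x$frac_equal_bias_P2, x$n_equal_parent))
  invisible(x)
}
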