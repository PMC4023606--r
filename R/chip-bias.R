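#' Gene-body RPKM for ChIP read counts
#'
#' Normalises per-gene ChIP read counts to RPKM over the gene body
#' (`1e9 * count / (lib_size * gene_length)`), per mark and sample.
#'
#' @param chip_counts Long tibble with columns `gene_id`, `mark`, `sample`,
#'   `count` (e.g. from [simulate_chip_counts()] or [read_chip_counts()]).
#' @param models Gene-model table with `gene_id` and `length`.
#' @param lib_sizes Named library sizes covering every sample present.
#' @return The input tibble with an added `rpkm` column; genes lacking a
#'   model are dropped with a warning.
#' @export
gene_body_rpkm <- function(chip_counts, models, lib_sizes) {
  stopifnot(all(c("gene_id", "mark", "sample", "count") %in%
                  names(chip_counts)))
  missing_lib <- setdiff(unique(chip_counts$sample), names(lib_sizes))
  if (length(missing_lib)) {
    stop(sprintf("no library size for sample(s): %s",
                 paste(missing_lib, collapse = ", ")), call. = FALSE)
  }
  len <- setNames(models$length, models$gene_id)
  keep <- chip_counts$gene_id %in% names(len)
  if (!any(keep)) stop("no counted gene has a gene model", call. = FALSE)
  if (!all(keep)) {
    warning(sprintf("%d record(s) without a gene model dropped", sum(!keep)),
            call. = FALSE)
    chip_counts <- chip_counts[keep, , drop = FALSE]
  }
  dplyr::mutate(chip_counts,
                rpkm = rpkm(.data$count,
                            unname(lib_sizes[.data$sample]),
                            unname(len[.data$gene_id])))
}

#' Genes carrying a histone mark in a sample
#'
#' Returns the genes considered "modified" for a mark in a sample: RPKM
#' strictly above `min_rpkm` (so a threshold of 0 excludes only
#' zero-signal genes) and read count at least `min_count`. The count floor
#' guards against calling a mark present from one or two stray reads in
#' the absence of a peak-calling step.
#'
#' @param signals Tibble from [gene_body_rpkm()].
#' @param mark,sample Mark and sample to select.
#' @param min_rpkm RPKM threshold (strict `>`).
#' @param min_count Minimum read count (default 10).
#' @return Character vector of gene ids.
#' @export
modified_gene_set <- function(signals, mark, sample, min_rpkm = 0,
                              min_count = 10) {
  if (min_rpkm < 0) stop("`min_rpkm` must be >= 0", call. = FALSE)
  sel <- signals$mark == mark & signals$sample == sample
  if (!any(sel)) {
    stop(sprintf("no records for mark '%s' in sample '%s'", mark, sample),
         call. = FALSE)
  }
  sub <- signals[sel, ]
  sub$gene_id[sub$rpkm > min_rpkm & sub$count >= min_count]
}

#' Modification similarity between an F1 hybrid and a parent
#'
#' Tests, gene by gene, whether the F1's gene-body signal for a mark
#' differs from a parent's, using the two-sided Audic-Claverie test on raw
#' gene-body counts with library sizes, and Benjamini-Hochberg FDR over
#' the tested universe. The universe is the union of the two samples'
#' modified-gene sets ([modified_gene_set()]). A gene is "similar" when
#' its q-value is at or above `fdr_threshold` (default 0.001, the
#' histone-modification rule); the similarity fraction is
#' `n_similar / n_universe`.
#'
#' @param signals Tibble from [gene_body_rpkm()] containing both samples.
#' @param mark Histone mark to test.
#' @param sample_f1,sample_parent The two samples to compare.
#' @param lib_sizes Named library sizes.
#' @param fdr_threshold FDR below which a gene is differentially modified.
#' @param min_rpkm,min_count Modified-gene thresholds passed to
#'   [modified_gene_set()].
#' @return A list with `fraction` (similar / universe), `n_similar`,
#'   `n_universe`, and `calls` (per-gene tibble with counts, `p_value`,
#'   `q_value`, `similar`).
#' @export
modification_similarity <- function(signals, mark, sample_f1, sample_parent,
                                    lib_sizes, fdr_threshold = 0.001,
                                    min_rpkm = 0, min_count = 10) {
  universe <- union(
    modified_gene_set(signals, mark, sample_f1, min_rpkm, min_count),
    modified_gene_set(signals, mark, sample_parent, min_rpkm, min_count)
  )
  if (length(universe) == 0L) {
    stop("empty modified-gene universe", call. = FALSE)
  }
  pick <- function(s) {
    sub <- signals[signals$mark == mark & signals$sample == s, ]
    setNames(sub$count, sub$gene_id)[universe]
  }
  x <- pick(sample_f1)
  y <- pick(sample_parent)
  if (anyNA(x) || anyNA(y)) {
    stop("universe genes missing a count in one sample", call. = FALSE)
  }
  p <- ac_two_sided_p(x, y, lib_sizes[[sample_f1]], lib_sizes[[sample_parent]])
  q <- bh_fdr(p)
  similar <- q >= fdr_threshold
  list(
    fraction = mean(similar),
    n_similar = sum(similar),
    n_universe = length(universe),
    calls = tibble::tibble(gene_id = universe,
                           count_f1 = unname(x), count_parent = unname(y),
                           p_value = p, q_value = q, similar = similar)
  )
}

#' Overlap between two modified-gene sets
#'
#' Jaccard overlap `|A n B| / |A u B|` between two gene sets (e.g. genes
#' carrying two different histone marks), with both directional fractions
#' `|A n B| / |A|` and `|A n B| / |B|` also reported.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return A list with `jaccard`, `frac_of_a`, `frac_of_b`,
#'   `n_intersection`, `n_union`; all fractions `NA` when both sets are
#'   empty.
#' @export
mark_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  ni <- length(intersect(set_a, set_b))
  nu <- length(union(set_a, set_b))
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  list(jaccard = frac(ni, nu),
       frac_of_a = frac(ni, length(set_a)),
       frac_of_b = frac(ni, length(set_b)),
       n_intersection = ni, n_union = nu)
}
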