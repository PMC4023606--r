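#' Reads Per Kilobase per Million mapped reads
#'
#' `RPKM = 1e9 * C / (N * L)` for read count `C`, library size `N` (total
#' mapped reads) and feature length `L` in bp. Vectorised over all three
#' arguments.
#'
#' @param count Non-negative read count(s).
#' @param lib_size Library size(s), > 0.
#' @param length_bp Feature length(s) in bp, > 0.
#' @return Numeric RPKM value(s); 0 wherever `count` is 0.
#' @examples
#' rpkm(10, 1e6, 1000)  # 10
#' @export
rpkm <- function(count, lib_size, length_bp) {
  stop_if_not_positive(lib_size, "lib_size")
  stop_if_not_positive(length_bp, "length_bp")
  if (any(count < 0)) stop("`count` must be non-negative", call. = FALSE)
  1e9 * count / (lib_size * length_bp)
}

#' RPKM matrix from a count matrix and gene models
#'
#' Applies [rpkm()] elementwise to a genes-by-samples count matrix, taking
#' per-gene lengths from a gene-model table and per-sample library sizes.
#' Genes without a model are dropped with a warning.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param lib_sizes Named numeric vector of library sizes covering every
#'   column of `counts`.
#' @param models Gene-model data frame with `gene_id` and `length` columns
#'   (e.g. from [simulate_gene_models()] or [read_gene_models()]).
#' @return Numeric matrix of RPKM values with the same dimnames as the
#'   retained rows of `counts`.
#' @export
rpkm_matrix <- function(counts, lib_sizes, models) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  missing_lib <- setdiff(colnames(counts), names(lib_sizes))
  if (length(missing_lib)) {
    stop(sprintf("no library size for sample(s): %s",
                 paste(missing_lib, collapse = ", ")), call. = FALSE)
  }
  len <- setNames(models$length, models$gene_id)
  keep <- rownames(counts) %in% names(len)
  if (!any(keep)) {
    stop("no gene in `counts` has a gene model", call. = FALSE)
  }
  if (!all(keep)) {
    warning(sprintf("%d gene(s) without a model dropped", sum(!keep)),
            call. = FALSE)
    counts <- counts[keep, , drop = FALSE]
  }
  L <- len[rownames(counts)]
  N <- lib_sizes[colnames(counts)]
  # same operation order as the scalar rpkm(), so the two agree bitwise
  denom <- outer(unname(L), unname(N))
  out <- 1e9 * counts / denom
  dimnames(out) <- dimnames(counts)
  out
}

#' Expressed-gene call
#'
#' Returns the genes whose RPKM in a sample strictly exceeds a threshold.
#' The default threshold 0 treats any nonzero signal as expressed.
#'
#' @param expr RPKM matrix (genes x samples) with dimnames.
#' @param sample Sample (column) name.
#' @param threshold Non-negative RPKM threshold; strict `>` is applied.
#' @return Character vector of gene ids.
#' @export
expressed_genes <- function(expr, sample, threshold = 0) {
  if (!sample %in% colnames(expr)) {
    stop(sprintf("unknown sample '%s'", sample), call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  rownames(expr)[expr[, sample] > threshold]
}
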