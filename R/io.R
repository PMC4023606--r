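#' Read and write long-format phenotype tables
#'
#' Phenotype CSVs have the columns `parent_a`, `parent_b`, `env`, `rep`,
#' `trait`, `value`, one row per plot record.
#'
#' @param phenotypes Data frame as produced by
#'   [simulate_diallel_phenotypes()].
#' @param path File path.
#' @return `read_phenotypes()` returns a tibble; `write_phenotypes()`
#'   returns `path` invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(all(c("parent_a", "parent_b", "env", "rep", "trait", "value")
                %in% names(phenotypes)))
  write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' Read and write count matrices with a library-size sidecar
#'
#' Counts are stored as TSV with a `gene_id` column plus one column per
#' sample; library sizes go to a two-column sidecar TSV (`sample`,
#' `lib_size`), by default at `<path>.libsizes`.
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param lib_sizes Named numeric vector covering every sample column.
#' @param path Count TSV path.
#' @param lib_path Sidecar path (default `<path>.libsizes`).
#' @return `read_counts()` returns `list(counts, lib_sizes)`;
#'   `write_counts()` returns `path` invisibly.
#' @export
write_counts <- function(counts, lib_sizes, path,
                         lib_path = paste0(path, ".libsizes")) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  missing_lib <- setdiff(colnames(counts), names(lib_sizes))
  if (length(missing_lib)) {
    stop(sprintf("no library size for sample(s): %s",
                 paste(missing_lib, collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ls_df <- data.frame(sample = colnames(counts),
                      lib_size = unname(lib_sizes[colnames(counts)]))
  write.table(ls_df, lib_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, lib_path = paste0(path, ".libsizes")) {
  df <- read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  ls_df <- read.delim(lib_path, check.names = FALSE)
  list(counts = counts,
       lib_sizes = setNames(ls_df$lib_size, ls_df$sample))
}

#' Read and write gene models as BED or GFF3
#'
#' Gene models are held internally with 0-based half-open coordinates
#' (`length = end - start`). On disk, BED keeps that convention while GFF3
#' is 1-based closed; both conversions are delegated to
#' [rtracklayer::export()] / [rtracklayer::import()].
#'
#' @param models Gene-model tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `length`).
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`; inferred from the file extension
#'   when `NULL`.
#' @return `read_gene_models()` returns a gene-model tibble;
#'   `write_gene_models()` returns `path` invisibly.
#' @export
write_gene_models <- function(models, path, format = NULL) {
  format <- infer_model_format(path, format)
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start + 1L, end = models$end),
    strand = models$strand
  )
  gr$name <- models$gene_id
  if (format == "bed") {
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "BED")
  } else {
    gr$type <- "gene"
    gr$ID <- models$gene_id
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path, format = NULL) {
  format <- infer_model_format(path, format)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  ids <- if (format == "bed") gr$name else {
    if (!is.null(gr$ID)) gr$ID else gr$Name
  }
  tibble::tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length = GenomicRanges::width(gr)
  )
}

infer_model_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("bed", "gff3")))
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") "bed"
  else if (ext %in% c("gff", "gff3")) "gff3"
  else stop("cannot infer gene-model format; pass `format`", call. = FALSE)
}

#' Read and write long-format ChIP count tables
#'
#' TSV with columns `gene_id`, `mark`, `sample`, `count`.
#'
#' @param chip_counts Tibble in the long ChIP count layout.
#' @param path File path.
#' @return `read_chip_counts()` returns a tibble; `write_chip_counts()`
#'   returns `path` invisibly.
#' @export
write_chip_counts <- function(chip_counts, path) {
  stopifnot(all(c("gene_id", "mark", "sample", "count") %in%
                  names(chip_counts)))
  write.table(chip_counts[, c("gene_id", "mark", "sample", "count")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chip_counts
#' @export
read_chip_counts <- function(path) {
  tibble::as_tibble(read.delim(path, check.names = FALSE))
}

#' Packaged RPKM fixture: flowering and GA pathway genes
#'
#' Published RPKM values for seven flowering-pathway and five gibberellin
#' (GA) metabolism genes in the rice parents GL, TQ and 93-11 and the
#' hybrids GL x TQ, GL x 93-11 and 93-11 x TQ. Useful as a small real-data
#' fixture for direction checks such as [count_higher_in_all()] and for
#' [expressed_genes()].
#'
#' @param as_matrix Return a numeric matrix (genes x samples, with the
#'   pathway as attribute `"pathway"`) instead of a tibble.
#' @return A tibble with columns `gene`, `pathway` and the six sample
#'   columns, or the corresponding matrix.
#' @export
table2_expression <- function(as_matrix = FALSE) {
  path <- system.file("extdata", "pathway_rpkm.tsv", package = "gcabias",
                      mustWork = TRUE)
  df <- tibble::as_tibble(read.delim(path, check.names = FALSE))
  if (!as_matrix) return(df)
  m <- as.matrix(df[, -(1:2)])
  rownames(m) <- df$gene
  attr(m, "pathway") <- setNames(df$pathway, df$gene)
  m
}
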