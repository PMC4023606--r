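#' Build a pipeline configuration
#'
#' Assembles and validates the single configuration object driving
#' [run_pipeline()]. Only the count matrix and gene models are mandatory;
#' phenotype and ChIP inputs switch their stages on.
#'
#' @param counts Path to a count TSV (see [write_counts()]).
#' @param models Path to a BED or GFF3 gene-model file.
#' @param trios List of trio definitions, each a named list with
#'   `hybrid_id`, `f1`, `p1`, `p2` (sample names in the count matrix).
#' @param phenotypes Optional path to a phenotype CSV.
#' @param chip Optional path to a long ChIP count TSV; `chip_lib_sizes`
#'   must then name a library-size sidecar TSV (`sample`, `lib_size`).
#' @param chip_lib_sizes Optional path to the ChIP library-size TSV.
#' @param fc Fold-change threshold for expression DEGs (strict `>`).
#' @param fdr_expr FDR threshold for expression DEGs.
#' @param fdr_chip FDR threshold for differential histone modification.
#' @param expressed_rpkm Expressed-gene RPKM threshold (strict `>`).
#' @param min_chip_count Minimum gene-body count for a modified-gene call.
#' @param griffing_method Griffing method for the GCA stage, 2 or 4.
#' @param pairing_scheme Parent-F1 correlation pairing scheme.
#' @param distance,linkage Clustering options (see [cluster_samples()]).
#' @param seed Seed recorded in the report (the analysis stages are
#'   deterministic; the seed matters when inputs are generated).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, models, trios,
                            phenotypes = NULL,
                            chip = NULL, chip_lib_sizes = NULL,
                            fc = 2, fdr_expr = 0.05, fdr_chip = 0.001,
                            expressed_rpkm = 0, min_chip_count = 10,
                            griffing_method = 2,
                            pairing_scheme = c("pooled_z", "per_trait"),
                            distance = "correlation", linkage = "average",
                            seed = 1L) {
  cfg <- list(
    inputs = list(counts = counts, models = models, phenotypes = phenotypes,
                  chip = chip, chip_lib_sizes = chip_lib_sizes),
    trios = trios,
    thresholds = list(fc = fc, fdr_expr = fdr_expr, fdr_chip = fdr_chip,
                      expressed_rpkm = expressed_rpkm,
                      min_chip_count = min_chip_count),
    methods = list(griffing_method = as.integer(griffing_method),
                   pairing_scheme = match.arg(pairing_scheme),
                   distance = distance, linkage = linkage),
    seed = as.integer(seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  th <- cfg$thresholds
  if (th$fc <= 0 || th$fdr_expr <= 0 || th$fdr_chip <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (!cfg$methods$griffing_method %in% c(2L, 4L)) {
    stop("`griffing_method` must be 2 or 4", call. = FALSE)
  }
  for (tr in cfg$trios) {
    if (!all(c("hybrid_id", "f1", "p1", "p2") %in% names(tr))) {
      stop("each trio needs hybrid_id, f1, p1, p2", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML layout mirrors the arguments of [pipeline_config()]:
#' top-level keys `inputs`, `trios`, `thresholds`, `methods`, `seed`,
#' all optional except `inputs.counts`, `inputs.models` and `trios`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    list(counts = y$inputs$counts, models = y$inputs$models,
         trios = y$trios, phenotypes = y$inputs$phenotypes,
         chip = y$inputs$chip, chip_lib_sizes = y$inputs$chip_lib_sizes),
    y$thresholds, y$methods,
    if (!is.null(y$seed)) list(seed = y$seed)
  ))
}

#' Run the full bias-analysis pipeline
#'
#' Executes every configured stage — GCA estimation from phenotypes,
#' RPKM quantification, per-trio DEG calling and trio classification,
#' sample clustering, and ChIP modification-similarity analysis — writing
#' per-stage tables under `outdir` plus one JSON report containing every
#' summary fraction with its numerator, denominator and thresholds. The
#' run is deterministic for fixed inputs and configuration.
#'
#' @param config A `pipeline_config` object.
#' @param outdir Output directory (created if needed).
#' @return The report, invisibly, as a nested list (also written to
#'   `outdir/report.json`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  report <- list(
    package_version = as.character(utils::packageVersion("gcabias")),
    seed = config$seed,
    thresholds = th,
    methods = config$methods
  )

  cc <- read_counts(config$inputs$counts)
  models <- read_gene_models(config$inputs$models)
  expr <- rpkm_matrix(cc$counts, cc$lib_sizes, models)
  write.table(data.frame(gene_id = rownames(expr), expr, check.names = FALSE),
              file.path(outdir, "rpkm.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  message(sprintf("quantify: %d genes x %d samples", nrow(expr), ncol(expr)))

  if (!is.null(config$inputs$phenotypes)) {
    ph <- read_phenotypes(config$inputs$phenotypes)
    gca_rows <- lapply(unique(ph$trait), function(tr) {
      means <- cross_means(ph, tr)
      fit <- if (config$methods$griffing_method == 2L) {
        gca_method2(means)
      } else {
        gca_method4(means)
      }
      tibble::tibble(parent = names(fit$g), trait = tr, gca = unname(fit$g),
                     grand_mean = fit$mu)
    })
    gca_tab <- dplyr::bind_rows(gca_rows)
    write.table(gca_tab, file.path(outdir, "gca.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    report$gca <- lapply(split(gca_tab, gca_tab$trait), function(d) {
      list(grand_mean = d$grand_mean[1],
           gca = as.list(setNames(d$gca, d$parent)))
    })
    message(sprintf("gca: method %d, %d trait(s)",
                    config$methods$griffing_method, length(unique(ph$trait))))
  }

  report$trios <- lapply(config$trios, function(tr) {
    f1 <- tr$f1; p1 <- tr$p1; p2 <- tr$p2
    deg1 <- call_degs(cc$counts, cc$lib_sizes, f1, p1,
                      fc_threshold = th$fc, sig_threshold = th$fdr_expr)
    deg2 <- call_degs(cc$counts, cc$lib_sizes, f1, p2,
                      fc_threshold = th$fc, sig_threshold = th$fdr_expr)
    write.table(deg1, file.path(outdir, sprintf("deg_%s_vs_%s.tsv", f1, p1)),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(deg2, file.path(outdir, sprintf("deg_%s_vs_%s.tsv", f1, p2)),
                sep = "\t", row.names = FALSE, quote = FALSE)
    expressed <- expressed_genes(expr, f1, th$expressed_rpkm)
    sim1 <- similarity_to_parent(deg1, expressed)
    sim2 <- similarity_to_parent(deg2, expressed)
    cls <- classify_trio(deg1, deg2, expr, f1 = f1, p1 = p1, p2 = p2,
                         sig_threshold = th$fdr_expr)
    write.table(cls, file.path(outdir,
                               sprintf("classification_%s.tsv", tr$hybrid_id)),
                sep = "\t", row.names = FALSE, quote = FALSE)
    bs <- bias_summary(cls, sim1, sim2, n_expressed = length(expressed),
                       hybrid_id = tr$hybrid_id)
    message(sprintf("bias: %s, %d DEG trio genes / %d expressed",
                    tr$hybrid_id, bs$n_deg, bs$n_expressed))
    c(list(hybrid_id = tr$hybrid_id, f1 = f1, p1 = p1, p2 = p2),
      unclass(bs)[setdiff(names(unclass(bs)), "hybrid_id")],
      list(n_similar_P1 = sim1$n_similar, n_similar_P2 = sim2$n_similar))
  })

  hc <- cluster_samples(expr, distance = config$methods$distance,
                        linkage = config$methods$linkage)
  as_newick(hc, file.path(outdir, "samples.nwk"))
  report$clustering <- list(newick = as_newick(hc),
                            distance = config$methods$distance,
                            linkage = config$methods$linkage)

  if (!is.null(config$inputs$chip)) {
    chip <- read_chip_counts(config$inputs$chip)
    ls_df <- read.delim(config$inputs$chip_lib_sizes, check.names = FALSE)
    chip_ls <- setNames(ls_df$lib_size, ls_df$sample)
    sig <- gene_body_rpkm(chip, models, chip_ls)
    marks <- unique(sig$mark)
    report$chip <- lapply(config$trios, function(tr) {
      per_mark <- lapply(marks, function(mk) {
        res <- lapply(c(tr$p1, tr$p2), function(par) {
          ms <- modification_similarity(sig, mk, tr$f1, par, chip_ls,
                                        fdr_threshold = th$fdr_chip,
                                        min_count = th$min_chip_count)
          list(parent = par, fraction = ms$fraction,
               n_similar = ms$n_similar, n_universe = ms$n_universe)
        })
        setNames(res, c(tr$p1, tr$p2))
      })
      ov <- if (length(marks) == 2L) {
        mark_overlap(
          modified_gene_set(sig, marks[1], tr$f1, min_count = th$min_chip_count),
          modified_gene_set(sig, marks[2], tr$f1, min_count = th$min_chip_count)
        )
      }
      list(hybrid_id = tr$hybrid_id,
           similarity = setNames(per_mark, marks),
           mark_overlap_f1 = ov)
    })
    message(sprintf("chip: %d mark(s), %d trio(s)", length(marks),
                    length(config$trios)))
  }

  write_report(report, file.path(outdir, "report.json"))
  invisible(report)
}

#' Write the pipeline report as JSON
#'
#' Serialises a [run_pipeline()] report. The report must already contain
#' the version, seed, threshold and trio sections; every fraction inside
#' it sits next to its numerator and denominator so it can be recomputed
#' from the emitted per-gene tables.
#'
#' @param report Nested report list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  required <- c("package_version", "seed", "thresholds", "trios")
  missing <- setdiff(required, names(report))
  if (length(missing)) {
    stop(sprintf("report is missing section(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
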