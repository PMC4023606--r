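#' Simulate non-overlapping gene models on synthetic chromosomes
#'
#' Lays out `n_genes` genes sequentially along one or more synthetic
#' chromosomes with random intergenic gaps, so intervals never overlap.
#' Coordinates are 0-based half-open internally (BED convention); gene
#' length is `end - start`.
#'
#' @param n_genes Number of genes (> 0).
#' @param length_range Two-element numeric, min and max gene length in bp.
#' @param gap_range Two-element numeric, min and max intergenic gap in bp.
#' @param n_chrom Number of synthetic chromosomes to spread genes over.
#' @param chrom_length Optional fixed chromosome length; an error is raised
#'   if the genes do not fit.
#' @param seed Random seed.
#'
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `length`.
#' @seealso [write_gene_models()], [read_gene_models()]
#' @export
simulate_gene_models <- function(n_genes, length_range = c(500, 5000),
                                 gap_range = c(200, 2000), n_chrom = 1,
                                 chrom_length = NULL, seed = NULL) {
  if (n_genes < 1) stop("`n_genes` must be > 0", call. = FALSE)
  stop_if_not_positive(length_range, "length_range")
  if (length(length_range) != 2L || length_range[1] > length_range[2]) {
    stop("`length_range` must be c(min, max) with min <= max", call. = FALSE)
  }
  with_seed(seed, {
    len <- round(runif(n_genes, length_range[1], length_range[2]))
    gap <- round(runif(n_genes, gap_range[1], gap_range[2]))
    chrom_idx <- rep(seq_len(n_chrom), length.out = n_genes)
    start <- integer(n_genes)
    cursor <- setNames(rep(0L, n_chrom), seq_len(n_chrom))
    for (i in seq_len(n_genes)) {
      k <- chrom_idx[i]
      start[i] <- cursor[k] + gap[i]
      cursor[k] <- start[i] + len[i]
      if (!is.null(chrom_length) && cursor[k] > chrom_length) {
        stop(sprintf("genes do not fit: chromosome %d exceeds length %d",
                     k, chrom_length), call. = FALSE)
      }
    }
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      chrom = paste0("chr", chrom_idx),
      start = start,
      end = start + len,
      strand = strand,
      length = len
    )
  })
}

# Draw counts with mean `mu`; NB with the given dispersion, Poisson at 0.
draw_counts <- function(mu, dispersion) {
  if (dispersion <= 0) rpois(length(mu), mu) else {
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
}

# Expected read count for an expression level in RPKM units.
rpkm_to_mean_count <- function(rpkm, length, lib_size) {
  rpkm * length * lib_size / 1e9
}

#' Simulate read counts for a parent/parent/F1 trio with known structure
#'
#' Generates an integer count matrix for two parents and their F1 hybrid in
#' which each gene belongs to a known category describing where the F1's
#' true expression lies relative to the parents:
#'
#' * `equal_high` — F1 mean equals the designated (positive-GCA) parent;
#' * `equal_low` — F1 mean equals the other parent;
#' * `over_parents` — F1 mean outside the parental range, at `over_k` times
#'   the nearer boundary (above the maximum or below the minimum, chosen at
#'   random per gene);
#' * `between_parents` — F1 mean at the arithmetic mid-parent value;
#' * `null_equal` — all three means equal (the remainder after the four
#'   fractions).
#'
#' At differential genes (the first four categories) the two parents
#' differ by a per-gene fold drawn log-normally around `parent_fold`, with
#' the direction random: the designated parent is the higher-expressed one
#' at about half of these genes. Combining ability describes phenotype,
#' not a global expression shift, so an F1 biased towards one parent
#' tracks that parent's level gene by gene rather than being uniformly
#' up- or down-regulated. For `null_equal` genes all samples share the
#' baseline. True expression baselines are log-normal across genes; counts
#' are Poisson (`dispersion = 0`, one pooled library per genotype) or
#' negative binomial with the given dispersion, with expected count
#' `rpkm * length * lib_size / 1e9`.
#'
#' @param n_genes Number of genes.
#' @param frac_equal_high,frac_equal_low,frac_over,frac_between Category
#'   fractions, each in \[0, 1\] and summing to at most 1; the remainder of
#'   genes is `null_equal`. Defaults encode a hybrid in which about 30% of
#'   genes differ from a parent and most of those track the high-GCA parent.
#' @param dispersion Negative-binomial dispersion; 0 gives Poisson counts.
#' @param lib_sizes Named vector of library sizes for `P1`, `P2`, `F1`.
#' @param length_range Gene length range, passed to [simulate_gene_models()].
#' @param designated_parent The parent the `equal_high` genes track
#'   (`"P1"` or `"P2"`), playing the positive-GCA role.
#' @param parent_fold Median true RPKM ratio between the parents at
#'   differential genes (> 1). The per-gene ratio is log-normal around
#'   this value (`parent_fold_sdlog`); without that spread the parental
#'   difference would be a constant in log space and invisible to
#'   correlation-based clustering, which no real parent pair is.
#' @param parent_fold_sdlog Standard deviation of the per-gene log fold
#'   around `log(parent_fold)`.
#' @param over_k Multiple of the nearer parental boundary used for
#'   `over_parents` genes (> 1).
#' @param base_rpkm_meanlog,base_rpkm_sdlog Log-normal parameters of the
#'   low-parent baseline RPKM across genes.
#' @param category_assignment_out Return the true per-gene labels.
#' @param seed Random seed.
#'
#' @return A list of class `trio_sim` with elements `counts` (genes x
#'   samples integer matrix, columns `P1`, `P2`, `F1`), `lib_sizes`,
#'   `models` (gene models tibble) and, if requested, `truth` (tibble of
#'   `gene_id`, `category`, and true mean RPKM per sample).
#' @seealso [classify_trio()], [bias_summary()]
#' @export
simulate_trio_counts <- function(n_genes = 2000,
                                 frac_equal_high = 0.17,
                                 frac_equal_low = 0.07,
                                 frac_over = 0.04,
                                 frac_between = 0.02,
                                 dispersion = 0,
                                 lib_sizes = c(P1 = 1e7, P2 = 1e7, F1 = 1e7),
                                 length_range = c(500, 5000),
                                 designated_parent = c("P1", "P2"),
                                 parent_fold = 4,
                                 parent_fold_sdlog = 0.25,
                                 over_k = 2,
                                 base_rpkm_meanlog = log(8),
                                 base_rpkm_sdlog = 1,
                                 category_assignment_out = TRUE,
                                 seed = NULL) {
  designated_parent <- match.arg(designated_parent)
  fr <- c(frac_equal_high, frac_equal_low, frac_over, frac_between)
  for (f in fr) stop_if_not_scalar_prob(f, "category fraction")
  if (sum(fr) > 1 + 1e-12) {
    stop("category fractions must sum to at most 1", call. = FALSE)
  }
  if (n_genes < 1) stop("`n_genes` must be > 0", call. = FALSE)
  stop_if_not_positive(lib_sizes, "lib_sizes")
  if (parent_fold <= 1 || over_k <= 1) {
    stop("`parent_fold` and `over_k` must exceed 1", call. = FALSE)
  }

  with_seed(seed, {
    models <- simulate_gene_models(n_genes, length_range = length_range)
    n_cat <- floor(fr * n_genes)
    categories <- rep(
      c("equal_high", "equal_low", "over_parents", "between_parents", "null_equal"),
      times = c(n_cat, n_genes - sum(n_cat))
    )
    categories <- sample(categories)

    base <- exp(rnorm(n_genes, base_rpkm_meanlog, base_rpkm_sdlog))
    fold_g <- parent_fold * exp(rnorm(n_genes, 0, parent_fold_sdlog))
    up <- runif(n_genes) < 0.5   # designated parent higher at this gene?
    d_val <- ifelse(up, base * fold_g, base)   # designated parent
    o_val <- ifelse(up, base, base * fold_g)   # other parent
    is_null <- categories == "null_equal"
    d_val[is_null] <- base[is_null]
    o_val[is_null] <- base[is_null]

    f1 <- numeric(n_genes)
    f1[categories == "equal_high"] <- d_val[categories == "equal_high"]
    f1[categories == "equal_low"] <- o_val[categories == "equal_low"]
    f1[is_null] <- base[is_null]
    mid <- (d_val + o_val) / 2
    f1[categories == "between_parents"] <- mid[categories == "between_parents"]
    over_idx <- which(categories == "over_parents")
    if (length(over_idx)) {
      above <- as.logical(sample(c(TRUE, FALSE), length(over_idx), replace = TRUE))
      hi <- pmax(d_val, o_val); lo <- pmin(d_val, o_val)
      f1[over_idx] <- ifelse(above, hi[over_idx] * over_k,
                             lo[over_idx] / over_k)
    }

    true_rpkm <- if (designated_parent == "P1") {
      cbind(P1 = d_val, P2 = o_val, F1 = f1)
    } else {
      cbind(P1 = o_val, P2 = d_val, F1 = f1)
    }

    counts <- matrix(0L, n_genes, 3L,
                     dimnames = list(models$gene_id, c("P1", "P2", "F1")))
    for (s in colnames(counts)) {
      counts[, s] <- draw_counts(
        rpkm_to_mean_count(true_rpkm[, s], models$length, lib_sizes[[s]]),
        dispersion)
    }
    storage.mode(counts) <- "integer"

    out <- list(counts = counts, lib_sizes = lib_sizes, models = models)
    if (category_assignment_out) {
      out$truth <- tibble::tibble(
        gene_id = models$gene_id,
        category = categories,
        rpkm_P1 = true_rpkm[, "P1"],
        rpkm_P2 = true_rpkm[, "P2"],
        rpkm_F1 = true_rpkm[, "F1"]
      )
    }
    structure(out, class = "trio_sim")
  })
}

#' Simulate gene-body ChIP read counts with known parental bias
#'
#' Generates per-gene ChIP read counts for two parents and an F1 hybrid at
#' one histone mark. A fraction `modified_fraction` of genes carries the
#' mark; the remaining genes receive only a low background signal. Among
#' modified genes the two parents differ by `fold` in true gene-body RPKM,
#' and the F1 mean equals the designated parent's mean for `bias_fraction`
#' of them and the other parent's mean for the rest — the ground truth that
#' [modification_similarity()] should recover.
#'
#' @param models Gene models tibble from [simulate_gene_models()].
#' @param bias_fraction Fraction of modified genes whose F1 signal tracks
#'   the designated parent (in \[0, 1\]).
#' @param modified_fraction Fraction of genes carrying the mark.
#' @param mark Mark label, e.g. `"H3K36me3"`.
#' @param designated_parent Parent the F1 is biased towards (`"P1"`/`"P2"`).
#' @param fold True signal ratio between the two parents at modified genes.
#' @param signal_rpkm_meanlog,signal_rpkm_sdlog Log-normal parameters of
#'   the designated parent's signal over modified genes.
#' @param background_rpkm Mean background RPKM at unmodified genes.
#' @param dispersion Negative-binomial dispersion; 0 gives Poisson.
#' @param lib_sizes Named library sizes for `P1`, `P2`, `F1`.
#' @param seed Random seed.
#'
#' @return A list of class `chip_sim` with `counts` (long tibble: `gene_id`,
#'   `mark`, `sample`, `count`), `lib_sizes`, `models`, and `truth`
#'   (`gene_id`, `modified`, `biased_to`).
#' @seealso [gene_body_rpkm()], [modification_similarity()]
#' @export
simulate_chip_counts <- function(models, bias_fraction = 0.9,
                                 modified_fraction = 0.3,
                                 mark = "H3K36me3",
                                 designated_parent = c("P1", "P2"),
                                 fold = 4,
                                 signal_rpkm_meanlog = log(5),
                                 signal_rpkm_sdlog = 0.5,
                                 background_rpkm = 0.05,
                                 dispersion = 0,
                                 lib_sizes = c(P1 = 1e7, P2 = 1e7, F1 = 1e7),
                                 seed = NULL) {
  designated_parent <- match.arg(designated_parent)
  stop_if_not_scalar_prob(bias_fraction, "bias_fraction")
  stop_if_not_scalar_prob(modified_fraction, "modified_fraction")
  stop_if_not_positive(lib_sizes, "lib_sizes")
  n <- nrow(models)
  other <- setdiff(c("P1", "P2"), designated_parent)

  with_seed(seed, {
    modified <- seq_len(n) %in% sample.int(n, round(modified_fraction * n))
    biased <- rep(NA_character_, n)
    mod_idx <- which(modified)
    biased[mod_idx] <- other
    n_biased <- round(bias_fraction * length(mod_idx))
    if (n_biased > 0) {
      biased[sample(mod_idx, n_biased)] <- designated_parent
    }

    sig <- exp(rnorm(n, signal_rpkm_meanlog, signal_rpkm_sdlog))
    rpkm <- matrix(background_rpkm, n, 3,
                   dimnames = list(models$gene_id, c("P1", "P2", "F1")))
    rpkm[modified, designated_parent] <- sig[modified]
    rpkm[modified, other] <- sig[modified] / fold
    rpkm[modified, "F1"] <- ifelse(biased[modified] == designated_parent,
                                   rpkm[modified, designated_parent],
                                   rpkm[modified, other])

    counts <- matrix(0L, n, 3L,
                     dimnames = list(models$gene_id, c("P1", "P2", "F1")))
    for (s in colnames(counts)) {
      counts[, s] <- draw_counts(
        rpkm_to_mean_count(rpkm[, s], models$length, lib_sizes[[s]]),
        dispersion)
    }
    long <- tibble::tibble(
      gene_id = rep(models$gene_id, 3L),
      mark = mark,
      sample = rep(c("P1", "P2", "F1"), each = n),
      count = as.integer(counts)
    )
    structure(list(
      counts = long, lib_sizes = lib_sizes, models = models,
      truth = tibble::tibble(gene_id = models$gene_id, modified = modified,
                             biased_to = biased)
    ), class = "chip_sim")
  })
}
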