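#' Bin genes into consecutive 500-gene length bins
#'
#' Genes are sorted by descending genomic length (ties broken by ascending
#' `gene_id` so binning is reproducible) and cut into consecutive bins of
#' exactly `bin_size` genes anchored at the *longest* genes; the trailing
#' incomplete bin of shortest genes is discarded. `bin_index` 0 is the
#' longest-gene bin.
#'
#' @param genes Annotation `data.frame` (`gene_id`, `length_bp`) restricted to
#'   the analysis universe (see [tmm_abundance_filter()]).
#' @param bin_size Genes per bin, default 500.
#' @return `data.frame` of class `length_bins` with columns `bin_index`,
#'   `mean_length_bp`, `n_total` and a list-column `gene_ids`; discarded gene
#'   ids are kept in `attr(, "discarded")`.
#' @export
bin_by_length <- function(genes, bin_size = 500) {
  stopifnot(all(c("gene_id", "length_bp") %in% names(genes)))
  n <- nrow(genes)
  if (n < bin_size) {
    stop("universe smaller than one bin (", n, " < ", bin_size, ")", call. = FALSE)
  }
  ord <- order(-genes$length_bp, genes$gene_id)
  genes <- genes[ord, ]
  n_bins <- n %/% bin_size
  used <- seq_len(n_bins * bin_size)
  bin_of <- rep(seq_len(n_bins) - 1L, each = bin_size)
  ids <- split(genes$gene_id[used], bin_of)
  mean_len <- vapply(split(genes$length_bp[used], bin_of), mean, 0.0)
  out <- data.frame(
    bin_index = seq_len(n_bins) - 1L,
    mean_length_bp = unname(mean_len),
    n_total = bin_size
  )
  out$gene_ids <- unname(ids)
  structure(out,
    discarded = genes$gene_id[-used][0L + seq_len(n - n_bins * bin_size)],
    bin_size = bin_size,
    class = c("length_bins", "data.frame")
  )
}

#' Per-bin up-regulation ratio
#'
#' For each length bin, counts direction-called genes and computes the
#' up-ratio `n_up / (n_up + n_down)`. In `all_genes` mode (the default) the
#' direction is the sign of the fold-change estimate for every gene; in
#' `deg_only` mode only significant genes are counted, which with few DEGs
#' leaves most bins undefined. Genes with `log2fc == 0` are counted in
#' neither direction. An odds variant `n_up / n_down` is available via
#' `ratio = "odds"` for plotting against the bounded default.
#'
#' @param bins A [bin_by_length()] table.
#' @param de DE table covering every binned gene.
#' @param mode `"all_genes"` or `"deg_only"`.
#' @param ratio `"fraction"` (default, bounded) or `"odds"`.
#' @return The bin table with columns `n_up`, `n_down`, `up_ratio` (`NA`
#'   when no gene in the bin has a direction) appended.
#' @export
bin_direction_ratio <- function(bins, de, mode = c("all_genes", "deg_only"),
                                ratio = c("fraction", "odds")) {
  mode <- match.arg(mode)
  ratio <- match.arg(ratio)
  all_ids <- unlist(bins$gene_ids, use.names = FALSE)
  miss <- setdiff(all_ids, de$gene_id)
  if (length(miss)) {
    stop(
      "binned gene(s) missing from the DE table: ",
      paste(utils::head(miss, 5L), collapse = ", "),
      if (length(miss) > 5L) " ..." else "",
      call. = FALSE
    )
  }
  lfc <- setNames(de$log2fc, de$gene_id)
  sig <- if ("significant" %in% names(de)) {
    setNames(de$significant, de$gene_id)
  } else {
    setNames(de$padj < 0.05, de$gene_id)
  }
  counts <- t(vapply(bins$gene_ids, function(ids) {
    v <- lfc[ids]
    if (mode == "deg_only") v <- v[sig[ids] %in% TRUE]
    c(up = sum(v > 0), down = sum(v < 0))
  }, c(up = 0, down = 0)))
  bins$n_up <- as.integer(counts[, "up"])
  bins$n_down <- as.integer(counts[, "down"])
  bins$up_ratio <- if (ratio == "fraction") {
    denom <- bins$n_up + bins$n_down
    ifelse(denom > 0, bins$n_up / denom, NA_real_)
  } else {
    ifelse(bins$n_down > 0, bins$n_up / bins$n_down, NA_real_)
  }
  bins
}

#' Regression of bin up-ratio on log10 mean length
#'
#' Ordinary least squares of the per-bin up-ratio on log10 mean bin length;
#' reports the slope, intercept, Pearson correlation, and the t test
#' `t = r * sqrt(df / (1 - r^2))` on `df = n_bins - 2` degrees of freedom.
#' Bins with undefined ratio are dropped (never imputed); a negative slope is
#' the length-dependent decline signature.
#'
#' @param bins A [bin_direction_ratio()] table.
#' @return List of class `gltd_fit`: `slope`, `intercept`, `pearson_r`,
#'   `t_stat`, `df`, `pvalue`, `n_bins`.
#' @export
length_ratio_regression <- function(bins) {
  use <- !is.na(bins$up_ratio)
  if (sum(use) < 3L) {
    stop("need at least 3 bins with a defined up-ratio", call. = FALSE)
  }
  x <- log10(bins$mean_length_bp[use])
  y <- bins$up_ratio[use]
  if (var(y) == 0 || var(x) == 0) {
    stop("degenerate regression: zero variance in ratios or lengths", call. = FALSE)
  }
  fit <- lm(y ~ x)
  r <- cor(x, y)
  df <- length(x) - 2L
  t_stat <- r * sqrt(df / (1 - r^2))
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    pearson_r = r,
    t_stat = t_stat,
    df = df,
    pvalue = 2 * pt(-abs(t_stat), df),
    n_bins = length(x)
  ), class = "gltd_fit")
}

#' @export
print.gltd_fit <- function(x, ...) {
  cat(sprintf(
    "up-ratio ~ log10(length): slope = %.4f, r = %.3f, t(%d) = %.2f, p = %.3g (%d bins)\n",
    x$slope, x$pearson_r, x$df, x$t_stat, x$pvalue, x$n_bins
  ))
  invisible(x)
}

#' Between-cohort comparison of length-ratio slopes
#'
#' Fits the bin-level model `up_ratio ~ log10(length) * cohort` against the
#' reduced `up_ratio ~ log10(length) + cohort` and reports the ANOVA F test
#' of the interaction (do the cohorts' slopes differ?), together with the
#' pooled fixed-effects fit: the common slope across cohorts and the cohort
#' main effect.
#'
#' @param bins_a,bins_b [bin_direction_ratio()] tables for the two cohorts.
#' @return List with `f_stat`, `df` (numerator, denominator), `pvalue`, and a
#'   `pooled` block (`slope`, `slope_se`, `slope_t`, `slope_df`, `slope_p`,
#'   `cohort_effect`, `cohort_p`).
#' @export
cohort_interaction_regression <- function(bins_a, bins_b) {
  take <- function(b, lab) {
    use <- !is.na(b$up_ratio)
    if (sum(use) < 3L) stop("cohort ", lab, " has fewer than 3 usable bins", call. = FALSE)
    data.frame(
      x = log10(b$mean_length_bp[use]), y = b$up_ratio[use],
      cohort = lab, stringsAsFactors = FALSE
    )
  }
  d <- rbind(take(bins_a, "A"), take(bins_b, "B"))
  d$cohort <- factor(d$cohort)
  full <- lm(y ~ x * cohort, data = d)
  reduced <- lm(y ~ x + cohort, data = d)
  if (any(!is.finite(coef(full)))) stop("degenerate design", call. = FALSE)
  an <- anova(reduced, full)
  cf <- summary(reduced)$coefficients
  structure(list(
    f_stat = an$F[2L],
    df = as.integer(c(an$Df[2L], an$Res.Df[2L])),
    pvalue = an$`Pr(>F)`[2L],
    pooled = list(
      slope = cf["x", "Estimate"],
      slope_se = cf["x", "Std. Error"],
      slope_t = cf["x", "t value"],
      slope_df = reduced$df.residual,
      slope_p = cf["x", "Pr(>|t|)"],
      cohort_effect = cf[3L, "Estimate"],
      cohort_p = cf[3L, "Pr(>|t|)"]
    )
  ), class = "gltd_interaction")
}

#' Mann-Whitney test for a length shift between up- and down-regulated DEGs
#'
#' Compares the genomic lengths of significantly up- versus down-regulated
#' genes with a Mann-Whitney U test: exact when both groups have at most 8
#' genes and no ties straddle the groups, the normal approximation with
#' continuity and tie correction otherwise. A small U (few up-regulated genes
#' longer than down-regulated ones) indicates that down-regulated genes are
#' the longer ones.
#'
#' @param de DE table with a `significant` flag (see [nb_wald_test()]).
#' @param lengths Annotation `data.frame` (`gene_id`, `length_bp`).
#' @param exact_max Largest per-group size at which the exact null is used.
#' @return List with `U`, `n_up`, `n_down`, `pvalue`, `method`.
#' @export
deg_length_shift_test <- function(de, lengths, exact_max = 8) {
  len <- setNames(lengths$length_bp, lengths$gene_id)
  sig <- de[de$significant %in% TRUE, ]
  up <- len[sig$gene_id[sig$log2fc > 0]]
  down <- len[sig$gene_id[sig$log2fc < 0]]
  up <- up[!is.na(up)]
  down <- down[!is.na(down)]
  if (!length(up) || !length(down)) {
    stop("test undefined: need at least one significant gene in each direction",
      call. = FALSE
    )
  }
  has_ties <- anyDuplicated(c(up, down)) > 0
  use_exact <- length(up) <= exact_max && length(down) <= exact_max && !has_ties
  wt <- suppressWarnings(
    wilcox.test(up, down, exact = use_exact, correct = TRUE)
  )
  list(
    U = unname(wt$statistic),
    n_up = length(up), n_down = length(down),
    pvalue = wt$p.value,
    method = if (use_exact) "exact" else "normal approximation"
  )
}

#' One-call length-decline analysis of a cohort
#'
#' The standard workflow from a raw count matrix to the length-decline fit:
#' median-of-ratios normalization, the expression filter (at least half of
#' the smallest group above 20 normalized counts by default), the NB Wald
#' test on the filtered genes, TMM abundance selection of the bin universe,
#' 500-gene binning, per-bin up-ratios, and the up-ratio-versus-length
#' regression.
#'
#' @param counts A [count_matrix()].
#' @param annotation Gene length `data.frame` (`gene_id`, `length_bp`).
#' @param min_replicates Samples per group required above `min_count`;
#'   defaults to half the smallest group (rounded up).
#' @param min_count Expression-filter threshold, default 20.
#' @param tmm_threshold Abundance cutoff (CPM) for the bin universe, default 1.
#' @param bin_size Genes per bin, default 500.
#' @param alpha FDR threshold, default 0.05.
#' @param mode Direction mode for [bin_direction_ratio()].
#' @param de Optional externally produced DE table; when supplied the
#'   internal Wald test is skipped.
#' @return List with `de`, `size_factors`, `tmm`, `universe` (bin gene ids),
#'   `bins`, `fit`.
#' @export
gltd_analysis <- function(counts, annotation, min_replicates = NULL,
                          min_count = 20, tmm_threshold = 1, bin_size = 500,
                          alpha = 0.05, mode = "all_genes", de = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  groups <- paste(counts$sample_meta$condition, counts$sample_meta$treatment,
    sep = "."
  )
  norm <- median_of_ratios(counts)
  if (is.null(min_replicates)) {
    min_replicates <- ceiling(min(table(groups)) / 2)
  }
  expressed <- expression_filter(norm$normalized, groups, min_replicates, min_count)
  if (is.null(de)) {
    de <- nb_wald_test(
      counts$counts[expressed, , drop = FALSE],
      condition = counts$sample_meta$condition,
      size_factors = norm$size_factors, alpha = alpha
    )
  }
  tmm <- tmm_factors(counts)
  abundant <- tmm_abundance_filter(counts, tmm, threshold = tmm_threshold)
  universe <- intersect(abundant, de$gene_id)
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  bins <- bin_by_length(ann, bin_size = bin_size)
  bins <- bin_direction_ratio(bins, de, mode = mode)
  fit <- length_ratio_regression(bins)
  list(
    de = de, size_factors = norm$size_factors, tmm = tmm,
    expressed = expressed, universe = universe, bins = bins, fit = fit
  )
}
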