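#' Median-of-ratios size factors and normalized counts
#'
#' The classical count-normalization used for differential expression: a
#' pseudo-reference sample is built as the per-gene geometric mean across
#' samples (genes with a zero in any sample are excluded from factor
#' estimation), each sample's size factor is the median over those genes of
#' `count / reference`, and normalized counts are `count / size_factor`.
#'
#' @param counts A [count_matrix()] or numeric count matrix.
#' @return List of class `normalization` with elements `size_factors` (named,
#'   all > 0) and `normalized` (matrix of the same shape as the input).
#' @export
median_of_ratios <- function(counts) {
  m <- .counts_of(counts)
  if (ncol(m) < 2L) stop("need at least two samples", call. = FALSE)
  keep <- rowSums(m == 0) == 0L
  if (!any(keep)) {
    stop(
      "no gene has nonzero counts in every sample; ",
      "filter low-count genes before normalizing",
      call. = FALSE
    )
  }
  ref <- exp(rowMeans(log(m[keep, , drop = FALSE])))
  sf <- apply(m[keep, , drop = FALSE], 2L, function(x) median(x / ref))
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("degenerate size factor(s); check the count matrix", call. = FALSE)
  }
  structure(
    list(size_factors = sf, normalized = sweep(m, 2L, sf, "/")),
    class = "normalization"
  )
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample scaling factors from trimmed, precision-weighted means of
#' library-size-adjusted log2 ratios (M values) against a reference sample.
#' Genes in the extreme `trim_m` tails of M and `trim_a` tails of average
#' log abundance (A) are discarded; remaining M values are combined with
#' inverse asymptotic-variance weights and the factors rescaled to geometric
#' mean one. With `reference = "auto"` the sample whose upper-quartile
#' count fraction is closest to the mean upper quartile is used.
#'
#' @param counts A [count_matrix()] or numeric count matrix.
#' @param reference Sample id, column index, or `"auto"`.
#' @param trim_m Fraction trimmed from *each* tail of the M distribution,
#'   default 0.30.
#' @param trim_a Fraction trimmed from each tail of the A distribution,
#'   default 0.05.
#' @return Named vector of TMM factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, reference = "auto", trim_m = 0.30, trim_a = 0.05) {
  m <- .counts_of(counts)
  lib <- colSums(m)
  if (any(lib == 0)) stop("sample(s) with zero library size", call. = FALSE)
  if (identical(reference, "auto")) {
    f75 <- apply(m, 2L, function(x) quantile(x / sum(x), 0.75, names = FALSE))
    ref <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(reference)) {
    ref <- match(reference, colnames(m))
    if (is.na(ref)) stop("reference sample not found: ", reference, call. = FALSE)
  } else {
    ref <- as.integer(reference)
  }
  yr <- m[, ref]
  f <- vapply(seq_len(ncol(m)), function(i) {
    if (i == ref) return(1)
    yi <- m[, i]
    pos <- yi > 0 & yr > 0
    if (!any(pos)) stop("no genes shared with the reference sample", call. = FALSE)
    pi_ <- yi[pos] / lib[i]
    pr_ <- yr[pos] / lib[ref]
    M <- log2(pi_ / pr_)
    A <- 0.5 * log2(pi_ * pr_)
    if (max(abs(M)) < 1e-6) return(1) # identical relative profiles
    # asymptotic variance of M (delta method on binomial counts)
    v <- (lib[i] - yi[pos]) / (lib[i] * yi[pos]) +
      (lib[ref] - yr[pos]) / (lib[ref] * yr[pos])
    n <- length(M)
    lo_m <- floor(n * trim_m) + 1
    lo_a <- floor(n * trim_a) + 1
    keep <- rank(M) >= lo_m & rank(M) <= n + 1 - lo_m &
      rank(A) >= lo_a & rank(A) <= n + 1 - lo_a
    if (!any(keep)) stop("all genes trimmed; lower the trim fractions", call. = FALSE)
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, 0.0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

#' Expression filter defining the analyzed gene universe
#'
#' A gene is retained iff at least one group contains `min_replicates`
#' samples with normalized counts strictly greater than `min_count`
#' (the inequality is strict: a count of exactly `min_count` does not
#' qualify). Raising either threshold can only shrink the retained set.
#'
#' @param normalized Normalized count matrix (e.g.
#'   `median_of_ratios(x)$normalized`).
#' @param groups Vector of group labels, one per column.
#' @param min_replicates Required number of qualifying samples within a group;
#'   must not exceed the smallest group.
#' @param min_count Normalized-count threshold, default 20.
#' @return Character vector of retained gene ids.
#' @export
expression_filter <- function(normalized, groups, min_replicates, min_count = 20) {
  if (length(groups) == 0L || all(is.na(groups))) {
    stop("`groups` must assign each sample to a group", call. = FALSE)
  }
  if (length(groups) != ncol(normalized)) {
    stop("`groups` must have one entry per sample column", call. = FALSE)
  }
  sizes <- table(groups)
  if (min_replicates > min(sizes)) {
    stop("min_replicates exceeds the smallest group size", call. = FALSE)
  }
  keep <- Reduce(`|`, lapply(names(sizes), function(g) {
    rowSums(normalized[, groups == g, drop = FALSE] > min_count) >= min_replicates
  }))
  rownames(normalized)[keep]
}

#' Abundance filter for the length-bin universe
#'
#' Selects the abundantly expressed genes entering the gene-length analysis:
#' those whose TMM-normalized abundance, in counts per million over the
#' TMM-adjusted effective library sizes, exceeds `threshold` — averaged over
#' samples (`aggregate = "mean"`, the default) or required in every sample
#' (`aggregate = "all"`).
#'
#' @param counts A [count_matrix()] or numeric count matrix.
#' @param factors Optional TMM factors from [tmm_factors()]; computed on the
#'   same samples when omitted.
#' @param threshold Abundance cutoff on the CPM scale, default 1.
#' @param aggregate `"mean"` or `"all"`.
#' @return Character vector of retained gene ids.
#' @export
tmm_abundance_filter <- function(counts, factors = NULL, threshold = 1,
                                 aggregate = c("mean", "all")) {
  aggregate <- match.arg(aggregate)
  m <- .counts_of(counts)
  if (is.null(factors)) factors <- tmm_factors(m)
  if (length(factors) != ncol(m)) {
    stop("`factors` must supply one value per sample", call. = FALSE)
  }
  eff_lib <- colSums(m) * factors
  cpm <- sweep(m, 2L, eff_lib / 1e6, "/")
  stat <- switch(aggregate,
    mean = rowMeans(cpm),
    all = apply(cpm, 1L, min)
  )
  rownames(m)[stat > threshold]
}
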