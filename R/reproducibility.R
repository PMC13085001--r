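#' Within- and between-cohort expression-profile correlations
#'
#' Quantifies baseline comparability of two cohorts: every within-cohort and
#' between-cohort sample pair is correlated (Pearson) on
#' `log2(normalized count + 1)` over the genes shared by both cohorts, with
#' median-of-ratios factors computed per cohort. Reports per-stratum mean and
#' sd, the percent difference between the average within- and between-cohort
#' correlation, and the shared variance `between_mean^2`.
#'
#' @param counts_a,counts_b [count_matrix()] objects for the two cohorts.
#' @param sample_filter Predicate on a metadata `data.frame` returning a
#'   logical per sample; defaults to vehicle-treated controls (the baseline
#'   stratum).
#' @param min_shared Minimum number of shared genes required, default 100.
#' @return List of class `correlation_summary` with `within_a_mean/sd`,
#'   `within_b_mean/sd`, `between_mean/sd`, `pct_difference`,
#'   `shared_variance`, `n_genes`.
#' @export
profile_correlations <- function(counts_a, counts_b,
                                 sample_filter = function(meta) {
                                   meta$condition == "control" &
                                     meta$treatment == "vehicle"
                                 },
                                 min_shared = 100L) {
  prep <- function(x) {
    stopifnot(inherits(x, "count_matrix"))
    keep <- sample_filter(x$sample_meta)
    if (sum(keep) < 2L) {
      stop("need at least 2 samples per cohort after filtering", call. = FALSE)
    }
    norm <- median_of_ratios(x)$normalized
    log2(norm[, keep, drop = FALSE] + 1)
  }
  la <- prep(counts_a)
  lb <- prep(counts_b)
  shared <- intersect(rownames(la), rownames(lb))
  if (!length(shared)) stop("cohorts share no genes", call. = FALSE)
  if (length(shared) < min_shared) {
    stop("fewer than ", min_shared, " shared genes (", length(shared), ")",
      call. = FALSE
    )
  }
  la <- la[shared, , drop = FALSE]
  lb <- lb[shared, , drop = FALSE]
  pair_cors <- function(m) {
    cm <- cor(m)
    cm[upper.tri(cm)]
  }
  within_a <- pair_cors(la)
  within_b <- pair_cors(lb)
  between <- as.vector(cor(la, lb))
  within_all <- c(within_a, within_b)
  structure(list(
    within_a_mean = mean(within_a), within_a_sd = sd(within_a),
    within_b_mean = mean(within_b), within_b_sd = sd(within_b),
    between_mean = mean(between), between_sd = sd(between),
    pct_difference = (mean(within_all) - mean(between)) / mean(within_all) * 100,
    shared_variance = mean(between)^2,
    n_genes = length(shared)
  ), class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "within A: r = %.3f +/- %.3f; within B: r = %.3f +/- %.3f\n",
      "between:  r = %.3f +/- %.3f (%.1f%% below within; %.0f%% shared variance)\n"
    ),
    x$within_a_mean, x$within_a_sd, x$within_b_mean, x$within_b_sd,
    x$between_mean, x$between_sd, x$pct_difference, 100 * x$shared_variance
  ))
  invisible(x)
}

#' Cross-cohort directionality consistency of fold changes
#'
#' Fraction of selected genes whose fold-change signs agree between two
#' cohorts, with an exact two-sided binomial test against chance (0.5).
#' Selection is either the significant genes of the reference cohort
#' (`"degs_of_a"`, the default) or all shared genes. Genes with a zero fold
#' change in either table carry no sign; they are excluded and counted.
#'
#' @param de_a,de_b DE tables; `de_a` is the reference cohort.
#' @param selection `"degs_of_a"` or `"all_shared"`.
#' @return List with `fraction`, `n_consistent`, `n_total`,
#'   `n_zero_excluded`, `pvalue`.
#' @export
directionality_consistency <- function(de_a, de_b,
                                       selection = c("degs_of_a", "all_shared")) {
  selection <- match.arg(selection)
  shared <- intersect(de_a$gene_id, de_b$gene_id)
  if (!length(shared)) stop("DE tables share no genes", call. = FALSE)
  if (selection == "degs_of_a") {
    degs <- de_a$gene_id[de_a$significant %in% TRUE]
    if (!length(degs)) {
      stop("reference cohort has no significant genes", call. = FALSE)
    }
    shared <- intersect(shared, degs)
  }
  sa <- sign(de_a$log2fc[match(shared, de_a$gene_id)])
  sb <- sign(de_b$log2fc[match(shared, de_b$gene_id)])
  nonzero <- sa != 0 & sb != 0
  n_zero <- sum(!nonzero)
  if (!any(nonzero)) {
    stop("all selected genes have a zero fold change in one of the tables",
      call. = FALSE
    )
  }
  agree <- sa[nonzero] == sb[nonzero]
  bt <- binom.test(sum(agree), length(agree), p = 0.5)
  list(
    fraction = mean(agree),
    n_consistent = sum(agree),
    n_total = length(agree),
    n_zero_excluded = n_zero,
    pvalue = bt$p.value
  )
}

#' Overlap (Venn) analysis of DEG sets
#'
#' Counts every region of the inclusion-exclusion partition over two or more
#' named gene sets. When `pooled` names one of the sets (a pooled-cohort DEG
#' list), the genes significant in some per-cohort set but absent from the
#' pooled set are additionally reported as "lost by pooling".
#'
#' @param deg_sets Named list (>= 2) of gene-id character vectors.
#' @param pooled Optional name of the pooled set within `deg_sets`.
#' @return `data.frame` with one row per non-empty membership pattern:
#'   `region` (set names joined by `&`), `count`, and a list-column `genes`;
#'   genes lost by pooling are in `attr(, "lost_by_pooling")`.
#' @export
overlap_analysis <- function(deg_sets, pooled = NULL) {
  if (length(deg_sets) < 2L) stop("need at least two named sets", call. = FALSE)
  if (is.null(names(deg_sets)) || any(!nzchar(names(deg_sets)))) {
    stop("all sets must be named", call. = FALSE)
  }
  universe <- sort(unique(unlist(deg_sets, use.names = FALSE)))
  membership <- vapply(deg_sets, function(s) universe %in% s,
    logical(length(universe))
  )
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern <- apply(membership, 1L, function(row) {
    paste(names(deg_sets)[row], collapse = "&")
  })
  regions <- split(universe, pattern)
  out <- data.frame(
    region = names(regions),
    count = lengths(regions),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$genes <- unname(regions)
  if (!is.null(pooled)) {
    if (!pooled %in% names(deg_sets)) {
      stop("`pooled` must name one of the sets", call. = FALSE)
    }
    per_cohort <- unlist(deg_sets[setdiff(names(deg_sets), pooled)],
      use.names = FALSE
    )
    attr(out, "lost_by_pooling") <- sort(setdiff(per_cohort, deg_sets[[pooled]]))
  }
  out
}
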