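#' Two-group negative-binomial Wald test
#'
#' A transparent per-gene differential-expression caller for two groups: an
#' explicit surrogate for heavier DE machinery, with no cross-gene dispersion
#' shrinkage, no outlier replacement and no independent filtering, so its
#' behaviour is fully determined by the formulas below. External DE tables
#' (via [read_de_table()]) are first-class alternatives everywhere downstream.
#'
#' Per gene, on the normalized scale: group means `m_t`, `m_c`; a
#' method-of-moments NB dispersion pooled across the two groups (floored at
#' `dispersion_floor`); `log2fc = log2((m_t + pc) / (m_c + pc))` with
#' pseudo-count `pc`; a delta-method standard error from the NB variances
#' `mu/s + alpha mu^2`; a two-sided normal Wald p; and Benjamini-Hochberg
#' adjusted p across genes.
#'
#' @param counts A [count_matrix()] or numeric count matrix (pre-filtered
#'   with [expression_filter()] in a standard workflow).
#' @param condition Group label per sample; defaults to the metadata
#'   `condition` column when `counts` is a [count_matrix()].
#' @param contrast Length-2 character vector `(treatment_level,
#'   control_level)`; `log2fc` is treatment over control. Defaults to
#'   `c("ELS", "control")` when both are present, otherwise the two levels in
#'   reverse order of appearance.
#' @param size_factors Optional per-sample size factors; computed with
#'   [median_of_ratios()] when omitted.
#' @param alpha FDR threshold for the `significant` flag, default 0.05.
#' @param pseudo_count Fold-change stabilizer `pc`, default 0.5.
#' @param dispersion_floor Lower bound for the dispersion estimate.
#' @return `data.frame` with columns `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `pvalue`, `padj`, `significant`.
#' @export
nb_wald_test <- function(counts, condition = NULL, contrast = NULL,
                         size_factors = NULL, alpha = 0.05,
                         pseudo_count = 0.5, dispersion_floor = 1e-8) {
  m <- .counts_of(counts)
  if (is.null(condition) && inherits(counts, "count_matrix")) {
    condition <- counts$sample_meta$condition
  }
  if (is.null(condition)) stop("`condition` is required for bare matrices", call. = FALSE)
  if (length(condition) != ncol(m)) {
    stop("`condition` must have one entry per sample", call. = FALSE)
  }
  if (is.null(contrast)) {
    lev <- unique(condition)
    contrast <- if (all(c("ELS", "control") %in% lev)) {
      c("ELS", "control")
    } else {
      rev(lev[1:2])
    }
  }
  idx_t <- which(condition == contrast[1L])
  idx_c <- which(condition == contrast[2L])
  if (length(idx_t) < 2L || length(idx_c) < 2L) {
    stop("each contrast group needs at least 2 samples for a dispersion estimate",
      call. = FALSE
    )
  }
  if (is.null(size_factors)) {
    size_factors <- median_of_ratios(m[, c(idx_t, idx_c), drop = FALSE])$size_factors
    size_factors <- setNames(
      size_factors[match(colnames(m)[c(idx_t, idx_c)], names(size_factors))],
      colnames(m)[c(idx_t, idx_c)]
    )
    sf <- rep(NA_real_, ncol(m))
    sf[c(idx_t, idx_c)] <- size_factors
  } else {
    if (length(size_factors) != ncol(m)) {
      stop("`size_factors` must supply one value per sample", call. = FALSE)
    }
    sf <- size_factors
  }
  nm <- sweep(m, 2L, sf, "/")
  nt <- length(idx_t)
  nc <- length(idx_c)
  mt <- rowMeans(nm[, idx_t, drop = FALSE])
  mc <- rowMeans(nm[, idx_c, drop = FALSE])
  vt <- .row_vars(nm[, idx_t, drop = FALSE])
  vc <- .row_vars(nm[, idx_c, drop = FALSE])
  # expected Poisson component of Var(count/s) is mu * mean(1/s) within a group
  ht <- mean(1 / sf[idx_t])
  hc <- mean(1 / sf[idx_c])
  at <- (vt - mt * ht) / mt^2
  ac <- (vc - mc * hc) / mc^2
  at[!is.finite(at)] <- 0
  ac[!is.finite(ac)] <- 0
  disp <- pmax(((nt - 1) * at + (nc - 1) * ac) / (nt + nc - 2), dispersion_floor)
  var_mt <- (mt * ht + disp * mt^2) / nt
  var_mc <- (mc * hc + disp * mc^2) / nc
  pc <- pseudo_count
  lfc <- log2((mt + pc) / (mc + pc))
  se <- sqrt(var_mt / (mt + pc)^2 + var_mc / (mc + pc)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  pvalue <- 2 * pnorm(-abs(z))
  padj <- bh_adjust(pvalue)
  data.frame(
    gene_id = rownames(m),
    base_mean = rowMeans(nm[, c(idx_t, idx_c), drop = FALSE]),
    log2fc = lfc, se = se, pvalue = pvalue, padj = padj,
    significant = padj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that the inputs are probabilities and applies the standard
#' step-up FDR adjustment (sort ascending, multiply by `n/rank`, enforce
#' monotonicity from the largest rank down, cap at 1, restore order).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  .assert_probabilities(pvalues, "pvalues")
  p.adjust(pvalues, method = "BH")
}

#' Condition-by-treatment interaction as a contrast of contrasts
#'
#' Tests, per gene, whether the ELS effect differs between treatment arms:
#' `delta = log2fc_ru486 - log2fc_vehicle`, `se = sqrt(se1^2 + se2^2)`,
#' two-sided normal Wald p, BH adjustment.
#'
#' @param de_vehicle,de_ru486 DE tables (with `se`) over the same gene
#'   universe: the ELS-vs-control contrast within each treatment arm.
#' @param alpha FDR threshold for the `significant` flag.
#' @return `data.frame` with `gene_id`, `delta_log2fc`, `se`, `pvalue`,
#'   `padj`, `significant`.
#' @export
interaction_contrast <- function(de_vehicle, de_ru486, alpha = 0.05) {
  for (nm in c("se")) {
    if (!nm %in% names(de_vehicle) || !nm %in% names(de_ru486)) {
      stop("both DE tables must carry an `se` column", call. = FALSE)
    }
  }
  if (!setequal(de_vehicle$gene_id, de_ru486$gene_id)) {
    stop("DE tables cover different gene universes", call. = FALSE)
  }
  de_ru486 <- de_ru486[match(de_vehicle$gene_id, de_ru486$gene_id), ]
  delta <- de_ru486$log2fc - de_vehicle$log2fc
  se <- sqrt(de_vehicle$se^2 + de_ru486$se^2)
  z <- ifelse(se > 0, delta / se, 0)
  pvalue <- 2 * pnorm(-abs(z))
  padj <- bh_adjust(pvalue)
  data.frame(
    gene_id = de_vehicle$gene_id, delta_log2fc = delta, se = se,
    pvalue = pvalue, padj = padj, significant = padj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Fixed-effect per-gene meta-analysis across cohorts
#'
#' Combines per-cohort effect estimates two ways: inverse-variance weighting
#' (`beta_iv = sum(beta/se^2) / sum(1/se^2)`, `se_iv = 1/sqrt(sum(1/se^2))`)
#' and equal weighting (arithmetic mean of the betas with
#' `se_eq = sqrt(sum(se^2))/k`), each with a two-sided normal p. Only genes
#' present in every cohort table are combined.
#'
#' @param tables Named list (>= 2) of `data.frame`s with columns `gene_id`,
#'   `log2fc` (or `delta_log2fc`) and `se`.
#' @return `data.frame` with `gene_id`, `beta_iv`, `se_iv`, `p_iv`,
#'   `beta_eq`, `se_eq`, `p_eq`.
#' @export
meta_analyze <- function(tables) {
  if (length(tables) < 2L) stop("need at least two cohorts", call. = FALSE)
  get_beta <- function(t) {
    if ("log2fc" %in% names(t)) t$log2fc else if ("delta_log2fc" %in% names(t)) {
      t$delta_log2fc
    } else {
      stop("each table needs a log2fc or delta_log2fc column", call. = FALSE)
    }
  }
  genes <- Reduce(intersect, lapply(tables, `[[`, "gene_id"))
  if (!length(genes)) stop("no genes shared across all cohorts", call. = FALSE)
  B <- vapply(tables, function(t) get_beta(t)[match(genes, t$gene_id)],
    numeric(length(genes))
  )
  S <- vapply(tables, function(t) t$se[match(genes, t$gene_id)],
    numeric(length(genes))
  )
  if (any(!is.finite(S)) || any(S <= 0)) {
    stop("standard errors must be positive and finite", call. = FALSE)
  }
  k <- ncol(B)
  w <- 1 / S^2
  beta_iv <- rowSums(B * w) / rowSums(w)
  se_iv <- 1 / sqrt(rowSums(w))
  beta_eq <- rowMeans(B)
  se_eq <- sqrt(rowSums(S^2)) / k
  data.frame(
    gene_id = genes,
    beta_iv = beta_iv, se_iv = se_iv,
    p_iv = 2 * pnorm(-abs(beta_iv / se_iv)),
    beta_eq = beta_eq, se_eq = se_eq,
    p_eq = 2 * pnorm(-abs(beta_eq / se_eq)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
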