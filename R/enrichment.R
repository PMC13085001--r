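#' Pi-value: significance-weighted fold change
#'
#' The ranking score combining effect direction and significance:
#' `log2fc * -log10(padj)`. Adjusted p-values of exactly 0 (common in
#' exported DE tables) are clamped to `floor` before taking the log; values
#' above 1 or at/below 0 with clamping disabled are an error.
#'
#' @param log2fc Fold-change estimate(s).
#' @param padj BH-adjusted p-value(s) in (0, 1\].
#' @param floor Clamp applied to `padj` of 0, default 1e-300. Set `NULL` to
#'   disable clamping (zeros then raise an error).
#' @return Numeric vector; the sign equals the sign of `log2fc`.
#' @export
pi_value <- function(log2fc, padj, floor = 1e-300) {
  if (any(padj > 1, na.rm = TRUE)) stop("padj above 1", call. = FALSE)
  if (is.null(floor)) {
    if (any(padj <= 0, na.rm = TRUE)) {
      stop("padj must be > 0 when clamping is disabled", call. = FALSE)
    }
  } else {
    padj <- pmax(padj, floor)
  }
  log2fc * (-log10(padj))
}

#' Rank genes by pi-value
#'
#' Ranks every gene in a DE table by descending pi-value (rank 1 = largest),
#' with ties broken by ascending `gene_id` so the ranking is deterministic
#' under any input order.
#'
#' @param de DE table with `gene_id`, `log2fc`, `padj`.
#' @param floor Passed to [pi_value()].
#' @return `data.frame` of class `ranked_list` with columns `gene_id`,
#'   `pi_value`, `rank`, sorted by rank.
#' @export
rank_genes <- function(de, floor = 1e-300) {
  if (anyDuplicated(de$gene_id)) {
    stop("duplicate gene_id in DE table", call. = FALSE)
  }
  score <- pi_value(de$log2fc, de$padj, floor = floor)
  ord <- order(-score, de$gene_id)
  structure(
    data.frame(
      gene_id = de$gene_id[ord], pi_value = score[ord],
      rank = seq_along(ord), stringsAsFactors = FALSE
    ),
    class = c("ranked_list", "data.frame")
  )
}

# scores: named vector sorted by descending score (ties by id)
.as_ranked_scores <- function(ranked) {
  if (inherits(ranked, "ranked_list") || is.data.frame(ranked)) {
    setNames(ranked$pi_value, ranked$gene_id)
  } else if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked[order(-ranked, names(ranked))]
  } else {
    stop("`ranked` must be a ranked_list or a named numeric vector", call. = FALSE)
  }
}

#' Weighted Kolmogorov-Smirnov enrichment score with running-sum profile
#'
#' Walks the ranked list: set members ("hits") increment the running sum by
#' `|score|^weight_exponent / sum over hits`, non-members decrement by
#' `1 / (N - N_hits)`. The enrichment score is the running-sum value of
#' maximum absolute deviation, signed. `weight_exponent = 0` recovers the
#' classic unweighted KS statistic.
#'
#' @param ranked A [rank_genes()] table or named numeric score vector.
#' @param gene_set Character vector of member gene ids; must intersect the
#'   ranked universe and must not cover it entirely.
#' @param weight_exponent Hit-weight exponent, default 1.
#' @return List with `es`, `running` (length-N profile), `hit_positions`,
#'   `extremum_position`, `leading_edge` (hit ids at or before the extremum).
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  scores <- .as_ranked_scores(ranked)
  n <- length(scores)
  hit <- names(scores) %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop("gene set does not intersect the ranked universe", call. = FALSE)
  if (nh == n) stop("gene set covers the entire ranked universe", call. = FALSE)
  w <- abs(scores[hit])^weight_exponent
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else rep(1 / nh, nh)
  step <- numeric(n)
  step[hit] <- inc
  step[!hit] <- -1 / (n - nh)
  running <- cumsum(step)
  ext <- which.max(abs(running))
  es <- running[ext]
  pos <- which(hit)
  list(
    es = es, running = running, hit_positions = pos,
    extremum_position = ext,
    leading_edge = names(scores)[pos[pos <= ext]]
  )
}

# Enrichment score from sorted hit positions only, O(k): the running sum is
# piecewise linear between hits, so its extrema sit just after or just before
# a hit. Used for the permutation null.
.es_from_positions <- function(pos, abs_w, n) {
  k <- length(pos)
  w <- abs_w[pos]
  sw <- sum(w)
  cw <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k
  mr <- 1 / (n - k)
  drop_ <- (pos - seq_len(k)) * mr
  after <- cw - drop_
  before <- c(0, cw[-k]) - drop_
  cand <- c(after, before)
  unname(cand[which.max(abs(cand))])
}

#' Permutation gene-set enrichment analysis over a pi-ranked list
#'
#' For each set (filtered to a size within `[min_size, max_size]` after
#' intersection with the ranked universe) the observed enrichment score is
#' compared against a gene-label permutation null: `n_perm` random same-size
#' subsets of the universe. The permutation p is one-tailed within the sign
#' of the observed score with the plus-one convention,
#' `p = (1 + #\{|ES_perm| >= |ES|, same sign\}) / (1 + #\{same-sign perms\})`,
#' the normalized score is `ES / mean(|ES_perm| same sign)`, and BH
#' adjustment runs across the retained sets. Gene-label (not sample)
#' permutation is used so the analysis applies equally to externally supplied
#' DE tables without per-sample data.
#'
#' @param ranked A [rank_genes()] table or named score vector.
#' @param sets A `gene_set_collection` (named list of gene-id vectors).
#' @param n_perm Number of permutations, >= 100; default 10000.
#' @param min_size,max_size Retained set-size range (after intersection),
#'   defaults 1 and 5000.
#' @param weight_exponent Hit-weight exponent, default 1.
#' @param seed Integer seed for the permutation stream.
#' @return `data.frame` with `set_name`, `set_size_used`, `es`, `nes`,
#'   `pvalue`, `padj` and a list-column `leading_edge`.
#' @export
gsea <- function(ranked, sets, n_perm = 10000, min_size = 1, max_size = 5000,
                 weight_exponent = 1, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  scores <- .as_ranked_scores(ranked)
  n <- length(scores)
  abs_w <- abs(scores)^weight_exponent
  sizes <- vapply(sets, function(s) sum(names(scores) %in% s), 0L)
  empty <- names(sets)[sizes == 0L]
  if (length(empty)) {
    warning("skipping set(s) with no genes in the ranked universe: ",
      paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(sizes == n)) {
    stop("set(s) covering the whole universe: ",
      paste(names(sets)[sizes == n], collapse = ", "),
      call. = FALSE
    )
  }
  retain <- sizes >= max(min_size, 1L) & sizes <= max_size & sizes < n
  if (!any(retain)) stop("no gene sets retained after size filtering", call. = FALSE)
  sets <- sets[retain]
  sizes <- sizes[retain]
  rows <- with_seed(substream_seed(seed, "gsea"), {
    lapply(seq_along(sets), function(i) {
      obs <- enrichment_score(scores, sets[[i]], weight_exponent)
      k <- sizes[[i]]
      es_null <- vapply(seq_len(n_perm), function(p) {
        .es_from_positions(sort(sample.int(n, k)), abs_w, n)
      }, 0.0)
      if (obs$es == 0) {
        p <- 1
        nes <- 0
      } else {
        same <- es_null[sign(es_null) == sign(obs$es)]
        p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
        nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
      }
      list(
        set_name = names(sets)[[i]], set_size_used = k,
        es = obs$es, nes = nes, pvalue = p,
        leading_edge = obs$leading_edge
      )
    })
  })
  out <- data.frame(
    set_name = vapply(rows, `[[`, "", "set_name"),
    set_size_used = vapply(rows, `[[`, 0L, "set_size_used"),
    es = vapply(rows, `[[`, 0.0, "es"),
    nes = vapply(rows, `[[`, 0.0, "nes"),
    pvalue = vapply(rows, `[[`, 0.0, "pvalue"),
    stringsAsFactors = FALSE
  )
  out$padj <- bh_adjust(out$pvalue)
  out$leading_edge <- lapply(rows, `[[`, "leading_edge")
  out
}

#' Write a GSEA result table as TSV
#'
#' @param res A [gsea()] result.
#' @param path Output TSV; the leading edge is comma-joined.
#' @export
write_enrichment <- function(res, path) {
  out <- res
  out$leading_edge <- vapply(res$leading_edge, paste, "", collapse = ",")
  write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(res)
}
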