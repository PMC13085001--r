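# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user streams.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.stage_offsets <- c(
  universe = 101L, effects = 211L, counts = 307L, sets = 401L,
  gsea = 503L, study = 601L, pipeline = 701L, cohort = 809L
)

#' Derive a per-stage random seed from one master seed
#'
#' One master integer seed drives every stochastic stage of the package. Each
#' stage draws from its own substream whose seed is an affine function of the
#' master seed and a fixed per-stage offset, so stages are decoupled: changing
#' the number of draws in one stage never perturbs another, and any stage can
#' be replayed in isolation.
#'
#' The scheme is `(seed mod 1e6) * 1009 + offset + 7919 * index`, which stays
#' below 2^31 for all stage offsets and small indices.
#'
#' @param seed Master integer seed.
#' @param stage One of `"universe"`, `"effects"`, `"counts"`, `"sets"`,
#'   `"gsea"`, `"study"`, `"pipeline"`, `"cohort"`.
#' @param index Optional non-negative integer distinguishing repeated uses of
#'   the same stage (e.g. multiple cohorts), default 0.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage, index = 0L) {
  stage <- match.arg(stage, names(.stage_offsets))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  base <- (as.integer(seed) %% 1000000L) * 1009L
  as.integer(base + .stage_offsets[[stage]] + 7919L * as.integer(index))
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "`%s` must be in %s%s, %s%s (got %g)", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ), call. = FALSE)
  }
  invisible(x)
}

.assert_probabilities <- function(p, name) {
  if (!is.numeric(p)) stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad)) {
    stop(sprintf(
      "`%s` must lie in [0, 1]; offending positions: %s", name,
      paste(utils::head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(p)
}

# row-wise variance of a numeric matrix (n - 1 denominator), no copies per row
.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) stop("need at least two columns to compute row variances", call. = FALSE)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
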