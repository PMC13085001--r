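#' Simulation configuration for a synthetic ELS-style cohort
#'
#' Bundles the generator parameters that define a simulated two-group bulk
#' RNA-seq experiment. The defaults are the package's reference study
#' conditions: an expressed-gene universe of 12,000 genes, 6 biological
#' replicates per group, a pervasive weak transcriptional response
#' (`de_fraction = 0.35` of genes affected, exponential \eqn{|log2FC|} with
#' mean `effect_scale = 0.2`), and a length-dependent direction bias of
#' `gltd_slope = 1` (change in log-odds of "up" per unit log10 length, sign
#' convention such that positive slopes favour up-regulation of *short*
#' genes). Dispersion follows a Gamma(4, 80) prior (mean 0.05, typical for
#' isogenic mouse bulk RNA-seq) and library-size factors are lognormal with
#' sdlog 0.15.
#'
#' @param n_genes Number of expressed genes.
#' @param n_per_group Biological replicates per group.
#' @param de_fraction Probability that a gene carries a true effect, in (0,1).
#' @param gltd_slope Length bias \eqn{\beta}: for affected genes,
#'   \eqn{P(up \mid L) = logistic(-\beta (log10 L - \overline{log10 L}))}.
#' @param effect_scale Mean of the exponential \eqn{|log2FC|} of affected genes.
#' @param dispersion_params Length-2 vector `(shape, rate)` of the gamma
#'   dispersion prior.
#' @param libsize_params Length-2 vector `(meanlog, sdlog)` of the lognormal
#'   library-size factors.
#' @param seed Master integer seed; stage substreams are derived via
#'   [substream_seed()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 12000, n_per_group = 6, de_fraction = 0.35,
                       gltd_slope = 1.0, effect_scale = 0.2,
                       dispersion_params = c(shape = 4, rate = 80),
                       libsize_params = c(meanlog = 0, sdlog = 0.15),
                       seed = 1L) {
  .assert_scalar_number(n_genes, "n_genes", lower = 2)
  .assert_scalar_number(n_per_group, "n_per_group", lower = 2)
  .assert_scalar_number(de_fraction, "de_fraction",
    lower = 0, upper = 1,
    strict_lower = TRUE, strict_upper = TRUE
  )
  .assert_scalar_number(gltd_slope, "gltd_slope")
  .assert_scalar_number(effect_scale, "effect_scale", lower = 0, strict_lower = TRUE)
  stopifnot(
    length(dispersion_params) == 2L, all(dispersion_params > 0),
    length(libsize_params) == 2L, libsize_params[2L] >= 0
  )
  structure(list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    de_fraction = de_fraction, gltd_slope = gltd_slope,
    effect_scale = effect_scale,
    dispersion_params = unname(dispersion_params),
    libsize_params = unname(libsize_params),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic expressed-gene universe
#'
#' Draws per-gene genomic lengths, baseline abundances, and negative-binomial
#' dispersions. Lengths are lognormal on the log10 scale (default mean 4.3,
#' sd 0.6, i.e. a 20 kb median), clipped to \[10^2.5, 10^6.5\] bp — a shape
#' that mimics mouse protein-coding genomic spans. Baseline means are
#' lognormal (default median 200 counts, as in deep poly(A) libraries) and
#' dispersions follow a gamma prior; length and abundance are generated
#' independently.
#'
#' @param n_genes Number of genes (>= 2).
#' @param seed Integer seed; output is byte-identical across runs with the
#'   same arguments.
#' @param length_log10_mean,length_log10_sd Mean and sd of log10 length.
#' @param base_mean_meanlog,base_mean_sdlog Lognormal parameters of the
#'   baseline expected count.
#' @param dispersion_shape,dispersion_rate Gamma prior on the NB dispersion
#'   \eqn{\alpha} (variance \eqn{\mu + \alpha \mu^2}).
#' @return `data.frame` of class `gene_universe` with columns `gene_id`,
#'   `length_bp`, `base_mean`, `dispersion`.
#' @export
generate_gene_universe <- function(n_genes, seed,
                                   length_log10_mean = 4.3,
                                   length_log10_sd = 0.6,
                                   base_mean_meanlog = log(200),
                                   base_mean_sdlog = 1.5,
                                   dispersion_shape = 4,
                                   dispersion_rate = 80) {
  .assert_scalar_number(n_genes, "n_genes", lower = 2)
  .assert_scalar_number(length_log10_sd, "length_log10_sd", lower = 0)
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    l10 <- rnorm(n_genes, length_log10_mean, length_log10_sd)
    l10 <- pmin(pmax(l10, 2.5), 6.5)
    length_bp <- pmax(1L, as.integer(round(10^l10)))
    base_mean <- rlnorm(n_genes, base_mean_meanlog, base_mean_sdlog)
    dispersion <- rgamma(n_genes, shape = dispersion_shape, rate = dispersion_rate)
    structure(
      data.frame(
        gene_id = sprintf("g%05d", seq_len(n_genes)),
        length_bp = length_bp, base_mean = base_mean, dispersion = dispersion,
        stringsAsFactors = FALSE
      ),
      class = c("gene_universe", "data.frame")
    )
  })
}

#' Assign ground-truth differential-expression effects
#'
#' Each gene is independently affected with probability `de_fraction`. For
#' affected genes the direction is drawn from a logistic model in centred
#' log10 length, `P(up | L) = plogis(-beta * (log10 L - mean log10 L))`, so a
#' positive `gltd_slope` beta makes short genes preferentially up-regulated
#' and long genes preferentially down-regulated — the mechanism that produces
#' a gene-length-dependent decline downstream. Effect magnitudes are
#' exponential with mean `effect_scale`, independent of length, so any
#' length trend in \eqn{|log2FC|} is attributable to the analysis, not the
#' generator.
#'
#' @param universe A [generate_gene_universe()] table.
#' @param config A [sim_config()]; uses the `effects` substream of
#'   `config$seed`.
#' @return `data.frame` with columns `gene_id`, `true_log2fc`, `is_de`,
#'   `direction` (`"up"`, `"down"`, `"null"`).
#' @export
assign_true_effects <- function(universe, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(universe)) stop("`universe` is empty", call. = FALSE)
  n <- nrow(universe)
  with_seed(substream_seed(config$seed, "effects"), {
    is_de <- runif(n) < config$de_fraction
    x <- log10(universe$length_bp) - mean(log10(universe$length_bp))
    eta <- -config$gltd_slope * x
    eta[x == 0] <- 0 # guard Inf * 0 in the beta -> Inf limit
    p_up <- plogis(eta)
    up <- runif(n) < p_up
    mag <- rexp(n, rate = 1 / config$effect_scale)
    lfc <- ifelse(is_de, ifelse(up, mag, -mag), 0)
    data.frame(
      gene_id = universe$gene_id,
      true_log2fc = lfc,
      is_de = is_de,
      direction = ifelse(!is_de, "null", ifelse(lfc > 0, "up", "down")),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate negative-binomial counts for a two-group design
#'
#' Counts are NB with mean `s_j * base_mean * 2^(true_log2fc * x_j)` where
#' `x_j` indicates ELS samples and `s_j` is a lognormal library-size factor;
#' the NB size is `1/dispersion` (dispersions below 1e-12 fall back to the
#' Poisson limit). Samples are laid out control first, then ELS, all
#' vehicle-treated.
#'
#' @param universe A [generate_gene_universe()] table.
#' @param effects Matching [assign_true_effects()] table.
#' @param config A [sim_config()]; uses the `counts` substream.
#' @param cohort Cohort label written into the sample metadata.
#' @return A [count_matrix()].
#' @export
simulate_counts <- function(universe, effects, config, cohort = "cohort1") {
  stopifnot(inherits(config, "sim_config"))
  if (!setequal(universe$gene_id, effects$gene_id)) {
    stop("`effects` must cover exactly the genes in `universe`", call. = FALSE)
  }
  effects <- effects[match(universe$gene_id, effects$gene_id), ]
  n <- nrow(universe)
  npg <- config$n_per_group
  ns <- 2L * npg
  with_seed(substream_seed(config$seed, "counts"), {
    s <- rlnorm(ns, config$libsize_params[1L], config$libsize_params[2L])
    x <- rep(c(0, 1), each = npg)
    mu <- (universe$base_mean * 2^(effects$true_log2fc %o% x)) *
      rep(s, each = n)
    size <- 1 / pmax(universe$dispersion, 1e-12)
    cts <- matrix(
      rnbinom(n * ns, mu = as.vector(mu), size = rep(size, ns)),
      nrow = n
    )
    sample_id <- c(
      sprintf("%s_ctrl_%02d", cohort, seq_len(npg)),
      sprintf("%s_els_%02d", cohort, seq_len(npg))
    )
    dimnames(cts) <- list(universe$gene_id, sample_id)
    meta <- data.frame(
      sample_id = sample_id,
      cohort = cohort,
      condition = rep(c("control", "ELS"), each = npg),
      treatment = "vehicle",
      stringsAsFactors = FALSE
    )
    count_matrix(cts, meta)
  })
}

#' Generate synthetic gene-set collections with known enrichment
#'
#' Stands in for curated aging-signature collections: `n_enriched` sets
#' sample members with weight proportional to `exp(enrichment_bias *
#' true_log2fc)` (so they concentrate genes moving in the positive direction
#' when the bias is positive), the remaining sets sample uniformly and act as
#' calibrated nulls.
#'
#' @param universe A [generate_gene_universe()] table.
#' @param effects Matching [assign_true_effects()] table.
#' @param n_sets Total number of sets.
#' @param n_enriched Number of biased sets (<= `n_sets`).
#' @param set_size Members per set (<= number of genes).
#' @param enrichment_bias Selection weight exponent; 0 makes every set null.
#' @param seed Integer seed (its `sets` substream is used).
#' @return A `gene_set_collection` (as from [read_gmt()]); enriched sets are
#'   named `aging_sig_*`, null sets `null_sig_*`.
#' @export
generate_gene_sets <- function(universe, effects, n_sets, n_enriched,
                               set_size, enrichment_bias, seed) {
  if (n_enriched > n_sets) stop("n_enriched must be <= n_sets", call. = FALSE)
  if (set_size > nrow(universe)) {
    stop("set_size exceeds the universe size", call. = FALSE)
  }
  effects <- effects[match(universe$gene_id, effects$gene_id), ]
  with_seed(substream_seed(seed, "sets"), {
    w <- exp(enrichment_bias * effects$true_log2fc)
    sets <- lapply(seq_len(n_sets), function(i) {
      if (i <= n_enriched) {
        sample(universe$gene_id, set_size, prob = w)
      } else {
        sample(universe$gene_id, set_size)
      }
    })
    names(sets) <- c(
      sprintf("aging_sig_%02d", seq_len(n_enriched)),
      sprintf("null_sig_%02d", seq_len(n_sets - n_enriched))
    )[seq_len(n_sets)]
    structure(sets,
      description = setNames(ifelse(seq_len(n_sets) <= n_enriched,
        "biased toward true effects", "uniform null set"
      ), names(sets)),
      class = "gene_set_collection"
    )
  })
}

#' Simulate a complete cohort (universe, truth, counts)
#'
#' Convenience composition of [generate_gene_universe()],
#' [assign_true_effects()] and [simulate_counts()] under one configuration.
#'
#' @param config A [sim_config()].
#' @param cohort Cohort label.
#' @param universe Optional pre-built universe shared across cohorts; when
#'   supplied, only effects and counts are drawn (from substreams offset by
#'   `cohort_index`).
#' @param cohort_index Integer distinguishing cohorts sharing one master seed.
#' @return List with elements `universe`, `effects`, `counts`, `annotation`
#'   (gene_id/length_bp) and `config`.
#' @export
simulate_cohort <- function(config, cohort = "cohort1", universe = NULL,
                            cohort_index = 0L) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$seed <- substream_seed(config$seed, "cohort", index = cohort_index)
  if (is.null(universe)) {
    universe <- generate_gene_universe(cfg$n_genes, seed = cfg$seed)
  }
  effects <- assign_true_effects(universe, cfg)
  counts <- simulate_counts(universe, effects, cfg, cohort = cohort)
  list(
    universe = universe, effects = effects, counts = counts,
    annotation = universe[, c("gene_id", "length_bp")], config = cfg
  )
}
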