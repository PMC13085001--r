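# Fixture builders shared across test files; everything is generated in code.

toy_meta <- function(sample_ids, cohort = "c1",
                     condition = rep(c("control", "ELS"), length.out = length(sample_ids)),
                     treatment = "vehicle") {
  data.frame(
    sample_id = sample_ids, cohort = cohort, condition = condition,
    treatment = treatment, stringsAsFactors = FALSE
  )
}

toy_counts <- function(m = NULL, ...) {
  if (is.null(m)) {
    m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
      dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))
    )
  }
  count_matrix(m, toy_meta(colnames(m), ...))
}

# deterministic medium fixture for filter / DE tests
sim_counts_fixture <- function(n_genes = 400, n_per_group = 4, seed = 7,
                               gltd_slope = 0, de_fraction = 0.2) {
  cfg <- sim_config(
    n_genes = n_genes, n_per_group = n_per_group,
    de_fraction = de_fraction, gltd_slope = gltd_slope, seed = seed
  )
  simulate_cohort(cfg)
}

# independent re-derivation of the binning contract
oracle_bins <- function(genes, bin_size) {
  ord <- order(-genes$length_bp, genes$gene_id)
  ids <- genes$gene_id[ord]
  nb <- nrow(genes) %/% bin_size
  used <- seq_len(nb * bin_size)
  list(
    bins = unname(split(ids[used], rep(seq_len(nb), each = bin_size))),
    discarded = ids[setdiff(seq_along(ids), used)]
  )
}

write_toy_gtf <- function(path) {
  attrs <- function(id) sprintf('gene_id "%s"; gene_biotype "protein_coding";', id)
  lines <- c(
    "#!genome-build toy1",
    paste("1", "toy", "gene", 100, 100, ".", "+", ".", attrs("gPoint"), sep = "\t"),
    paste("1", "toy", "gene", 1001, 2000, ".", "+", ".", attrs("gKilo"), sep = "\t"),
    paste("1", "toy", "exon", 1001, 1200, ".", "+", ".", attrs("gKilo"), sep = "\t"),
    paste("2", "toy", "gene", 500, 849, ".", "-", ".", attrs("gMid"), sep = "\t"),
    paste("2", "toy", "gene", 1, 25, ".", "+", ".", attrs("gTiny"), sep = "\t"),
    paste("X", "toy", "gene", 10000, 109999, ".", "-", ".", attrs("gLong"), sep = "\t")
  )
  writeLines(lines, path)
  path
}

# bin tables with a prescribed linear ratio trend, for regression tests
synthetic_bins <- function(slope, intercept = 0.5, n_bins = 24, noise_sd = 0,
                           seed = 1) {
  lengths <- 10^seq(5.8, 3.6, length.out = n_bins)
  x <- log10(lengths)
  withr::with_seed(seed, {
    y <- intercept + slope * (x - mean(x)) + rnorm(n_bins, 0, noise_sd)
  })
  y <- pmin(pmax(y, 0), 1)
  n_dir <- 500L
  n_up <- as.integer(round(y * n_dir))
  out <- data.frame(
    bin_index = seq_len(n_bins) - 1L,
    mean_length_bp = lengths,
    n_total = 500L,
    n_up = n_up,
    n_down = n_dir - n_up
  )
  out$up_ratio <- out$n_up / (out$n_up + out$n_down)
  out$gene_ids <- replicate(n_bins, character(0), simplify = FALSE)
  out
}
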