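test_that("gene universe generation is deterministic and honors its distribution", {
  u1 <- generate_gene_universe(1000, seed = 1)
  u2 <- generate_gene_universe(1000, seed = 1)
  expect_identical(u1, u2)
  expect_false(identical(u1, generate_gene_universe(1000, seed = 2)))

  expect_true(all(u1$length_bp >= 1))
  expect_true(all(u1$base_mean > 0))
  expect_true(all(u1$dispersion > 0))
  expect_false(anyDuplicated(u1$gene_id) > 0)
  expect_true(all(u1$length_bp >= 10^2.5 - 1 & u1$length_bp <= 10^6.5 + 1))

  # degenerate spread collapses every length onto the location parameter
  u0 <- generate_gene_universe(50, seed = 3, length_log10_sd = 0)
  expect_true(all(u0$length_bp == round(10^4.3)))

  # Monte-Carlo check of the log10-normal location at n = 12000
  u <- generate_gene_universe(12000, seed = 7)
  expect_equal(median(log10(u$length_bp)), 4.3, tolerance = 0.02 / 4.3)

  expect_error(generate_gene_universe(1, seed = 1), "n_genes")
})

test_that("true effects follow the logistic length-direction model", {
  # beta = 0: up/down symmetric among affected genes
  u <- generate_gene_universe(20000, seed = 11)
  cfg <- sim_config(n_genes = 20000, de_fraction = 0.5, gltd_slope = 0, seed = 11)
  eff <- assign_true_effects(u, cfg)
  expect_true(all(eff$true_log2fc[!eff$is_de] == 0))
  expect_true(all(sign(eff$true_log2fc[eff$direction == "up"]) == 1))
  expect_true(all(sign(eff$true_log2fc[eff$direction == "down"]) == -1))
  up_frac <- mean(eff$true_log2fc[eff$is_de] > 0)
  n_de <- sum(eff$is_de)
  expect_gt(n_de, 9000)
  expect_lt(abs(up_frac - 0.5), 3 * sqrt(0.25 / n_de))

  # beta -> +Inf: direction fully determined by side of the mean length
  cfg_inf <- sim_config(n_genes = 20000, de_fraction = 0.5, gltd_slope = 1e9, seed = 11)
  eff_inf <- assign_true_effects(u, cfg_inf)
  x <- log10(u$length_bp) - mean(log10(u$length_bp))
  de <- eff_inf$is_de
  expect_true(all(eff_inf$true_log2fc[de & x < 0] > 0))
  expect_true(all(eff_inf$true_log2fc[de & x > 0] < 0))

  # beta = 1: up-fraction declines from shortest to longest decile
  u12 <- generate_gene_universe(12000, seed = 3)
  cfg3 <- sim_config(n_genes = 12000, de_fraction = 0.1, gltd_slope = 1, seed = 3)
  eff3 <- assign_true_effects(u12, cfg3)
  dec <- cut(u12$length_bp, quantile(u12$length_bp, 0:10 / 10),
    include.lowest = TRUE, labels = FALSE
  )
  de3 <- eff3$is_de
  up_short <- mean(eff3$true_log2fc[de3 & dec == 1] > 0)
  up_long <- mean(eff3$true_log2fc[de3 & dec == 10] > 0)
  expect_gt(up_short, up_long)

  expect_error(
    sim_config(de_fraction = 0),
    "de_fraction"
  )
})

test_that("count simulation matches its NB construction", {
  # shape contract
  cfg <- sim_config(n_genes = 300, n_per_group = 6, seed = 5)
  sim <- simulate_cohort(cfg)
  expect_s3_class(sim$counts, "count_matrix")
  expect_identical(dim(sim$counts$counts), c(300L, 12L))
  expect_identical(
    sim$counts$sample_meta$condition,
    rep(c("control", "ELS"), each = 6)
  )

  # determinism
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$counts$counts, sim2$counts$counts)

  # a true log2fc of 1 doubles the expected ELS mean at large n
  u <- generate_gene_universe(60, seed = 9,
    base_mean_meanlog = log(500), base_mean_sdlog = 0.2
  )
  u$dispersion <- 0.02
  eff <- data.frame(
    gene_id = u$gene_id,
    true_log2fc = c(1, rep(0, 59)),
    is_de = c(TRUE, rep(FALSE, 59)),
    direction = c("up", rep("null", 59))
  )
  cfg_big <- sim_config(
    n_genes = 60, n_per_group = 300, seed = 21,
    libsize_params = c(0, 0)
  )
  cm <- simulate_counts(u, eff, cfg_big)
  is_els <- cm$sample_meta$condition == "ELS"
  ratio <- mean(cm$counts[1, is_els]) / mean(cm$counts[1, !is_els])
  expect_equal(ratio, 2, tolerance = 0.05)

  # Poisson limit: dispersion -> 0 and fixed library factors give var ~ mean
  u0 <- u
  u0$dispersion <- 0
  cm0 <- simulate_counts(u0, eff, cfg_big)
  ctrl <- cm0$counts[-1, !is_els]
  vm_ratio <- apply(ctrl, 1, var) / rowMeans(ctrl)
  expect_equal(mean(vm_ratio), 1, tolerance = 0.05)

  # programmed dispersion is recovered from NB moments within 10%
  ud <- u
  ud$dispersion <- 0.1
  cmd <- simulate_counts(ud, eff, cfg_big)
  ctl <- cmd$counts[-1, !is_els]
  mu <- rowMeans(ctl)
  alpha_hat <- (apply(ctl, 1, var) - mu) / mu^2
  expect_equal(median(alpha_hat), 0.1, tolerance = 0.10)

  # mismatched gene sets are rejected
  expect_error(
    simulate_counts(u, eff[-1, ], cfg_big),
    "cover exactly"
  )
})

test_that("synthetic gene sets carry the programmed enrichment and are reproducible", {
  u <- generate_gene_universe(2000, seed = 13)
  cfg <- sim_config(n_genes = 2000, de_fraction = 0.3, gltd_slope = 0, seed = 13)
  eff <- assign_true_effects(u, cfg)
  eff$true_log2fc <- abs(eff$true_log2fc) # all-positive effects

  sets <- generate_gene_sets(u, eff,
    n_sets = 6, n_enriched = 3, set_size = 80,
    enrichment_bias = 8, seed = 13
  )
  expect_length(sets, 6)
  mean_lfc <- function(ids) mean(eff$true_log2fc[match(ids, eff$gene_id)])
  for (nm in grep("^aging", names(sets), value = TRUE)) {
    expect_gt(mean_lfc(sets[[nm]]), mean(eff$true_log2fc))
  }

  # byte-identical GMT under a fixed seed
  f1 <- withr::local_tempfile(fileext = ".gmt")
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f1)
  write_gmt(generate_gene_sets(u, eff,
    n_sets = 6, n_enriched = 3, set_size = 80,
    enrichment_bias = 8, seed = 13
  ), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(
    generate_gene_sets(u, eff, n_sets = 2, n_enriched = 3, set_size = 10, 1, seed = 1),
    "n_enriched"
  )
  expect_error(
    generate_gene_sets(u, eff, n_sets = 2, n_enriched = 1, set_size = 1e6, 1, seed = 1),
    "set_size"
  )
})

test_that("generator randomness is independent across stage substreams", {
  cfg <- sim_config(n_genes = 500, seed = 17)
  sim_a <- simulate_cohort(cfg)
  # regenerating only the counts stage must not disturb effect assignment
  eff_again <- assign_true_effects(sim_a$universe, sim_a$config)
  expect_identical(sim_a$effects, eff_again)
  # distinct cohort indices give distinct draws under one master seed
  sim_b <- simulate_cohort(cfg, cohort = "b", cohort_index = 1L)
  expect_false(identical(sim_a$counts$counts[, 1], sim_b$counts$counts[, 1]))
})
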