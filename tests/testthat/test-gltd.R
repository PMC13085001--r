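test_that("length binning is anchored at the longest genes and drops the remainder", {
  ann <- function(n, seed = 1) {
    withr::with_seed(seed, data.frame(
      gene_id = sprintf("g%04d", sample(n)),
      length_bp = sample(300:2e6, n, replace = TRUE)
    ))
  }
  b1000 <- bin_by_length(ann(1000), bin_size = 500)
  expect_identical(nrow(b1000), 2L)
  expect_length(attr(b1000, "discarded"), 0L)

  b1234 <- bin_by_length(ann(1234), bin_size = 500)
  expect_identical(nrow(b1234), 2L)
  expect_length(attr(b1234, "discarded"), 234L)

  # randomized fixtures against the brute-force partition oracle
  for (n in c(500, 777, 1500, 2503)) {
    a <- ann(n, seed = n)
    a$length_bp[seq_len(50)] <- a$length_bp[51] # force ties
    got <- bin_by_length(a, 500)
    want <- oracle_bins(a, 500)
    expect_identical(unname(got$gene_ids), want$bins)
    expect_identical(attr(got, "discarded"), want$discarded)
    # partition: every retained gene in exactly one bin
    all_ids <- unlist(got$gene_ids)
    expect_false(anyDuplicated(all_ids) > 0)
    expect_setequal(c(all_ids, attr(got, "discarded")), a$gene_id)
    # discarded genes are exactly the (n mod 500) shortest
    expect_length(attr(got, "discarded"), n %% 500)
    if (n %% 500 > 0) {
      expect_lte(
        max(a$length_bp[a$gene_id %in% attr(got, "discarded")]),
        min(a$length_bp[a$gene_id %in% all_ids])
      )
    }
    expect_true(all(diff(got$mean_length_bp) < 0))
  }

  expect_error(bin_by_length(ann(300), 500), "smaller than one bin")
})

test_that("per-bin direction ratios count fold-change signs", {
  ann <- data.frame(
    gene_id = sprintf("g%03d", 1:100),
    length_bp = seq(1e6, 1e4, length.out = 100)
  )
  bins <- bin_by_length(ann, bin_size = 50)
  de <- data.frame(
    gene_id = ann$gene_id,
    log2fc = c(rep(1, 30), rep(-1, 20), rep(1, 10), rep(-1, 30), rep(0, 10)),
    padj = 1, significant = FALSE
  )
  br <- bin_direction_ratio(bins, de)
  expect_equal(br$n_up[1], 30)
  expect_equal(br$n_down[1], 20)
  expect_equal(br$up_ratio[1], 0.6)
  # zero fold changes count in neither direction
  expect_equal(br$n_up[2] + br$n_down[2], 40)
  expect_true(all(br$up_ratio >= 0 & br$up_ratio <= 1, na.rm = TRUE))
  expect_true(all(br$n_up + br$n_down <= br$n_total))

  # deg_only with an empty bin leaves the ratio undefined
  de$significant <- de$gene_id %in% sprintf("g%03d", 1:5)
  bd <- bin_direction_ratio(bins, de, mode = "deg_only")
  expect_equal(bd$n_up[1], 5)
  expect_true(is.na(bd$up_ratio[2]))

  expect_error(
    bin_direction_ratio(bins, de[-1, ]),
    "missing from the DE table"
  )
})

test_that("the ratio regression reproduces closed-form fits", {
  # perfectly linear decline
  bins <- synthetic_bins(slope = -0.12, noise_sd = 0)
  bins$up_ratio <- 0.5 - 0.12 * (log10(bins$mean_length_bp) -
    mean(log10(bins$mean_length_bp)))
  fit <- length_ratio_regression(bins)
  expect_equal(fit$pearson_r, -1)
  expect_equal(fit$slope, -0.12, tolerance = 1e-12)
  expect_lt(fit$pvalue, 1e-12)
  expect_identical(fit$df, fit$n_bins - 2L)

  # constant ratios: degenerate variance is an error, not a silent zero
  flat <- bins
  flat$up_ratio <- 0.5
  expect_error(length_ratio_regression(flat), "degenerate")

  # slope and r are invariant to length units (bp -> kb)
  noisy <- synthetic_bins(slope = -0.1, noise_sd = 0.03, seed = 5)
  f_bp <- length_ratio_regression(noisy)
  kb <- noisy
  kb$mean_length_bp <- kb$mean_length_bp / 1000
  f_kb <- length_ratio_regression(kb)
  expect_equal(f_kb$slope, f_bp$slope, tolerance = 1e-9)
  expect_equal(f_kb$pearson_r, f_bp$pearson_r, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f_kb$intercept, f_bp$intercept)))

  # r and slope always share sign
  for (s in c(-0.1, 0.1)) {
    f <- length_ratio_regression(synthetic_bins(slope = s, noise_sd = 0.02, seed = 9))
    expect_gt(f$slope * f$pearson_r, 0)
  }

  few <- bins[1:2, ]
  expect_error(length_ratio_regression(few), "3 bins")
})

test_that("cohort interaction detects differing slopes and not identical ones", {
  a <- synthetic_bins(slope = -0.4, noise_sd = 0.02, seed = 11)
  same <- cohort_interaction_regression(a, a)
  expect_lt(same$f_stat, 1e-8)
  expect_gt(same$pvalue, 0.999)

  b <- synthetic_bins(slope = 0.4, noise_sd = 0.02, seed = 12)
  diff_fit <- cohort_interaction_regression(a, b)
  expect_lt(diff_fit$pvalue, 0.01)
  expect_identical(diff_fit$df[1], 1L)
  # pooled slope lies between the two cohort slopes
  expect_gt(diff_fit$pooled$slope, -0.4)
  expect_lt(diff_fit$pooled$slope, 0.4)
})

test_that("the DEG length-shift test is exact for tiny groups", {
  lengths <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    length_bp = c(1, 2, 3, 4, 5, 6)
  )
  de <- data.frame(
    gene_id = lengths$gene_id,
    log2fc = c(1, 1, 1, -1, -1, -1),
    padj = 0.01, significant = TRUE
  )
  res <- deg_length_shift_test(de, lengths)
  expect_equal(unname(res$U), 0)
  expect_equal(res$pvalue, 0.1) # 2 * 1/choose(6,3)... = 2/20
  expect_identical(res$method, "exact")

  # identical multisets: no shift, p = 1
  de2 <- de
  lengths2 <- lengths
  lengths2$length_bp <- rep(c(10, 20, 30), 2)
  res2 <- deg_length_shift_test(de2, lengths2)
  expect_equal(res2$pvalue, 1)

  # the normal approximation tracks the exact p for small untied samples
  set.seed(19)
  up <- sample(1:1000, 8)
  down <- sample(1001:2000, 8)
  lens <- data.frame(
    gene_id = sprintf("h%d", 1:16), length_bp = c(up, down)
  )
  dd <- data.frame(
    gene_id = lens$gene_id,
    log2fc = rep(c(1, -1), each = 8),
    padj = 0.01, significant = TRUE
  )
  p_exact <- deg_length_shift_test(dd, lens)$pvalue
  p_norm <- deg_length_shift_test(dd, lens, exact_max = 0)$pvalue
  expect_equal(p_norm, p_exact, tolerance = 0.10)

  de_up_only <- de
  de_up_only$log2fc <- abs(de_up_only$log2fc)
  expect_error(deg_length_shift_test(de_up_only, lengths), "each direction")
})

test_that("an end-to-end simulated cohort recovers the programmed length decline", {
  cfg <- sim_config(n_genes = 6000, gltd_slope = 1.2, seed = 23)
  sim <- simulate_cohort(cfg)
  res <- gltd_analysis(sim$counts, sim$annotation)
  expect_lt(res$fit$slope, 0)
  expect_lt(res$fit$pvalue, 0.05)
  expect_gt(res$fit$slope * res$fit$pearson_r, 0)
  # bin mean lengths strictly decrease with bin index
  expect_true(all(diff(res$bins$mean_length_bp) < 0))
  # relabeling gene ids leaves the fit untouched
  relabel <- setNames(sprintf("x%05d", seq_along(sim$annotation$gene_id)),
    sim$annotation$gene_id
  )
  counts2 <- sim$counts
  rownames(counts2$counts) <- unname(relabel[rownames(counts2$counts)])
  ann2 <- sim$annotation
  ann2$gene_id <- unname(relabel[ann2$gene_id])
  res2 <- gltd_analysis(counts2, ann2)
  expect_equal(res2$fit$slope, res$fit$slope, tolerance = 1e-9)
})
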