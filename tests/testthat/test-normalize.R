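test_that("median-of-ratios reproduces the closed-form factors", {
  # identical samples
  m <- matrix(c(5, 8, 13, 5, 8, 13), nrow = 3,
    dimnames = list(paste0("g", 1:3), c("a", "b"))
  )
  expect_equal(unname(median_of_ratios(m)$size_factors), c(1, 1))

  # A = (10,20,30), B = (20,40,60): factors (1/sqrt(2), sqrt(2))
  ab <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
    dimnames = list(paste0("g", 1:3), c("A", "B"))
  )
  nr <- median_of_ratios(ab)
  expect_equal(unname(nr$size_factors), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(nr$normalized[, "A"], nr$normalized[, "B"], tolerance = 1e-12)

  # scaling one sample by 10 scales the factor *ratio* by 10; the absolute
  # factors shift together because the geometric-mean reference rescales too,
  # and the normalized profiles stay proportional across samples
  sc <- ab
  sc[, "B"] <- sc[, "B"] * 10
  sf <- median_of_ratios(sc)$size_factors
  expect_equal(
    unname(sf["B"] / sf["A"]),
    unname(nr$size_factors["B"] / nr$size_factors["A"]) * 10,
    tolerance = 1e-12
  )
  nsc <- median_of_ratios(sc)$normalized
  expect_equal(nsc[, "A"], nsc[, "B"], tolerance = 1e-12)

  expect_error(
    median_of_ratios(matrix(c(0, 1, 1, 0), 2,
      dimnames = list(c("g1", "g2"), c("a", "b"))
    )),
    "filter"
  )
})

test_that("median-of-ratios centres every sample's ratios on the pseudo-reference", {
  sim <- sim_counts_fixture(n_genes = 500, n_per_group = 5)
  m <- sim$counts$counts
  nr <- median_of_ratios(m)
  keep <- rowSums(m == 0) == 0
  ref <- exp(rowMeans(log(m[keep, ])))
  med_ratio <- apply(nr$normalized[keep, ], 2, function(x) median(x / ref))
  expect_equal(unname(med_ratio), rep(1, ncol(m)), tolerance = 1e-9)

  # invariant to gene and sample order
  perm <- nr$size_factors[c(2, 1, 3:ncol(m))]
  reord <- median_of_ratios(m[sample(nrow(m)), c(2, 1, 3:ncol(m))])
  expect_equal(reord$size_factors, perm, tolerance = 1e-12)
})

test_that("TMM factors are 1 for identical or purely rescaled samples", {
  m <- matrix(c(100, 200, 50, 400, 80, 20,
                100, 200, 50, 400, 80, 20), ncol = 2,
    dimnames = list(paste0("g", 1:6), c("a", "b"))
  )
  expect_equal(unname(tmm_factors(m)), c(1, 1), tolerance = 1e-12)

  m2 <- m
  m2[, "b"] <- m[, "a"] * 2
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches a hand evaluation with the outlier trimmed", {
  # one gene is wildly overexpressed in b; with 30%/5% trims it must be cut
  m <- matrix(c(
    1000, 2000, 500, 4000, 800, 200, 100, 900, 1500, 600,
    1000, 2000, 500, 4000, 800, 20000, 100, 900, 1500, 600
  ), ncol = 2, dimnames = list(paste0("g", 1:10), c("a", "b")))
  got <- tmm_factors(m, reference = "a")

  # independent evaluation of the trimmed weighted mean
  lib <- colSums(m)
  pa <- m[, "a"] / lib["a"]
  pb <- m[, "b"] / lib["b"]
  M <- log2(pb / pa)
  A <- 0.5 * log2(pb * pa)
  v <- (lib["b"] - m[, "b"]) / (lib["b"] * m[, "b"]) +
    (lib["a"] - m[, "a"]) / (lib["a"] * m[, "a"])
  n <- length(M)
  lo_m <- floor(n * 0.3) + 1
  lo_a <- floor(n * 0.05) + 1
  keep <- rank(M) >= lo_m & rank(M) <= n + 1 - lo_m &
    rank(A) >= lo_a & rank(A) <= n + 1 - lo_a
  expect_false(keep[["g6"]]) # the outlier is trimmed
  fb <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  expected <- c(1, fb) / exp(mean(log(c(1, fb))))
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)

  # geometric mean one, and order invariance
  expect_equal(exp(mean(log(got))), 1, tolerance = 1e-12)
  sim <- sim_counts_fixture(n_genes = 300, n_per_group = 4)
  f <- tmm_factors(sim$counts$counts)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  shuffled <- tmm_factors(sim$counts$counts[sample(300), ])
  expect_equal(shuffled, f, tolerance = 1e-12)
})

test_that("TMM agrees with the edgeR reference implementation", {
  sim <- sim_counts_fixture(n_genes = 800, n_per_group = 5, seed = 3)
  m <- sim$counts$counts
  ours <- tmm_factors(m)
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("median-of-ratios agrees with the DESeq2 reference implementation", {
  sim <- sim_counts_fixture(n_genes = 600, n_per_group = 4, seed = 5)
  m <- sim$counts$counts
  ours <- median_of_ratios(m)$size_factors
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("expression filter applies the strict group-replicate rule", {
  nm <- rbind(
    keepme = c(25, 25, 25, 5, 1, 1, 1, 1),
    dropme = c(25, 25, 19, 5, 21, 19, 1, 1),
    border = c(20, 20, 20, 20, 20, 20, 20, 20)
  )
  colnames(nm) <- paste0("s", 1:8)
  groups <- rep(c("ctl", "els"), each = 4)
  kept <- expression_filter(nm, groups, min_replicates = 3, min_count = 20)
  expect_identical(kept, "keepme")
  # strict inequality: exactly 20 never qualifies
  expect_false("border" %in% kept)

  expect_error(expression_filter(nm, character(0), 3), "group")
  expect_error(expression_filter(nm, groups, min_replicates = 5), "smallest group")
})

test_that("expression filter equals a brute-force per-gene scan and is monotone", {
  sim <- sim_counts_fixture(n_genes = 400, n_per_group = 4, seed = 11)
  nm <- median_of_ratios(sim$counts$counts)$normalized
  groups <- sim$counts$sample_meta$condition
  kept <- expression_filter(nm, groups, min_replicates = 3, min_count = 20)

  brute <- rownames(nm)[vapply(seq_len(nrow(nm)), function(i) {
    any(vapply(unique(groups), function(g) {
      sum(nm[i, groups == g] > 20) >= 3
    }, logical(1)))
  }, logical(1))]
  expect_identical(kept, brute)

  stricter_count <- expression_filter(nm, groups, 3, min_count = 40)
  stricter_reps <- expression_filter(nm, groups, 4, min_count = 20)
  expect_true(all(stricter_count %in% kept))
  expect_true(all(stricter_reps %in% kept))
})

test_that("TMM abundance filter selects by mean normalized CPM", {
  sim <- sim_counts_fixture(n_genes = 300, n_per_group = 4, seed = 13)
  m <- sim$counts$counts
  m["g00001", ] <- 0
  f <- tmm_factors(m)
  kept <- tmm_abundance_filter(m, f, threshold = 1)
  expect_false("g00001" %in% kept)

  all_expressed <- tmm_abundance_filter(m, f, threshold = 0)
  expect_setequal(all_expressed, rownames(m)[rowSums(m) > 0])

  # direct re-derivation of the CPM rule
  cpm <- sweep(m, 2, colSums(m) * f / 1e6, "/")
  expect_setequal(kept, rownames(m)[rowMeans(cpm) > 1])
})
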