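#!/usr/bin/env Rscript
# Build the synthetic study: two adolescent cohorts (4 v 4 and 6 v 6,
# vehicle-treated ELS vs control) and two adult cohorts (2x2 design with an
# RU486 arm, 6 per group), all drawn from one shared expressed-gene universe
# with a length-dependent direction bias (beta = 1, |log2FC| ~ Exp(0.2)).
# Writes counts/metadata/annotation/truth TSVs and an aging-signature-style
# GMT under results/data/.

suppressPackageStartupMessages(library(gltdseq))

seed <- 20260927L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

base_cfg <- sim_config(n_genes = 12000, seed = seed)
universe <- generate_gene_universe(base_cfg$n_genes, seed = seed)
write_gene_lengths(universe[, c("gene_id", "length_bp")],
  file.path(out, "gene_lengths.tsv")
)

simulate_arm <- function(n_per_group, cohort, index, treatment = "vehicle") {
  cfg <- sim_config(n_genes = 12000, n_per_group = n_per_group, seed = seed)
  sc <- simulate_cohort(cfg,
    cohort = cohort, universe = universe, cohort_index = index
  )
  sc$counts$sample_meta$treatment <- treatment
  if (treatment != "vehicle") {
    ids <- sub("_(ctrl|els)_", paste0("_\\1_", tolower(treatment), "_"),
      sc$counts$sample_meta$sample_id
    )
    sc$counts$sample_meta$sample_id <- ids
    colnames(sc$counts$counts) <- ids
  }
  sc
}

cohorts <- list(
  adolescent1 = simulate_arm(4, "adolescent1", 0L),
  adolescent2 = simulate_arm(6, "adolescent2", 1L)
)

# adult cohorts: vehicle and RU486 arms drawn independently, so the ELS
# signature carries over but individual RU486-arm effects are cohort-specific
# (no programmed reversal)
for (ad in c("adult1", "adult2")) {
  idx <- if (ad == "adult1") c(2L, 3L) else c(4L, 5L)
  veh <- simulate_arm(6, ad, idx[1])
  ru <- simulate_arm(6, ad, idx[2], treatment = "RU486")
  cohorts[[ad]] <- list(counts = count_matrix(
    cbind(veh$counts$counts, ru$counts$counts),
    rbind(veh$counts$sample_meta, ru$counts$sample_meta)
  ), effects = list(vehicle = veh$effects, RU486 = ru$effects))
}

for (nm in names(cohorts)) {
  cm <- if (inherits(cohorts[[nm]], "count_matrix")) cohorts[[nm]] else {
    cohorts[[nm]]$counts
  }
  write_counts(cm,
    file.path(out, sprintf("counts_%s.tsv", nm)),
    file.path(out, sprintf("meta_%s.tsv", nm))
  )
  cat(sprintf(
    "%s: %d genes x %d samples (%s)\n", nm, nrow(cm$counts), ncol(cm$counts),
    paste(sort(unique(paste(cm$sample_meta$condition,
      cm$sample_meta$treatment
    ))), collapse = ", ")
  ))
}

truth <- cohorts$adolescent1$effects
write.table(truth, file.path(out, "truth_adolescent1.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)

sets <- generate_gene_sets(universe, cohorts$adolescent2$effects,
  n_sets = 9, n_enriched = 3, set_size = 100, enrichment_bias = 4, seed = seed
)
write_gmt(sets, file.path(out, "aging_signatures_synthetic.gmt"))
cat(sprintf(
  "gene sets: %d written (%d with programmed enrichment)\n", length(sets), 3
))
cat("done: inputs under", out, "\n")
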