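#!/usr/bin/env Rscript
# Pi-value ranking and permutation GSEA of each adolescent cohort's DE
# results against the synthetic aging-signature collection (three sets with
# programmed enrichment, six calibrated nulls), 10,000 permutations, BH
# correction, set sizes 1-5000.

suppressPackageStartupMessages(library(gltdseq))

ind <- "results/data"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
sets <- read_gmt(file.path(ind, "aging_signatures_synthetic.gmt"))
seed <- 20260927L

for (nm in c("adolescent1", "adolescent2")) {
  de <- read_de_table(file.path(out, sprintf("de_%s.tsv", nm)))
  ranked <- rank_genes(de)
  write.table(ranked, file.path(out, sprintf("ranked_%s.tsv", nm)),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  enr <- gsea(ranked, sets, n_perm = 10000, seed = seed)
  write_enrichment(enr, file.path(out, sprintf("enrichment_%s.tsv", nm)))
  hit <- enr$set_name[enr$padj < 0.05]
  cat(sprintf(
    "%s: %d/%d sets significant at padj < 0.05: %s\n",
    nm, length(hit), nrow(enr),
    if (length(hit)) paste(hit, collapse = ", ") else "none"
  ))
  top <- enr[order(enr$pvalue)[1], ]
  cat(sprintf(
    "  strongest: %s (ES = %.2f, NES = %.2f, p = %.2g, padj = %.2g)\n",
    top$set_name, top$es, top$nes, top$pvalue, top$padj
  ))
}
cat("enrichment tables written under", out, "\n")
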