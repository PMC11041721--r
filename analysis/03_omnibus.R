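#!/usr/bin/env Rscript

# Stage 3: combine the per-mask p-values of each gene-trait pair into a
# Cauchy omnibus p-value, apply Benjamini-Hochberg FDR within trait
# families (disease endpoints vs quantitative traits), and summarize each
# pair by its best mask -- the long-format table behind a heatmap of the
# dominance spectrum.

suppressPackageStartupMessages(library(cmspectrum))

res <- as.data.frame(data.table::fread("results/association/per_mask_results.tsv"))
out <- "results/omnibus"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fam <- c(disease = "disease_endpoints", qtrait = "quantitative_traits")
om <- omnibus_table(res, fdr_family = fam)
write_tsv(om, file.path(out, "omnibus.tsv"))

cat("gene-trait omnibus results:\n")
print(om, digits = 3, row.names = FALSE)
sig <- om[om$q_value < 0.05, ]
cat(sprintf("\n%d pair(s) at FDR Q < 0.05\n", nrow(sig)))
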