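#!/usr/bin/env Rscript

# Stage 1: generate the synthetic biobank-style cohort used by the
# association arm. One gene carries a planted protective-of-nothing --
# i.e. risk-increasing -- PTV effect (OR 5) on the disease endpoint; a
# second gene is null. Writes the genotype, annotation and phenotype
# tables plus a run manifest under results/sim/.

suppressPackageStartupMessages(library(cmspectrum))

seed <- 20260101
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- rbind(
  transform(default_variant_panel(gene = "LMOD2like", maf = 5e-4),
            variant_id = sprintf("7:%d:A:T", seq_len(14) * 500)),
  transform(default_variant_panel(gene = "NULLGENE", maf = 5e-4),
            variant_id = sprintf("2:%d:A:T", seq_len(14) * 500))
)
panel$popmax <- 1e-6  # ultra-rare in the reference populations

spec <- cohort_spec(
  n_samples = 50000, variants = panel,
  carrier_log_or = log(5),
  effect_variants = panel$variant_id[panel$gene == "LMOD2like" &
                                       panel$consequence == "stop_gained"],
  prevalence = 0.01, quantitative_effect = 0.4
)
sim <- simulate_cohort(spec, seed = seed)

write_genotype_matrix(sim$genotypes, file.path(out, "genotypes.tsv"))
write_tsv(sim$phenotypes, file.path(out, "phenotypes.tsv"))
write_tsv(sim$annotations, file.path(out, "annotations.tsv"))
write_manifest(file.path(out, "manifest.json"),
               config = list(n_samples = spec$n_samples,
                             prevalence = spec$prevalence,
                             carrier_log_or = spec$carrier_log_or,
                             quantitative_effect = spec$quantitative_effect),
               seeds = list(cohort = seed),
               inputs = character(0))

cat(sprintf("cohort: %d samples, %d variants, %d cases (%.2f%%), %d planted carriers\n",
            nrow(sim$genotypes), ncol(sim$genotypes),
            sum(sim$phenotypes$disease),
            100 * mean(sim$phenotypes$disease),
            sum(sim$truth$carrier)))
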