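# Per-population heterozygous-LOF carrier prevalence and biallelic-PTV
# screening of genotype datasets.

#' Carrier prevalence from allele frequencies
#'
#' Percentage of individuals carrying at least one qualifying LOF allele
#' in a population, under Hardy-Weinberg equilibrium and independence
#' across variants: `100 * (1 - prod_i (1 - q_i)^2)`. An alternative
#' count-based mode is available through [carrier_prevalence_counts()]
#' for datasets providing per-variant genotype counts.
#'
#' @param freqs numeric vector of allele frequencies of the qualifying
#'   variants (PTVs plus configured recurrent missense LOF-equivalents).
#' @return carrier prevalence as a percentage.
#' @examples
#' carrier_prevalence(0.008)  # 1.5936
#' @export
carrier_prevalence <- function(freqs) {
  if (length(freqs) == 0L) return(0)
  if (any(freqs < 0 | freqs > 1)) {
    cm_stop("allele frequencies must lie in [0, 1]")
  }
  if (any(freqs > 0.5)) {
    cm_warn("allele frequency above 0.5: minor-allele assumption violated")
  }
  100 * (1 - prod(1 - freqs)^2)
}

#' Carrier prevalence from genotype counts
#'
#' Count-based alternative: sums heterozygote and homozygote individuals
#' over qualifying variants and divides by the population sample size.
#' Individuals carrying several qualifying variants are counted once per
#' variant, so this mode slightly overestimates when carriers overlap.
#'
#' @param het_counts,hom_counts integer vectors per variant.
#' @param n_individuals population sample size.
#' @return carrier prevalence as a percentage.
#' @export
carrier_prevalence_counts <- function(het_counts, hom_counts, n_individuals) {
  if (n_individuals <= 0) cm_stop("n_individuals must be positive")
  100 * (sum(het_counts) + sum(hom_counts)) / n_individuals
}

#' Per-gene, per-population carrier prevalence table
#'
#' @param freq_table data.frame with columns `gene`, `population`,
#'   `variant_id`, `allele_frequency` (one row per qualifying variant).
#' @param qualifying_ids optional restriction to these variant ids.
#' @return data.frame `gene, population, n_variants, carrier_pct`.
#' @export
carrier_prevalence_table <- function(freq_table, qualifying_ids = NULL) {
  check_columns(freq_table,
                c("gene", "population", "variant_id", "allele_frequency"),
                "population frequency table")
  if (!is.null(qualifying_ids)) {
    freq_table <- freq_table[freq_table$variant_id %in% qualifying_ids, ,
                             drop = FALSE]
  }
  splits <- split(freq_table, list(freq_table$gene, freq_table$population),
                  drop = TRUE)
  rows <- lapply(splits, function(d) {
    data.frame(gene = d$gene[1], population = d$population[1],
               n_variants = nrow(d),
               carrier_pct = carrier_prevalence(d$allele_frequency),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene, out$population), ]
}

#' Biallelic-PTV screen over a genotype dataset
#'
#' Classifies each sample, per gene, by its qualifying high-confidence
#' PTV genotype (PTVs predicted to escape nonsense-mediated decay are
#' excluded by the annotation step): a dosage-2 PTV is `hom_PTV`; two
#' heterozygous PTVs predicted in trans are `comphet_trans`; two
#' heterozygous PTVs without phase, or classified unphased, are
#' `comphet_unphased`; pairs phased in cis (same haplotype, hence
#' monoallelic) and everything else are `none`.
#'
#' @param genotypes sample x variant dosage matrix (0/1/2/NA, variant ids
#'   as column names).
#' @param annotations annotated variant table ([annotate_variants()]).
#' @param phase optional data.frame `variant_id1, variant_id2, phase`
#'   with phase in `cis`, `trans`, `unphased` (order-insensitive).
#' @return list with `classification` (data.frame `sample_id, gene,
#'   class`) for samples with a non-`none` class, and `counts`
#'   (per-gene table of the three biallelic classes).
#' @export
biallelic_ptv_screen <- function(genotypes, annotations, phase = NULL) {
  ptv <- annotations[annotations$consequence == "PTV", , drop = FALSE]
  ptv_ids <- intersect(ptv$variant_id, colnames(genotypes))
  phase_of <- function(v1, v2) {
    if (is.null(phase)) return("unphased")
    hit <- (phase$variant_id1 == v1 & phase$variant_id2 == v2) |
      (phase$variant_id1 == v2 & phase$variant_id2 == v1)
    if (!any(hit)) return("unphased")
    phase$phase[which(hit)[1]]
  }
  res <- list()
  samples <- rownames(genotypes)
  for (g in unique(ptv$gene)) {
    ids <- intersect(ptv$variant_id[ptv$gene == g], ptv_ids)
    if (length(ids) == 0L) next
    G <- genotypes[, ids, drop = FALSE]
    G[is.na(G)] <- 0
    for (i in seq_len(nrow(G))) {
      row <- G[i, ]
      cls <- "none"
      if (any(row >= 2)) {
        cls <- "hom_PTV"
      } else {
        hets <- names(row)[row == 1]
        if (length(hets) >= 2L) {
          pairs <- utils::combn(hets, 2, simplify = FALSE)
          ph <- vapply(pairs, function(p) phase_of(p[1], p[2]), character(1))
          if (any(ph == "trans")) cls <- "comphet_trans"
          else if (any(ph == "unphased")) cls <- "comphet_unphased"
          # all pairs cis -> monoallelic -> none
        }
      }
      if (cls != "none") {
        res[[length(res) + 1L]] <- data.frame(
          sample_id = samples[i], gene = g, class = cls,
          stringsAsFactors = FALSE)
      }
    }
  }
  classification <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(sample_id = character(0), gene = character(0),
               class = character(0), stringsAsFactors = FALSE)
  counts <- if (nrow(classification) > 0L) {
    as.data.frame(table(gene = classification$gene,
                        class = classification$class),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), class = character(0), Freq = integer(0))
  }
  list(classification = classification, counts = counts)
}
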