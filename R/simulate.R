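# Synthetic-data generators: every input of the two analysis arms with
# known ground truth. All generators are pure functions of (spec, seed).

#' Specification for a synthetic rare-variant cohort
#'
#' Defaults emulate a middle-aged population biobank: enrollment ages
#' uniform on 40-69, balanced sex, standard-normal ancestry PCs, rare
#' variants in Hardy-Weinberg equilibrium.
#'
#' @param n_samples cohort size.
#' @param variants data.frame with columns `gene`, `consequence` (raw
#'   vocabulary, e.g. `stop_gained`, `missense`), `maf` (haplotype allele
#'   frequency used for simulation), and optionally `missense_score`,
#'   `lof_confidence`, `nmd_escape`, `popmax` (defaults: high-confidence,
#'   no NMD escape, popmax = maf). A default panel of one gene with PTVs
#'   and graded missense variants is supplied.
#' @param carrier_log_or log-odds added to carriers of the effect set
#'   (binary trait).
#' @param effect_variants variant ids forming the causal carrier set;
#'   default: all PTVs.
#' @param prevalence baseline disease prevalence (intercept solved on the
#'   logit scale).
#' @param covariate_effects named log-odds for `age_std`, `sex` (applied
#'   on standardized age and 0/1 sex).
#' @param quantitative_effect linear effect of the carrier set on the
#'   quantitative trait (SD units); the trait is Gaussian with unit
#'   residual SD.
#' @param n_pcs number of ancestry PCs to simulate (default 4).
#' @param family_blocks optional integer vector of sibship sizes; siblings
#'   share parental haplotypes and induce kinship triples (coefficient
#'   0.25).
#' @return a `cm_cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 10000,
                        variants = default_variant_panel(),
                        carrier_log_or = 0,
                        effect_variants = NULL,
                        prevalence = 0.01,
                        covariate_effects = c(age_std = 0.2, sex = 0.3),
                        quantitative_effect = 0,
                        n_pcs = 4,
                        family_blocks = NULL) {
  if (prevalence <= 0 || prevalence >= 1) {
    cm_stop("prevalence must lie in (0, 1)")
  }
  check_columns(variants, c("gene", "consequence", "maf"), "variant spec")
  if (any(variants$maf < 0 | variants$maf > 0.5)) {
    cm_stop("simulated variant MAFs must lie in [0, 0.5]")
  }
  structure(list(
    n_samples = n_samples, variants = variants,
    carrier_log_or = carrier_log_or, effect_variants = effect_variants,
    prevalence = prevalence, covariate_effects = covariate_effects,
    quantitative_effect = quantitative_effect, n_pcs = n_pcs,
    family_blocks = family_blocks
  ), class = "cm_cohort_spec")
}

#' Default synthetic variant panel
#'
#' One gene (`GENE1`) with a handful of ultra-rare PTVs and missense
#' variants spanning the deleteriousness-score ladder.
#'
#' @param gene gene symbol.
#' @param n_ptv,n_missense panel composition.
#' @param maf haplotype allele frequency shared by all variants.
#' @return variant data.frame for [cohort_spec()].
#' @export
default_variant_panel <- function(gene = "GENE1", n_ptv = 4, n_missense = 10,
                                  maf = 1e-4) {
  n <- n_ptv + n_missense
  data.frame(
    variant_id = sprintf("1:%d:A:T", seq_len(n) * 1000),
    gene = gene,
    consequence = c(rep("stop_gained", n_ptv), rep("missense", n_missense)),
    lof_confidence = c(rep("high", n_ptv), rep("not_lof", n_missense)),
    nmd_escape = FALSE,
    missense_score = c(rep(NA_real_, n_ptv),
                       seq(1, 0.1, length.out = n_missense)),
    maf = maf,
    stringsAsFactors = FALSE
  )
}

#' Simulate a rare-variant cohort
#'
#' Draws two haplotypes per sample (per-variant Bernoulli(maf) under
#' Hardy-Weinberg), covariates, and a binary phenotype from a logistic
#' model on carrier status and covariates (plus a quantitative trait from
#' the corresponding linear model). Identical seeds give identical
#' output.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return list with `genotypes` (dosage matrix), `haplotypes` (list of
#'   two 0/1 matrices, the phase ground truth), `annotations` (analysis-
#'   ready, via [annotate_variants()]), `phenotypes` (data.frame with
#'   `sample_id`, `disease`, `qtrait`, covariates and PCs), `kinship`
#'   (triples data.frame or `NULL`), and `truth` (the planted effects).
#' @export
simulate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cm_cohort_spec"))
  withr::with_seed(seed, {
    n <- spec$n_samples
    v <- spec$variants
    m <- nrow(v)
    sample_ids <- sprintf("S%06d", seq_len(n))
    if (!("variant_id" %in% names(v))) {
      v$variant_id <- sprintf("1:%d:A:T", seq_len(m) * 1000)
    }

    hap1 <- matrix(stats::rbinom(n * m, 1, rep(v$maf, each = n)), n, m)
    hap2 <- matrix(stats::rbinom(n * m, 1, rep(v$maf, each = n)), n, m)
    # Sibling blocks: overwrite trailing samples with haplotypes drawn
    # from shared simulated parents.
    kinship <- NULL
    if (!is.null(spec$family_blocks) && length(spec$family_blocks) > 0) {
      sizes <- spec$family_blocks
      if (sum(sizes) > n) cm_stop("family blocks exceed cohort size")
      pos <- n - sum(sizes)
      trip <- list()
      for (s in sizes) {
        p1 <- cbind(stats::rbinom(m, 1, v$maf), stats::rbinom(m, 1, v$maf))
        p2 <- cbind(stats::rbinom(m, 1, v$maf), stats::rbinom(m, 1, v$maf))
        members <- pos + seq_len(s)
        for (i in members) {
          hap1[i, ] <- p1[cbind(seq_len(m), sample(1:2, m, replace = TRUE))]
          hap2[i, ] <- p2[cbind(seq_len(m), sample(1:2, m, replace = TRUE))]
        }
        if (s > 1) {
          prs <- utils::combn(members, 2)
          trip[[length(trip) + 1L]] <- data.frame(
            id1 = sample_ids[prs[1, ]], id2 = sample_ids[prs[2, ]],
            coefficient = 0.25, stringsAsFactors = FALSE)
        }
        pos <- pos + s
      }
      if (length(trip) > 0) kinship <- do.call(rbind, trip)
    }
    G <- hap1 + hap2
    dimnames(G) <- list(sample_ids, v$variant_id)
    dimnames(hap1) <- dimnames(hap2) <- dimnames(G)

    age <- stats::runif(n, 40, 69)
    age_std <- (age - mean(age)) / stats::sd(age)
    sex <- stats::rbinom(n, 1, 0.5)
    tranche <- stats::rbinom(n, 1, 0.5)
    pcs <- matrix(stats::rnorm(n * spec$n_pcs), n, spec$n_pcs,
                  dimnames = list(NULL, paste0("PC", seq_len(spec$n_pcs))))

    eff_ids <- spec$effect_variants
    if (is.null(eff_ids)) {
      eff_ids <- v$variant_id[classify_consequence(
        v$consequence,
        if ("lof_confidence" %in% names(v)) v$lof_confidence else "high",
        if ("nmd_escape" %in% names(v)) v$nmd_escape else FALSE) == "PTV"]
    }
    carrier <- as.integer(rowSums(G[, eff_ids, drop = FALSE]) >= 1)

    ce <- spec$covariate_effects
    eta_cov <- age_std * ce[["age_std"]] + sex * ce[["sex"]]
    # Intercept so that baseline (non-carrier, covariates at mean) hits
    # the requested prevalence.
    intercept <- stats::qlogis(spec$prevalence)
    eta <- intercept + eta_cov + spec$carrier_log_or * carrier
    disease <- stats::rbinom(n, 1, stats::plogis(eta))
    if (sum(stats::plogis(eta)) < 1) cm_warn("expected case count below 1")
    qtrait <- 0.1 * age_std + 0.1 * sex +
      spec$quantitative_effect * carrier + stats::rnorm(n)

    ann_raw <- data.frame(
      variant_id = v$variant_id, gene = v$gene, consequence = v$consequence,
      lof_confidence = if ("lof_confidence" %in% names(v)) v$lof_confidence
                       else "high",
      nmd_escape = if ("nmd_escape" %in% names(v)) v$nmd_escape else FALSE,
      missense_score = if ("missense_score" %in% names(v)) v$missense_score
                       else NA_real_,
      nfe = if ("popmax" %in% names(v)) v$popmax else v$maf,
      stringsAsFactors = FALSE
    )
    phen <- data.frame(sample_id = sample_ids, disease = disease,
                       qtrait = qtrait, age = age, age2 = age^2,
                       sex = sex, tranche = tranche,
                       stringsAsFactors = FALSE)
    phen <- cbind(phen, as.data.frame(pcs))
    list(
      genotypes = G,
      haplotypes = list(hap1 = hap1, hap2 = hap2),
      annotations = annotate_variants(ann_raw),
      phenotypes = phen,
      kinship = kinship,
      truth = list(carrier_log_or = spec$carrier_log_or,
                   quantitative_effect = spec$quantitative_effect,
                   effect_variants = eff_ids,
                   carrier = stats::setNames(carrier, sample_ids))
    )
  })
}

#' Specification for a synthetic biallelic case series
#'
#' Per-gene onset distributions and exponential event hazards for
#' censored freedom-from-event times, emulating curated per-case tables
#' of biallelic cardiomyopathy patients.
#'
#' @param genes data.frame with columns `gene`, `n`, `onset_meanlog`,
#'   `onset_sdlog` (log-normal onset ages), `event_rate` (exponential
#'   hazard per year of age for the composite endpoint), `phenotype`.
#' @param censor_range uniform range of censoring ages (latest report of
#'   survival) in years.
#' @return a `cm_case_series_spec`.
#' @export
case_series_spec <- function(genes, censor_range = c(5, 40)) {
  check_columns(genes, c("gene", "n", "onset_meanlog", "onset_sdlog",
                         "event_rate"), "case series spec")
  if (any(genes$event_rate <= 0)) cm_stop("event hazards must be positive")
  structure(list(genes = genes, censor_range = censor_range),
            class = "cm_case_series_spec")
}

#' Simulate a biallelic case series
#'
#' Event ages are exponential with the gene's hazard; censoring ages are
#' uniform over `censor_range`. The output conforms to the case-table
#' schema consumed by the survival arm.
#'
#' @param spec a [case_series_spec()].
#' @param seed integer seed.
#' @return case table data.frame (`case_id, gene, phenotype, sex,
#'   zygosity, variant_class, age_onset, outcome, age_outcome`).
#' @export
simulate_case_series <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cm_case_series_spec"))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(spec$genes)), function(i) {
      gspec <- spec$genes[i, ]
      n <- gspec$n
      onset <- stats::rlnorm(n, gspec$onset_meanlog, gspec$onset_sdlog)
      t_event <- stats::rexp(n, rate = gspec$event_rate)
      t_censor <- stats::runif(n, spec$censor_range[1], spec$censor_range[2])
      event <- t_event <= t_censor
      time <- pmin(t_event, t_censor)
      outcome <- ifelse(event,
                        sample(c("deceased", "transplant", "LVAD"), n,
                               replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                        "alive")
      data.frame(
        case_id = sprintf("%s_%03d", gspec$gene, seq_len(n)),
        gene = gspec$gene,
        phenotype = if ("phenotype" %in% names(gspec)) gspec$phenotype
                    else "DCM",
        sex = sample(c("F", "M"), n, replace = TRUE),
        zygosity = sample(c("homozygous", "compound_het", "double_het"), n,
                          replace = TRUE, prob = c(0.6, 0.3, 0.1)),
        variant_class = "PTV",
        age_onset = pmin(onset, time),
        outcome = outcome,
        age_outcome = time,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate trio pedigrees
#'
#' Parents heterozygous for the configured variant(s); offspring
#' genotypes by Mendelian segregation. The homozygous design makes both
#' parents carriers of the same variant; the compound-heterozygous design
#' gives each parent one of two variants, so phase truth is known.
#'
#' @param n_families number of trios.
#' @param design `"homozygous"` or `"compound_het"`.
#' @param seed integer seed.
#' @return data.frame with one row per family: offspring dosages
#'   (`child_v1`, `child_v2`), parental dosages, and `biallelic`
#'   (logical, offspring has a biallelic genotype).
#' @export
simulate_trios <- function(n_families, design = c("homozygous", "compound_het"),
                           seed = 1) {
  design <- match.arg(design)
  withr::with_seed(seed, {
    transmit <- function(n) stats::rbinom(n, 1, 0.5)
    if (design == "homozygous") {
      c1 <- transmit(n_families) + transmit(n_families)  # one from each parent
      out <- data.frame(
        family = seq_len(n_families),
        mother_v1 = 1L, father_v1 = 1L,
        mother_v2 = 0L, father_v2 = 0L,
        child_v1 = c1, child_v2 = 0L
      )
      out$biallelic <- out$child_v1 == 2L
    } else {
      # mother heterozygous for v1 only, father for v2 only
      c1 <- transmit(n_families)
      c2 <- transmit(n_families)
      out <- data.frame(
        family = seq_len(n_families),
        mother_v1 = 1L, father_v1 = 0L,
        mother_v2 = 0L, father_v2 = 1L,
        child_v1 = c1, child_v2 = c2
      )
      out$biallelic <- out$child_v1 == 1L & out$child_v2 == 1L
    }
    out
  })
}
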