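# Curated biallelic-case arm: Kaplan-Meier curves, Cox contrasts between
# causal genes, onset comparisons, outcome tallies, zygosity logic and
# ClinGen-style estimated LOD scores.

# Outcomes counting as survival-endpoint events: freedom from death,
# heart transplant or LVAD implantation. Fetal termination may optionally
# be treated as an event at age 0.
EVENT_OUTCOMES <- c("deceased", "transplant", "LVAD")

#' Prepare a case table for survival analysis
#'
#' Builds (time, event) pairs: time zero is birth, events are death,
#' transplant or LVAD at `age_outcome`; cases alive at last report are
#' censored at `age_outcome`. Cases with unknown outcome or missing
#' `age_outcome` are excluded and counted.
#'
#' @param cases case table (see [read_case_table()] for the schema).
#' @param include_fetal_termination treat fetal termination as an event at
#'   age 0 (default `FALSE`: it is excluded, matching the endpoint list).
#' @return list with `data` (cases with `time` and `event` columns) and
#'   `n_excluded`.
#' @export
prepare_survival <- function(cases, include_fetal_termination = FALSE) {
  check_columns(cases, c("gene", "outcome", "age_outcome"), "case table")
  if (any(cases$age_outcome < 0, na.rm = TRUE) ||
      any(cases$age_onset < 0, na.rm = TRUE)) {
    cm_stop("ages must be non-negative", class = "cm_case_error")
  }
  events <- EVENT_OUTCOMES
  d <- cases
  d$event <- NA_integer_
  d$time <- as.numeric(d$age_outcome)
  d$event[d$outcome %in% events] <- 1L
  d$event[d$outcome == "alive"] <- 0L
  if (include_fetal_termination) {
    ft <- d$outcome == "fetal_termination"
    d$event[ft] <- 1L
    d$time[ft] <- 0
  }
  keep <- !is.na(d$event) & !is.na(d$time)
  list(data = d[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Kaplan-Meier freedom-from-event estimate
#'
#' Product-limit estimate of freedom from the adverse outcomes (death,
#' transplant, LVAD) with censoring at the latest report of survival.
#'
#' @inheritParams prepare_survival
#' @param by optional column to stratify by (e.g. `"gene"`).
#' @return a `survival::survfit` object; the prepared data and exclusion
#'   count are attached as attributes `data` and `n_excluded`.
#' @export
km_estimate <- function(cases, by = NULL, include_fetal_termination = FALSE) {
  prep <- prepare_survival(cases, include_fetal_termination)
  d <- prep$data
  if (nrow(d) == 0L) cm_stop("no cases with usable outcome data")
  fit <- if (is.null(by)) {
    survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  } else {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~", by))
    survival::survfit(f, data = d)
  }
  attr(fit, "data") <- d
  attr(fit, "n_excluded") <- prep$n_excluded
  fit
}

#' Survival probability at given times
#'
#' Convenience evaluation of a Kaplan-Meier step function.
#'
#' @param fit a `survfit` object from [km_estimate()] (unstratified).
#' @param times numeric vector of ages.
#' @return survival probabilities at `times`.
#' @export
km_surv_at <- function(fit, times) {
  s <- summary(fit, times = times, extend = TRUE)
  s$surv
}

#' Cox proportional-hazards contrast between causal genes
#'
#' Fits a Cox model with the causal gene as the only covariate (Efron tie
#' handling), using `baseline_gene` as the reference level, over genes
#' with at least `min_cases` outcome-complete cases. A gene with no
#' events (monotone likelihood) yields an infinite-HR sentinel with a
#' flag rather than an error.
#'
#' @inheritParams prepare_survival
#' @param baseline_gene reference gene (default `"NRAP"`).
#' @param min_cases minimum outcome-complete cases per gene (default 9,
#'   i.e. more than eight).
#' @return list with `fit` (the `coxph` object), `table` (per-gene `hr`,
#'   `ci_low`, `ci_high`, `p`, `n`, `monotone` flag) and
#'   `genes_excluded`.
#' @export
cox_hr <- function(cases, baseline_gene = "NRAP", min_cases = 9,
                   include_fetal_termination = FALSE) {
  prep <- prepare_survival(cases, include_fetal_termination)
  d <- prep$data
  counts <- table(d$gene)
  eligible <- names(counts)[counts >= min_cases]
  if (!(baseline_gene %in% eligible)) {
    cm_stop(sprintf("baseline gene '%s' has fewer than %d usable cases",
                    baseline_gene, min_cases))
  }
  if (length(eligible) < 2L) {
    cm_stop("need at least two genes passing the case-count filter")
  }
  d <- d[d$gene %in% eligible, , drop = FALSE]
  d$gene <- stats::relevel(factor(d$gene), ref = baseline_gene)
  fit <- survival::coxph(survival::Surv(time, event) ~ gene, data = d,
                         ties = "efron")
  sm <- summary(fit)
  genes <- sub("^gene", "", rownames(sm$coefficients))
  no_events <- vapply(genes, function(g) sum(d$event[d$gene == g]) == 0,
                      logical(1))
  if (any(no_events)) {
    cm_warn(sprintf("gene(s) with no events (monotone likelihood): %s",
                    paste(genes[no_events], collapse = ", ")))
  }
  tab <- data.frame(
    gene = genes,
    hr = sm$coefficients[, "exp(coef)"],
    ci_low = sm$conf.int[, "lower .95"],
    ci_high = sm$conf.int[, "upper .95"],
    p = sm$coefficients[, "Pr(>|z|)"],
    n = as.integer(counts[genes]),
    monotone = no_events,
    stringsAsFactors = FALSE
  )
  tab$hr[tab$monotone] <- ifelse(sm$coefficients[tab$monotone, "coef"] < 0,
                                 0, Inf)
  rownames(tab) <- NULL
  list(fit = fit, table = tab,
       baseline = baseline_gene,
       genes_excluded = setdiff(names(counts), eligible),
       n_excluded_cases = prep$n_excluded)
}

#' Two-sample z-test from summary statistics
#'
#' Two-tailed z-test comparing group means given summary statistics, as
#' used for onset comparisons against registry cohorts where only
#' mean +/- SD and n are published.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `z` and `p` (two-tailed).
#' @export
onset_ztest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) cm_stop("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) cm_stop("standard deviations must be positive")
  z <- (mean2 - mean1) / sqrt(sd1^2 / n1 + sd2^2 / n2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank-sum test for onset distributions
#'
#' Two-sided rank-sum test with midranks for ties. Uses exact enumeration
#' over all rank assignments when `n1 + n2 <= 12`, otherwise the normal
#' approximation with continuity correction.
#'
#' @param sample1,sample2 numeric vectors.
#' @return list with `statistic` (rank-sum W of sample 1, Mann-Whitney
#'   form), `p`, and `method` (`"exact"` or `"normal"`).
#' @export
onset_wilcoxon <- function(sample1, sample2) {
  x <- as.numeric(sample1); y <- as.numeric(sample2)
  if (length(x) == 0L || length(y) == 0L) cm_stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)  # midranks
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 12) {
    combos <- utils::combn(n1 + n2, n1)
    ws <- apply(combos, 2, function(i) sum(rk[i])) - n1 * (n1 + 1) / 2
    p_low <- mean(ws <= w_obs)
    p_high <- mean(ws >= w_obs)
    p <- min(1, 2 * min(p_low, p_high))
    return(list(statistic = w_obs, p = p, method = "exact"))
  }
  res <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  list(statistic = unname(res$statistic), p = res$p.value, method = "normal")
}

#' Outcome proportions for a case series
#'
#' Tallies reported outcomes over cases with known outcome (the
#' denominator policy) and the sex balance.
#'
#' @param cases case table.
#' @return list with `n_total`, `n_known`, `proportions` (named:
#'   `deceased`, `transplant_or_LVAD`, `alive`, `fetal_termination`, as
#'   fractions of known-outcome cases), `pct_female` (over cases with
#'   known sex) or `NA`.
#' @export
outcome_summary <- function(cases) {
  if (nrow(cases) == 0L) {
    return(list(n_total = 0L, n_known = 0L,
                proportions = c(deceased = NA_real_,
                                transplant_or_LVAD = NA_real_,
                                alive = NA_real_,
                                fetal_termination = NA_real_),
                pct_female = NA_real_))
  }
  known <- cases$outcome[!is.na(cases$outcome) & cases$outcome != "unknown"]
  n_known <- length(known)
  prop <- function(x) if (n_known == 0L) NA_real_ else sum(known %in% x) / n_known
  pct_female <- if ("sex" %in% names(cases)) {
    s <- cases$sex[!is.na(cases$sex)]
    if (length(s) == 0L) NA_real_ else 100 * mean(s %in% c("F", "female"))
  } else NA_real_
  list(
    n_total = nrow(cases), n_known = n_known,
    proportions = c(
      deceased = prop("deceased"),
      transplant_or_LVAD = prop(c("transplant", "LVAD")),
      alive = prop("alive"),
      fetal_termination = prop("fetal_termination")
    ),
    pct_female = pct_female
  )
}

#' ClinGen-style estimated LOD score for a pedigree
#'
#' Estimates a segregation LOD score from pedigree counts when a reported
#' LOD is unavailable. Eligibility follows gene-curation practice: at
#' least `min_affected` affected biallelic cases, genotypes known for
#' affected and unaffected individuals, and demonstrated recessive
#' inheritance (heterozygous parent(s)); otherwise a refusal (not a zero
#' score) is returned. The default arithmetic credits each affected
#' individual beyond the proband(s) with `log10(4)` (probability 1/4 of a
#' biallelic genotype per meiosis under recessive segregation) and each
#' genotyped unaffected non-carrier-or-heterozygous relative with
#' `log10(4/3)`; it is override-able via the `log10_*` arguments.
#'
#' @param n_affected_biallelic affected individuals with the biallelic
#'   genotype.
#' @param n_unaffected unaffected genotyped relatives who are
#'   non-carriers or heterozygous.
#' @param probands number of probands (ascertainment-corrected; default 1).
#' @param parents_het_confirmed at least one parent demonstrated
#'   heterozygous.
#' @param genotypes_known genotypes available for affected and unaffected
#'   individuals.
#' @param min_affected eligibility minimum (default 3).
#' @param log10_affected,log10_unaffected per-individual increments.
#' @return list with `eligible` (logical), `lod` (`NA` when refused) and
#'   `reason` (refusal reason or `NA`).
#' @export
estimate_lod <- function(n_affected_biallelic, n_unaffected = 0, probands = 1,
                         parents_het_confirmed = TRUE, genotypes_known = TRUE,
                         min_affected = 3,
                         log10_affected = log10(4),
                         log10_unaffected = log10(4 / 3)) {
  if (n_affected_biallelic < probands || probands < 1) {
    cm_stop("need n_affected_biallelic >= probands >= 1")
  }
  refuse <- function(reason) list(eligible = FALSE, lod = NA_real_,
                                  reason = reason)
  if (n_affected_biallelic < min_affected) {
    return(refuse(sprintf("fewer than %d affected biallelic cases",
                          min_affected)))
  }
  if (!genotypes_known) return(refuse("genotypes not known for affected and unaffected individuals"))
  if (!parents_het_confirmed) return(refuse("recessive inheritance not demonstrated (no heterozygous parent)"))
  lod <- (n_affected_biallelic - probands) * log10_affected +
    n_unaffected * log10_unaffected
  list(eligible = TRUE, lod = lod, reason = NA_character_)
}

#' Classify biallelic zygosity
#'
#' One variant at dosage 2 is homozygous. Two variants in the same gene
#' are compound heterozygous only with explicit trans evidence: each
#' parent heterozygous for exactly one of the two variants, or direct
#' phase showing trans. Two variants without such proof are double
#' heterozygous; contradictory parental genotypes (one parent carrying
#' both variants) also yield double heterozygous, with a warning.
#'
#' @param dosages named numeric vector of the proband's dosages for the
#'   candidate variants (1 or 2 entries).
#' @param mother,father optional named 0/1/2 dosage vectors for the
#'   parents over the same variants.
#' @param phase optional direct phase evidence: `"trans"`, `"cis"` or
#'   `"unphased"`.
#' @return one of `"homozygous"`, `"compound_het"`, `"double_het"`.
#' @export
classify_zygosity <- function(dosages, mother = NULL, father = NULL,
                              phase = NULL) {
  if (length(dosages) < 1L) cm_stop("at least one variant required")
  if (length(dosages) == 1L) {
    if (dosages >= 2) return("homozygous")
    cm_stop("single heterozygous variant is not a biallelic genotype")
  }
  if (any(dosages >= 2)) return("homozygous")
  if (length(dosages) != 2L) {
    cm_stop("zygosity classification expects one or two variants")
  }
  if (!is.null(phase) && identical(phase, "trans")) return("compound_het")
  if (!is.null(mother) && !is.null(father)) {
    v <- names(dosages)
    m <- mother[v] >= 1
    f <- father[v] >= 1
    contradictory <- (all(m) || all(f))
    if (contradictory) {
      cm_warn("same parent carries both variants; trans configuration unproven")
      return("double_het")
    }
    if (sum(m) == 1L && sum(f) == 1L && !any(m & f)) {
      return("compound_het")
    }
  }
  "double_het"
}
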