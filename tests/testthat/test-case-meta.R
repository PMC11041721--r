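make_cases <- function(gene, times, events, onset = 0.5) {
  data.frame(
    case_id = paste0(gene, "_", seq_along(times)),
    gene = gene, phenotype = "DCM", sex = "F",
    zygosity = "homozygous", variant_class = "PTV",
    age_onset = onset,
    outcome = ifelse(events == 1, "deceased", "alive"),
    age_outcome = times, stringsAsFactors = FALSE
  )
}

test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  cases <- make_cases("G", times = c(1, 4, 5), events = c(1, 1, 0))
  fit <- km_estimate(cases)
  expect_equal(km_surv_at(fit, c(2, 4)), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # all censored: flat at 1
  flat <- km_estimate(make_cases("G", c(2, 3, 9), c(0, 0, 0)))
  expect_equal(km_surv_at(flat, c(1, 5, 10)), c(1, 1, 1))
  # single case with an event: survival jumps 1 -> 0 at the event age
  single <- km_estimate(make_cases("G", 2, 1))
  expect_equal(km_surv_at(single, c(1.99, 2)), c(1, 0))
})

test_that("Kaplan-Meier equals a brute-force risk-set computation", {
  withr::with_seed(111, {
    for (i in 1:10) {
      k <- sample(5:20, 1)
      times <- round(rexp(k, 0.1), 1)
      events <- rbinom(k, 1, 0.6)
      fit <- km_estimate(make_cases("G", times, events))
      at <- sort(unique(times))
      expect_equal(km_surv_at(fit, at),
                   vapply(at, function(t) km_oracle(times, events, t),
                          numeric(1)),
                   tolerance = 1e-12)
    }
  })
})

test_that("survival preparation excludes unknown outcomes and validates ages", {
  cases <- make_cases("G", c(1, 2, 3), c(1, 0, 1))
  cases$outcome[2] <- "unknown"
  prep <- prepare_survival(cases)
  expect_equal(prep$n_excluded, 1)
  expect_equal(nrow(prep$data), 2)
  bad <- make_cases("G", c(-1, 2), c(1, 1))
  expect_error(prepare_survival(bad), class = "cm_case_error")
  # fetal termination: excluded by default, an event at age 0 when enabled
  ft <- make_cases("G", c(1, 2), c(1, 1))
  ft$outcome[2] <- "fetal_termination"
  expect_equal(nrow(prepare_survival(ft)$data), 1)
  with_ft <- prepare_survival(ft, include_fetal_termination = TRUE)$data
  expect_equal(with_ft$time[with_ft$outcome == "fetal_termination"], 0)
})

test_that("Cox gene contrasts recover simulated hazard ratios", {
  spec <- case_series_spec(data.frame(
    gene = c("NRAP", "FASTG"), n = 250,
    onset_meanlog = log(5), onset_sdlog = 0.5,
    event_rate = c(0.05, 0.20), phenotype = "DCM"),
    censor_range = c(10, 60))
  withr::with_seed(112, {
    cover <- replicate(40, {
      cases <- simulate_case_series(spec, seed = sample.int(1e6, 1))
      tab <- cox_hr(cases, baseline_gene = "NRAP", min_cases = 9)$table
      row <- tab[tab$gene == "FASTG", ]
      row$ci_low <= 4 && 4 <= row$ci_high
    })
    expect_gte(mean(cover), 0.85)
  })
})

test_that("Cox contrast covers 1 for identical event-time distributions", {
  spec <- case_series_spec(data.frame(
    gene = c("NRAP", "GENE2"), n = 150,
    onset_meanlog = log(5), onset_sdlog = 0.5,
    event_rate = 0.1, phenotype = "DCM"))
  cases <- simulate_case_series(spec, seed = 113)
  tab <- cox_hr(cases, baseline_gene = "NRAP")$table
  row <- tab[tab$gene == "GENE2", ]
  expect_true(row$ci_low <= 1 && 1 <= row$ci_high)
})

test_that("Cox contrast excludes genes below the case-count floor and flags no-event genes", {
  spec <- case_series_spec(data.frame(
    gene = c("NRAP", "BIG", "TINY"), n = c(30, 30, 4),
    onset_meanlog = log(5), onset_sdlog = 0.5,
    event_rate = 0.1, phenotype = "DCM"))
  cases <- simulate_case_series(spec, seed = 114)
  res <- cox_hr(cases, baseline_gene = "NRAP", min_cases = 9)
  expect_true("TINY" %in% res$genes_excluded)
  expect_false("TINY" %in% res$table$gene)
  # a gene with no events gives an infinite/zero HR sentinel with a flag
  noev <- make_cases("NOEV", times = rep(50, 12), events = rep(0, 12))
  base <- make_cases("NRAP", times = seq(1, 12), events = rep(1, 12))
  expect_warning(res2 <- cox_hr(rbind(noev, base), baseline_gene = "NRAP"),
                 "monotone")
  row <- res2$table[res2$table$gene == "NOEV", ]
  expect_true(row$monotone)
  expect_true(row$hr %in% c(0, Inf))
})

test_that("two-sample z-test matches the normal oracle and is antisymmetric", {
  res <- onset_ztest(0, 1, 100, 0.2, 1, 100)
  z_expect <- 0.2 / sqrt(2 / 100)
  expect_equal(res$z, z_expect, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-z_expect), tolerance = 1e-10)
  flip <- onset_ztest(0.2, 1, 100, 0, 1, 100)
  expect_equal(flip$z, -res$z)
  expect_equal(flip$p, res$p)
  same <- onset_ztest(5, 2, 50, 5, 2, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(onset_ztest(1, 0, 10, 2, 1, 10), "positive")
})

test_that("Wilcoxon rank-sum uses exact enumeration for small samples", {
  res <- onset_wilcoxon(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$method, "exact")
  expect_equal(res$p, 0.1)  # 2 * 1/20 over all C(6,3) rank assignments
  ident <- onset_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p, 1)
  # ties via midranks equal the enumeration oracle
  x <- c(1, 1, 2); y <- c(1, 2, 2)
  res_t <- onset_wilcoxon(x, y)
  rk <- rank(c(x, y))
  combos <- combn(6, 3)
  ws <- apply(combos, 2, function(i) sum(rk[i])) - 6
  w_obs <- sum(rk[1:3]) - 6
  p_oracle <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  expect_equal(res_t$p, p_oracle)
})

test_that("Wilcoxon large-sample branch matches the continuity-corrected normal test", {
  withr::with_seed(115, {
    x <- rexp(30); y <- rexp(40) + 0.3
    res <- onset_wilcoxon(x, y)
    expect_equal(res$method, "normal")
    expect_equal(res$p,
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  })
})

test_that("outcome summary tallies proportions over known outcomes", {
  cases <- data.frame(
    case_id = 1:10, gene = "G",
    sex = c(rep("F", 4), rep("M", 6)),
    outcome = c(rep("deceased", 4), rep("alive", 3), "transplant", "LVAD",
                "unknown"),
    stringsAsFactors = FALSE
  )
  s <- outcome_summary(cases)
  expect_equal(s$n_known, 9)
  expect_equal(unname(s$proportions["deceased"]), 4 / 9)
  expect_equal(unname(s$proportions["transplant_or_LVAD"]), 2 / 9)
  expect_equal(s$pct_female, 40)
  empty <- outcome_summary(cases[0, ])
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$proportions["deceased"]))
})

test_that("estimated LOD scores follow the segregation formula with eligibility gates", {
  r <- estimate_lod(3, n_unaffected = 0, probands = 1)
  expect_true(r$eligible)
  expect_equal(r$lod, 2 * log10(4), tolerance = 1e-12)
  big <- estimate_lod(13, n_unaffected = 0, probands = 1)
  expect_equal(big$lod, 12 * log10(4), tolerance = 1e-12)
  withunaff <- estimate_lod(4, n_unaffected = 6, probands = 1)
  expect_equal(withunaff$lod, 3 * log10(4) + 6 * log10(4 / 3))
  # refusals, not zeros
  too_few <- estimate_lod(2, parents_het_confirmed = TRUE)
  expect_false(too_few$eligible)
  expect_true(is.na(too_few$lod))
  expect_match(too_few$reason, "fewer than 3")
  no_parents <- estimate_lod(5, parents_het_confirmed = FALSE)
  expect_false(no_parents$eligible)
})

test_that("zygosity classification demands explicit trans evidence for compound hets", {
  expect_equal(classify_zygosity(c(v1 = 2)), "homozygous")
  expect_equal(
    classify_zygosity(c(v1 = 1, v2 = 1),
                      mother = c(v1 = 1, v2 = 0),
                      father = c(v1 = 0, v2 = 1)),
    "compound_het")
  expect_equal(classify_zygosity(c(v1 = 1, v2 = 1)), "double_het")
  expect_equal(classify_zygosity(c(v1 = 1, v2 = 1), phase = "trans"),
               "compound_het")
  expect_equal(classify_zygosity(c(v1 = 1, v2 = 1), phase = "unphased"),
               "double_het")
  # contradictory parental genotypes never yield compound het
  expect_warning(
    cls <- classify_zygosity(c(v1 = 1, v2 = 1),
                             mother = c(v1 = 1, v2 = 1),
                             father = c(v1 = 0, v2 = 0)),
    "same parent")
  expect_equal(cls, "double_het")
})
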