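test_that("PC screening keeps PCs 1-4 always and screens 5-20 marginally", {
  withr::with_seed(31, {
    n <- 3000
    d <- data.frame(sample_id = seq_len(n), age = runif(n, 40, 69),
                    sex = rbinom(n, 1, 0.5))
    d$age2 <- d$age^2
    for (k in 1:8) d[[paste0("PC", k)]] <- rnorm(n)
    # PC6 strongly associated with the trait, PC5/7/8 pure noise
    d$disease <- rbinom(n, 1, plogis(-1 + 1.5 * d$PC6))
    null <- fit_null(d, "disease", family = "binary",
                     base_covariates = c("age", "age2", "sex"), pc_max = 8)
    expect_true(all(paste0("PC", 1:4) %in% null$included_pcs))
    expect_true("PC6" %in% null$included_pcs)
  })
})

test_that("quantitative null without kinship reduces to ordinary least squares", {
  withr::with_seed(32, {
    n <- 500
    d <- data.frame(sample_id = seq_len(n), age = runif(n, 40, 69),
                    sex = rbinom(n, 1, 0.5), PC1 = rnorm(n))
    d$age2 <- d$age^2
    d$y <- 0.1 * d$PC1 + rnorm(n)
    null <- fit_null(d, "y", family = "quantitative",
                     base_covariates = c("age", "age2", "sex"), pc_max = 1,
                     pc_always = 1)
    ols <- lm(y ~ age + age2 + sex + PC1, data = d)
    expect_equal(unname(null$coefficients), unname(coef(ols)),
                 tolerance = 1e-8)
  })
})

test_that("quantitative score test matches the exact regression coefficient and t-test", {
  withr::with_seed(35, {
    n <- 800
    d <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                    age = runif(n, 40, 69), sex = rbinom(n, 1, 0.5))
    d$age2 <- d$age^2
    g <- setNames(as.integer(runif(n) < 0.05), d$sample_id)
    # residual SD far from 1 so scale errors cannot hide
    d$y <- 0.2 * d$sex + 5 * g + rnorm(n, sd = 4)
    null <- fit_null(d, "y", family = "quantitative",
                     base_covariates = c("age", "age2", "sex"))
    st <- score_test(null, g)
    res <- run_gene_trait(null, list(collapse_carriers(
      matrix(g, ncol = 1, dimnames = list(names(g), "v1")), "v1",
      gene = "G", mask_id = "m")), cmac_min = 1)
    fit <- lm(y ~ age + age2 + sex + g, data = cbind(d, g = g))
    expect_equal(res$effect, unname(coef(fit)["g"]), tolerance = 1e-6)
    # under a null carrier the score z matches the regression t closely
    # (under an alternative the score test's null residual variance is
    # larger by construction)
    g0 <- setNames(as.integer(runif(n) < 0.05), d$sample_id)
    st0 <- score_test(null, g0)
    fit0 <- lm(y ~ age + age2 + sex + g0, data = cbind(d, g0 = g0))
    expect_equal(st0$z, unname(coef(summary(fit0))["g0", "t value"]),
                 tolerance = 0.02)
  })
})

test_that("a kinship matrix with no related pairs leaves p-values unchanged", {
  withr::with_seed(33, {
    n <- 400
    d <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                    age = runif(n, 40, 69), sex = rbinom(n, 1, 0.5))
    d$age2 <- d$age^2
    d$disease <- rbinom(n, 1, 0.3)
    g <- setNames(integer(n), d$sample_id)
    g[sample(n, 30)] <- 1L
    plain <- fit_null(d, "disease", family = "binary",
                      base_covariates = c("age", "age2", "sex"))
    # triples table with zero informative pairs
    kin <- data.frame(id1 = character(0), id2 = character(0),
                      coefficient = numeric(0))
    mixed <- fit_null(d, "disease", family = "binary",
                      base_covariates = c("age", "age2", "sex"), kinship = kin)
    expect_equal(mixed$tau, 0)
    expect_equal(mixed$mu, plain$mu, tolerance = 1e-10)
    expect_equal(score_test(mixed, g)$p_normal, score_test(plain, g)$p_normal,
                 tolerance = 1e-8)
  })
})

test_that("mixed-model machinery with real related pairs runs and stays calibrated", {
  withr::with_seed(34, {
    spec <- cohort_spec(n_samples = 300, prevalence = 0.3,
                        variants = default_variant_panel(maf = 0.05),
                        family_blocks = rep(2, 60))
    sim <- simulate_cohort(spec, seed = 9)
    null <- fit_null(sim$phenotypes, "disease", family = "binary",
                     kinship = sim$kinship)
    expect_true(null$has_kinship)
    expect_gte(null$tau, 0)
    g <- setNames(as.integer(rowSums(sim$genotypes[, 1:2]) > 0),
                  rownames(sim$genotypes))
    st <- score_test(null, g)
    expect_true(st$p_normal > 0 && st$p_normal <= 1)
  })
})

test_that("score test handles degenerate carrier vectors", {
  d <- balanced_null(500)
  null <- fit_null(d, "disease", family = "binary")
  st <- score_test(null, setNames(integer(500), d$sample_id))
  expect_true(st$degenerate)
  expect_equal(st$p_normal, 1)
})

test_that("score test is calibrated under the null and tracks the LRT", {
  d <- balanced_null(5000, seed = 41)
  null <- fit_null(d, "disease", family = "binary")
  withr::with_seed(42, {
    n_rep <- 400
    hits <- 0
    for (i in seq_len(n_rep)) {
      g <- setNames(integer(5000), d$sample_id)
      g[sample(5000, 50)] <- 1L
      if (score_test(null, g)$p_normal < 0.05) hits <- hits + 1
    }
    ci <- binom.test(hits, n_rep, 0.05)$conf.int
    expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
  })
  # large balanced sample: score p agrees with the likelihood-ratio p
  withr::with_seed(43, {
    g <- setNames(integer(5000), d$sample_id)
    carriers <- sample(5000, 300)
    g[carriers] <- 1L
    d2 <- d
    d2$disease[carriers] <- rbinom(300, 1, 0.65)
    null2 <- fit_null(d2, "disease", family = "binary")
    p_score <- score_test(null2, g)$p_normal
    full <- glm(d2$disease ~ g + age + age2 + sex + PC1 + PC2 + PC3 + PC4,
                data = d2, family = binomial())
    red <- glm(d2$disease ~ age + age2 + sex + PC1 + PC2 + PC3 + PC4,
               data = d2, family = binomial())
    p_lrt <- pchisq(red$deviance - full$deviance, 1, lower.tail = FALSE)
    expect_lt(abs(log10(p_score) - log10(p_lrt)), 0.1 * abs(log10(p_lrt)))
  })
})

test_that("saddlepoint p-value matches the normal p for balanced common carriers", {
  withr::with_seed(51, {
    n <- 4000
    d <- balanced_null(n, seed = 51)
    null <- fit_null(d, "disease", family = "binary")
    g <- setNames(integer(n), d$sample_id)
    carriers <- sample(n, 400)
    g[carriers] <- 1L
    d$disease[carriers] <- rbinom(400, 1, 0.58)
    null <- fit_null(d, "disease", family = "binary")
    sp <- spa_pvalue(null, g, switch = 0)  # force the SPA branch
    expect_false(sp$fallback)
    expect_lt(abs(sp$p_spa - sp$p_normal) / sp$p_normal, 0.05)
  })
})

test_that("saddlepoint branch is continuous and the fallback is exact", {
  d <- balanced_null(3000, seed = 52)
  null <- fit_null(d, "disease", family = "binary")
  withr::with_seed(52, {
    g <- setNames(integer(3000), d$sample_id)
    g[sample(3000, 40)] <- 1L
    st <- score_test(null, g)
    # fallback regime: identical to normal p
    sp <- spa_pvalue(null, g, switch = 1e6)
    expect_identical(sp$p_spa, sp$p_normal)
    expect_true(sp$fallback)
    # SPA branch continuity: nearby switch settings around the observed |z|
    # cannot change the SPA-branch p-value
    spa_lo <- spa_pvalue(null, g, switch = abs(st$z) * 0.999)
    spa_lo2 <- spa_pvalue(null, g, switch = abs(st$z) * 0.998)
    expect_equal(spa_lo$p_spa, spa_lo2$p_spa, tolerance = 1e-6)
  })
})

test_that("saddlepoint corrects the anti-conservative normal tail under imbalance", {
  # 1:50 imbalance, rare carriers: tail calibration at alpha = 0.01 over
  # replicated null carriers (the full-strength 1:300 check runs in the
  # acceptance suite)
  withr::with_seed(53, {
    n <- 10000
    d <- data.frame(sample_id = sprintf("S%05d", 1:n),
                    age = runif(n, 40, 69), sex = rbinom(n, 1, 0.5))
    d$age2 <- d$age^2
    d$disease <- rbinom(n, 1, 1 / 51)
    null <- fit_null(d, "disease", family = "binary",
                     base_covariates = c("age", "age2", "sex"))
    n_rep <- 500
    p_spa <- p_norm <- numeric(n_rep)
    for (i in seq_len(n_rep)) {
      g <- setNames(integer(n), d$sample_id)
      g[sample(n, 20)] <- 1L
      sp <- spa_pvalue(null, g)
      p_spa[i] <- sp$p_spa
      p_norm[i] <- sp$p_normal
    }
    alpha <- 0.01
    hits_spa <- sum(p_spa < alpha)
    ci <- binom.test(hits_spa, n_rep, alpha)$conf.int
    expect_true(ci[1] <= alpha && alpha <= ci[2])
    expect_gte(sum(p_norm < alpha), hits_spa)
  })
})

test_that("Firth regression gives finite estimates under complete separation", {
  withr::with_seed(61, {
    y <- c(rep(1, 5), rbinom(995, 1, 0.3))
    g <- c(rep(1, 5), rep(0, 995))
    fr <- firth_refit(y, NULL, g)
    expect_true(is.finite(fr$log_odds))
    expect_gt(fr$log_odds, 0)
    expect_true(all(is.finite(fr$ci)))
  })
})

test_that("Firth estimate matches a grid-search penalized-likelihood oracle", {
  # 2x2 table: carriers 10/5 case/control, non-carriers 490/495
  y <- c(rep(1, 10), rep(0, 5), rep(1, 490), rep(0, 495))
  g <- c(rep(1, 15), rep(0, 985))
  fit <- firth_refit(y, NULL, g)
  pll <- function(b0, b1) {
    eta <- b0 + b1 * g
    mu <- plogis(eta)
    X <- cbind(1, g)
    I <- crossprod(X * sqrt(mu * (1 - mu)))
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(I)$modulus[1]
  }
  b1_grid <- seq(fit$log_odds - 0.5, fit$log_odds + 0.5, by = 1e-4)
  best <- b1_grid[which.max(vapply(
    b1_grid,
    function(b1) optimize(function(b0) pll(b0, b1), c(-5, 5),
                          maximum = TRUE)$objective,
    numeric(1)))]
  expect_equal(fit$log_odds, best, tolerance = 5e-4)
})

test_that("Firth penalized likelihood increases monotonically across iterations", {
  withr::with_seed(62, {
    n <- 300
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.05))
    y <- rbinom(n, 1, plogis(-2 + 2 * X[, 3]))
    fit <- firth_logistic(X, y)
    expect_true(all(diff(fit$pll_trace) >= -1e-10))
  })
})

test_that("Firth estimates are unbiased at zero effect", {
  withr::with_seed(63, {
    n <- 2000
    est <- replicate(150, {
      g <- rbinom(n, 1, 0.02)
      y <- rbinom(n, 1, 0.1)
      firth_refit(y, NULL, g)$log_odds
    })
    se_mc <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est)), 3 * se_mc)
  })
})

test_that("run_gene_trait applies the CMAC filter and the Firth trigger rule", {
  withr::with_seed(71, {
    v <- default_variant_panel(maf = 0.005)
    v$popmax <- 1e-6
    spec <- cohort_spec(n_samples = 4000, prevalence = 0.2,
                        carrier_log_or = log(4), variants = v)
    sim <- simulate_cohort(spec, seed = 72)
    null <- fit_null(sim$phenotypes, "disease", family = "binary")
    burdens <- build_burdens(sim$genotypes, sim$annotations, "GENE1")
    res <- run_gene_trait(null, burdens, cmac_min = 20)
    expect_equal(nrow(res), 22)
    expect_true(all(res$filtered == (res$cmac < 20)))
    # Firth refits exactly where p < 0.05 and OR > 1 among unfiltered masks
    trigger <- !res$filtered & res$p < 0.05 & res$effect > 0 &
      !is.na(res$effect)
    expect_true(all(res$firth_applied[res$filtered] == FALSE))
    expect_true(any(res$firth_applied))
    # a filtered mask never reaches the omnibus
    om <- omnibus_table(res)
    expect_equal(om$n_masks_used, sum(!res$filtered))
  })
})

test_that("per-mask p-values are uniform under phenotype permutation", {
  withr::with_seed(81, {
    n <- 2000
    d <- balanced_null(n, seed = 81)
    g <- setNames(integer(n), d$sample_id)
    g[sample(n, 60)] <- 1L
    n_perm <- 400
    pvals <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      d2 <- d
      d2$disease <- sample(d$disease)
      null <- fit_null(d2, "disease", family = "binary")
      pvals[i] <- score_test(null, g)$p_normal
    }
    expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  })
})

test_that("planted carrier odds ratios are recovered by the Firth refit", {
  withr::with_seed(91, {
    v <- default_variant_panel(maf = 0.01)
    v$popmax <- 1e-6
    spec <- cohort_spec(n_samples = 5000, prevalence = 0.1,
                        carrier_log_or = log(3), variants = v)
    cover <- replicate(30, {
      sim <- simulate_cohort(spec, seed = sample.int(1e6, 1))
      null <- fit_null(sim$phenotypes, "disease", family = "binary")
      b <- collapse_carriers(sim$genotypes, sim$truth$effect_variants,
                             gene = "GENE1", mask_id = "ptv")
      fr <- firth_refit(null$y, null$X[, -1], sim$truth$carrier)
      fr$ci[1] <= log(3) && log(3) <= fr$ci[2]
    })
    expect_gte(mean(cover), 0.8)
  })
})
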