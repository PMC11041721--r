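# Shared fixture builders, all generated in code.

# Small annotated variant table covering all consequence classes.
toy_annotations <- function() {
  annotate_variants(data.frame(
    variant_id = paste0("1:", 1:6 * 100, ":A:T"),
    gene = "GENE1",
    consequence = c("stop_gained", "frameshift", "missense", "missense",
                    "stop_gained", "splice_donor"),
    lof_confidence = c("high", "high", "not_lof", "not_lof", "flagged",
                       "high"),
    nmd_escape = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    n_damaging = c(NA, NA, 14, 2, NA, NA),
    n_predicting = c(NA, NA, 28, 10, NA, NA),
    nfe = c(0, 0.0005, 0.00005, 0.002, 0, 0),
    sas = c(0.00002, 0, 0, 0.004, 0, 0),
    stringsAsFactors = FALSE
  ))
}

# Tiny genotype matrix matching toy_annotations().
toy_genotypes <- function(n = 20) {
  ids <- paste0("1:", 1:6 * 100, ":A:T")
  G <- matrix(0, n, 6, dimnames = list(sprintf("S%03d", 1:n), ids))
  G[1, 1] <- 1   # PTV carrier
  G[2, 1] <- 2   # homozygous PTV
  G[3, 3] <- 1   # damaging missense (score 0.5)
  G[4, 2] <- 1   # second PTV
  G[5, 4] <- 1   # common missense, score 0.2
  G
}

# Brute-force product-limit estimator over risk sets.
km_oracle <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  for (t in ut[ut <= at]) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Brute-force BH step-up.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

# Balanced binary cohort with a fitted null model, shared by association
# tests.
balanced_null <- function(n = 2000, seed = 7) {
  withr::with_seed(seed, {
    d <- data.frame(
      sample_id = sprintf("S%05d", seq_len(n)),
      age = runif(n, 40, 69), sex = rbinom(n, 1, 0.5),
      PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n), PC4 = rnorm(n)
    )
    d$age2 <- d$age^2
    d$disease <- rbinom(n, 1, 0.5)
    d
  })
}
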