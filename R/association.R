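# Null trait models, score tests with saddlepoint approximation, and
# Firth bias-reduced effect re-estimation.

#' Fit the null trait model
#'
#' Fits the covariate-only model against which carrier burdens are score
#' tested. Fixed effects are the base covariates (by default age, age^2,
#' sex, sequencing tranche), ancestry principal components 1-4, and each
#' of PCs 5-20 whose marginal single-covariate association with the trait
#' has P below `pc_screen_alpha`. Rows with missing values in the trait or
#' any candidate covariate are dropped (complete-case) and counted.
#'
#' With a sparse kinship matrix, a single additional variance component is
#' estimated (penalized quasi-likelihood for binary traits, REML for
#' quantitative ones). A kinship matrix with no off-diagonal entries
#' carries no relatedness information that is separable from the residual,
#' so the variance component is fixed at zero and the fit reduces exactly
#' to the ordinary regression.
#'
#' @param data data.frame holding the trait and covariates.
#' @param trait name of the trait column (0/1 for binary).
#' @param family `"binary"` or `"quantitative"`.
#' @param base_covariates names of always-included covariate columns;
#'   columns absent from `data` are silently skipped (so small synthetic
#'   designs work), but at least one column or PC must remain.
#' @param pc_prefix prefix of principal-component columns (`PC1`, ...).
#' @param pc_always number of leading PCs always included (default 4).
#' @param pc_max highest candidate PC (default 20).
#' @param pc_screen_alpha marginal screening level for PCs
#'   `pc_always+1 .. pc_max` (default 0.05).
#' @param kinship optional sparse symmetric kinship matrix
#'   (`Matrix::sparseMatrix` with sample ids as dimnames) or a data.frame
#'   of triples `id1, id2, coefficient`.
#' @param sample_id name of the sample id column (default `"sample_id"`).
#' @return object of class `cm_null_model`.
#' @export
fit_null <- function(data, trait, family = c("binary", "quantitative"),
                     base_covariates = c("age", "age2", "sex", "tranche"),
                     pc_prefix = "PC", pc_always = 4, pc_max = 20,
                     pc_screen_alpha = 0.05, kinship = NULL,
                     sample_id = "sample_id") {
  family <- match.arg(family)
  check_columns(data, trait, "phenotype table")
  base_covariates <- intersect(base_covariates, names(data))
  pc_all <- paste0(pc_prefix, seq_len(pc_max))
  pc_present <- intersect(pc_all, names(data))
  pc_base <- intersect(paste0(pc_prefix, seq_len(pc_always)), pc_present)
  pc_candidates <- setdiff(pc_present, pc_base)

  cols <- c(trait, base_covariates, pc_present)
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  y <- as.numeric(d[[trait]])
  if (family == "binary" && !all(y %in% c(0, 1))) {
    cm_stop(sprintf("binary trait '%s' must be coded 0/1", trait))
  }

  # Marginal screening of PCs beyond the always-included block.
  screened <- character(0)
  for (pc in pc_candidates) {
    x <- d[[pc]]
    p <- if (family == "binary") {
      fit <- stats::glm(y ~ x, family = stats::binomial())
      stats::coef(summary(fit))["x", "Pr(>|z|)"]
    } else {
      fit <- stats::lm(y ~ x)
      stats::coef(summary(fit))["x", "Pr(>|t|)"]
    }
    if (is.finite(p) && p < pc_screen_alpha) screened <- c(screened, pc)
  }
  covars <- c(base_covariates, pc_base, screened)

  X <- cbind(`(Intercept)` = 1,
             as.matrix(d[, covars, drop = FALSE]))
  # Drop aliased columns so the design has full rank.
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }

  K <- normalize_kinship(kinship, ids = if (sample_id %in% names(d))
    as.character(d[[sample_id]]) else rownames(d))
  has_kinship <- !is.null(K) && length(K@x) > 0 &&
    any(K[lower.tri(K)] != 0)

  if (!has_kinship) {
    fit <- if (family == "binary") {
      stats::glm.fit(X, y, family = stats::binomial())
    } else {
      stats::lm.fit(X, y)
    }
    if (family == "binary") {
      beta <- fit$coefficients
      mu <- fit$fitted.values
      if (!fit$converged || any(mu < 1e-12) || any(mu > 1 - 1e-12)) {
        # Separation in the null covariate fit: ridge-stabilized refit.
        cm_warn("null model fit unstable (possible separation); using ridge-stabilized fit")
        rf <- ridge_logistic(X, y, lambda = 1e-4)
        beta <- rf$beta; mu <- rf$mu
      }
      w <- mu * (1 - mu)
      sigma2 <- NA_real_
    } else {
      beta <- fit$coefficients
      mu <- X %*% beta
      mu <- as.numeric(mu)
      sigma2 <- sum((y - mu)^2) / (length(y) - ncol(X))
      w <- rep(1 / sigma2, length(y))
    }
    tau <- 0
    P <- NULL
    Ytilde <- NULL
  } else {
    mm <- fit_null_mixed(X, y, K, family)
    beta <- mm$beta; mu <- mm$mu; w <- mm$w; sigma2 <- mm$sigma2
    tau <- mm$tau; P <- mm$P; Ytilde <- mm$Ytilde
  }

  XtWX <- crossprod(X * sqrt(w))
  structure(list(
    trait = trait, family = family,
    covariates = covars, included_pcs = c(pc_base, screened),
    n = length(y), n_dropped = n_dropped,
    sample_ids = if (sample_id %in% names(d)) as.character(d[[sample_id]])
                 else rownames(d),
    y = y, X = X, coefficients = beta, mu = mu, w = w,
    sigma2 = sigma2, tau = tau, has_kinship = has_kinship,
    P = P, Ytilde = Ytilde,
    XtWX_inv = solve(XtWX),
    Xtr = as.numeric(crossprod(X, y - mu))
  ), class = "cm_null_model")
}

#' @export
print.cm_null_model <- function(x, ...) {
  cat(sprintf("<cm_null_model> trait=%s family=%s n=%d covariates=%d tau=%.4g\n",
              x$trait, x$family, x$n, length(x$covariates), x$tau))
  invisible(x)
}

# Ridge-stabilized logistic IRLS, used as a fallback under separation in
# the null covariate fit.
ridge_logistic <- function(X, y, lambda = 1e-4, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X * sqrt(w)) + diag(lambda, ncol(X))
    beta_new <- solve(XtWX, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  mu <- stats::plogis(as.numeric(X %*% beta))
  list(beta = as.numeric(beta), mu = pmin(pmax(mu, 1e-12), 1 - 1e-12))
}

# Convert kinship triples to a sparse symmetric matrix aligned to ids.
normalize_kinship <- function(kinship, ids) {
  if (is.null(kinship)) return(NULL)
  if (is.data.frame(kinship)) {
    check_columns(kinship, c("id1", "id2", "coefficient"), "kinship triples")
    i <- match(as.character(kinship$id1), ids)
    j <- match(as.character(kinship$id2), ids)
    ok <- !is.na(i) & !is.na(j)
    K <- Matrix::sparseMatrix(
      i = c(i[ok], j[ok]), j = c(j[ok], i[ok]),
      x = rep(kinship$coefficient[ok], 2),
      dims = c(length(ids), length(ids)),
      use.last.ij = TRUE
    )
    Matrix::diag(K) <- 0.5
    return(methods::as(K, "symmetricMatrix"))
  }
  if (!is.null(rownames(kinship))) {
    idx <- match(ids, rownames(kinship))
    if (any(is.na(idx))) cm_stop("kinship matrix missing some samples")
    kinship <- kinship[idx, idx]
  }
  methods::as(Matrix::Matrix(kinship, sparse = TRUE), "symmetricMatrix")
}

# Single-variance-component mixed null model. Dense linear algebra sized
# for cohorts up to a few thousand samples, which is the regime in which
# the kinship mode is exercised here; the no-kinship path scales to
# biobank n.
fit_null_mixed <- function(X, y, K, family, maxit = 20, tol = 1e-6) {
  n <- length(y)
  Kd <- as.matrix(K) * 2  # kinship coefficient -> relatedness (GRM) scale
  eig <- eigen(Kd, symmetric = TRUE)
  if (min(eig$values) < -1e-8) cm_stop("kinship matrix is not positive semi-definite")

  reml_fit <- function(z, w) {
    # Working model z = X b + u + e, u ~ N(0, tau Kd), e ~ N(0, diag(1/w)).
    nll <- function(log_tau) {
      tau <- exp(log_tau)
      V <- tau * Kd + diag(1 / w)
      cV <- chol(V)
      Vi_z <- backsolve(cV, forwardsolve(t(cV), z))
      Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
      XtViX <- crossprod(X, Vi_X)
      b <- solve(XtViX, crossprod(Vi_X, z))
      r <- z - X %*% b
      Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
      as.numeric(sum(log(diag(cV))) + 0.5 * determinant(XtViX)$modulus +
                   0.5 * crossprod(r, Vi_r))
    }
    opt <- stats::optimize(nll, lower = log(1e-8), upper = log(100))
    tau <- exp(opt$minimum)
    if (tau < 1e-6) tau <- 0
    tau
  }

  if (family == "quantitative") {
    # Profile REML over the kinship component with unit residual weights,
    # then rescale.
    fit0 <- stats::lm.fit(X, y)
    sigma2 <- sum(fit0$residuals^2) / (n - ncol(X))
    w <- rep(1 / sigma2, n)
    tau <- reml_fit(y, w)
    V <- tau * Kd + diag(1 / w)
    Vi <- solve(V)
    XtViX <- crossprod(X, Vi %*% X)
    beta <- solve(XtViX, crossprod(X, Vi %*% y))
    mu <- as.numeric(X %*% beta)
    P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    return(list(beta = as.numeric(beta), mu = mu, w = w, sigma2 = sigma2,
                tau = tau, P = P, Ytilde = y))
  }

  # Binary: penalized quasi-likelihood loop.
  beta <- rep(0, ncol(X)); beta[1] <- stats::qlogis(mean(y))
  tau <- 0.1
  b_rand <- rep(0, n)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta) + b_rand
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    tau_new <- reml_fit(z, w)
    V <- tau_new * Kd + diag(1 / w)
    Vi <- solve(V)
    XtViX <- crossprod(X, Vi %*% X)
    beta_new <- solve(XtViX, crossprod(X, Vi %*% z))
    r <- z - as.numeric(X %*% beta_new)
    b_rand <- as.numeric(tau_new * Kd %*% (Vi %*% r))
    conv <- max(abs(beta_new - beta)) < tol && abs(tau_new - tau) < tol
    beta <- as.numeric(beta_new); tau <- tau_new
    if (conv) break
  }
  eta <- as.numeric(X %*% beta) + b_rand
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  V <- tau * Kd + diag(1 / w)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  z <- eta + (y - mu) / w
  list(beta = beta, mu = mu, w = w, sigma2 = NA_real_, tau = tau,
       P = P, Ytilde = z)
}

#' Score test of a carrier burden against a null model
#'
#' Computes the efficient score for adding the dominant-model carrier
#' indicator to the null model: `S = sum_i g~_i (y_i - mu_i)` with `g~`
#' the carrier vector residualized on the fixed-effect design under the
#' null working weights, and its variance from the null model. The
#' two-sided normal p-value is `2 * pnorm(-|S| / sqrt(Var S))`. With a
#' kinship component the projection uses the mixed-model covariance.
#'
#' @param null a `cm_null_model`.
#' @param burden a `cm_burden` or a plain 0/1 carrier vector aligned to
#'   (named by) the null model's samples.
#' @return list with `score`, `var`, `z`, `p_normal`, `degenerate`,
#'   `n_carriers`, `n_case_carriers`, plus internals used by
#'   [spa_pvalue()].
#' @export
score_test <- function(null, burden) {
  g <- align_carrier(null, burden)
  n_car <- sum(g)
  n_case_car <- if (null$family == "binary") sum(g * null$y) else NA_integer_
  if (n_car == 0L || n_car == length(g)) {
    return(list(score = 0, var = 0, z = 0, p_normal = 1, degenerate = TRUE,
                n_carriers = n_car, n_case_carriers = n_case_car))
  }
  if (null$has_kinship) {
    S <- as.numeric(crossprod(g, null$P %*% null$Ytilde))
    varS <- as.numeric(crossprod(g, null$P %*% g))
  } else {
    idx <- which(g == 1)
    Xg <- crossprod(null$X[idx, , drop = FALSE], null$w[idx])  # X' W g
    b <- null$XtWX_inv %*% Xg
    r <- null$y - null$mu
    # X'(y - mu) vanishes at an exact null fit; keep the correction term
    # so ridge-stabilized fits stay exact.
    S <- sum(r[idx]) - as.numeric(crossprod(b, null$Xtr))
    if (null$family == "quantitative") S <- S / null$sigma2
    gWg <- sum(null$w[idx])
    varS <- gWg - as.numeric(crossprod(Xg, b))
  }
  if (varS <= 0) {
    return(list(score = S, var = 0, z = 0, p_normal = 1, degenerate = TRUE,
                n_carriers = n_car, n_case_carriers = n_case_car))
  }
  z <- S / sqrt(varS)
  list(score = S, var = varS, z = z,
       p_normal = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE,
       n_carriers = n_car, n_case_carriers = n_case_car)
}

align_carrier <- function(null, burden) {
  g <- if (inherits(burden, "cm_burden")) burden$carrier else burden
  if (!is.null(names(g)) && !is.null(null$sample_ids) &&
      !identical(names(g), null$sample_ids)) {
    idx <- match(null$sample_ids, names(g))
    if (any(is.na(idx))) {
      cm_stop("carrier vector does not cover all null-model samples")
    }
    g <- g[idx]
  }
  if (length(g) != null$n) {
    cm_stop("carrier vector length does not match null model samples")
  }
  as.numeric(g)
}

# Residualize the carrier vector on the design under the null working
# weights (dense; needed for the saddlepoint CGF).
residualize_carrier <- function(null, g) {
  Xg <- crossprod(null$X, null$w * g)
  b <- null$XtWX_inv %*% Xg
  as.numeric(g - null$X %*% b)
}

#' Saddlepoint-approximated p-value for a carrier score test
#'
#' Approximates the exact null tail probability of the score statistic
#' `S = sum_i g~_i B_i` (centered), where `B_i ~ Bernoulli(mu_i)` under
#' the fitted null and `g~` is the covariate-residualized carrier vector,
#' via the saddlepoint (Barndorff-Nielsen) approximation to the cumulant
#' generating function. This corrects the anti-conservative normal tail
#' under extreme case-control imbalance. When the standardized score is
#' below `switch` in absolute value (default 2), or the saddlepoint
#' root-finder fails, the normal p-value is returned and flagged.
#'
#' @param null a binary-family `cm_null_model`.
#' @param burden a `cm_burden` or carrier vector.
#' @param switch fallback threshold on `|z|` (default 2).
#' @return list with `p_spa`, `p_normal`, `z`, `fallback` (logical),
#'   `converged`, `degenerate`.
#' @export
spa_pvalue <- function(null, burden, switch = 2) {
  if (null$family != "binary") {
    cm_stop("saddlepoint approximation applies to binary traits only")
  }
  st <- score_test(null, burden)
  if (st$degenerate) {
    return(list(p_spa = 1, p_normal = 1, z = 0, fallback = TRUE,
                converged = TRUE, degenerate = TRUE))
  }
  if (abs(st$z) < switch) {
    return(list(p_spa = st$p_normal, p_normal = st$p_normal, z = st$z,
                fallback = TRUE, converged = TRUE, degenerate = FALSE))
  }
  g <- align_carrier(null, burden)
  gt <- residualize_carrier(null, g)
  mu <- null$mu
  s <- st$score

  p_up <- spa_tail(abs(s), gt, mu)
  p_lo <- spa_tail(-abs(s), gt, mu)
  if (is.na(p_up) || is.na(p_lo)) {
    return(list(p_spa = st$p_normal, p_normal = st$p_normal, z = st$z,
                fallback = TRUE, converged = FALSE, degenerate = FALSE))
  }
  p <- min(1, p_up + p_lo)
  list(p_spa = p, p_normal = st$p_normal, z = st$z, fallback = FALSE,
       converged = TRUE, degenerate = FALSE)
}

# One-tail saddlepoint probability for the centered score S = sum gt_i B_i
# - sum gt_i mu_i: P(S >= q) for q > 0, P(S <= q) for q < 0. Returns NA on
# root-finding failure.
spa_tail <- function(q, gt, mu, tol = 1e-8) {
  m1 <- sum(gt * mu)
  Kfun <- function(t) sum(log1p(mu * (exp(gt * t) - 1))) - t * m1
  K1 <- function(t) {
    e <- exp(gt * t)
    sum(gt * mu * e / (1 - mu + mu * e)) - m1
  }
  K2 <- function(t) {
    e <- exp(gt * t)
    d <- 1 - mu + mu * e
    sum(gt^2 * mu * (1 - mu) * e / d^2)
  }
  # Bracket the saddlepoint: K1 is increasing with K1(0) = 0.
  lo <- 0; hi <- 0
  step <- if (q > 0) 1 else -1
  t_try <- step
  for (i in 1:64) {
    v <- K1(t_try)
    if (!is.finite(v)) { t_try <- t_try / 2; next }
    if ((q > 0 && v >= q) || (q < 0 && v <= q)) { hi <- t_try; break }
    lo <- t_try
    t_try <- t_try * 2
  }
  if (hi == 0) return(NA_real_)
  root <- tryCatch(
    stats::uniroot(function(t) K1(t) - q, lower = min(lo, hi),
                   upper = max(lo, hi), tol = tol)$root,
    error = function(e) NA_real_
  )
  if (is.na(root) || abs(root) < 1e-10) return(NA_real_)
  k <- Kfun(root)
  arg <- root * q - k
  if (arg <= 0) return(NA_real_)
  w <- sign(root) * sqrt(2 * arg)
  v <- root * sqrt(K2(root))
  if (v <= 0 && q > 0) return(NA_real_)
  zstar <- w + log(v / w) / w
  if (q > 0) stats::pnorm(zstar, lower.tail = FALSE)
  else stats::pnorm(zstar, lower.tail = TRUE)
}

#' Firth bias-reduced logistic regression
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' `l(beta) + 0.5 log det X'WX` by Newton iterations with step-halving,
#' guaranteeing a monotone increase of the penalized likelihood and finite
#' estimates even under complete separation.
#'
#' @param X design matrix including an intercept column.
#' @param y 0/1 outcome.
#' @param maxit maximum Newton iterations (default 100).
#' @param tol convergence tolerance on the penalized score (default 1e-8).
#' @return list with `coefficients`, `se` (Wald, from the penalized
#'   information), `vcov`, `loglik_penalized`, `iterations`, `converged`,
#'   and `pll_trace` (per-iteration penalized log-likelihood).
#' @export
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  pll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    I <- crossprod(X * sqrt(w))
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(I)$modulus[1]
  }
  pll_old <- pll(beta)
  trace <- pll_old
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XW <- X * sqrt(w)
    I <- crossprod(XW)
    cI <- chol(I)
    H <- forwardsolve(t(cI), t(XW))
    h <- colSums(H^2)  # hat-matrix diagonal
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    if (max(abs(U)) < tol) { converged <- TRUE; break }
    delta <- backsolve(cI, forwardsolve(t(cI), U))
    # Step-halve until the penalized likelihood does not decrease.
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      pll_new <- pll(beta_new)
      if (is.finite(pll_new) && pll_new >= pll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { beta_new <- beta; pll_new <- pll_old; break }
    }
    beta <- as.numeric(beta_new)
    trace <- c(trace, pll_new)
    if (abs(pll_new - pll_old) < tol && max(abs(step * delta)) < 1e-6) {
      pll_old <- pll_new
      converged <- TRUE
      break
    }
    pll_old <- pll_new
  }
  if (!converged && it == maxit) {
    cm_stop(sprintf(
      "Firth regression did not converge in %d iterations (max |score| = %.3g)",
      maxit, max(abs(U))), class = "cm_convergence_error")
  }
  eta <- as.numeric(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  V <- solve(crossprod(X * sqrt(w)))
  list(coefficients = stats::setNames(beta, colnames(X)),
       se = sqrt(diag(V)), vcov = V,
       loglik_penalized = pll_old, iterations = it,
       converged = TRUE, pll_trace = trace)
}

#' Firth re-estimation of a carrier effect
#'
#' Refits the carrier log-odds with Firth's penalized logistic regression
#' on the full covariate design, returning the penalized estimate with a
#' Wald 95% confidence interval. Used to re-estimate effect sizes where
#' score-model effects are unreliable (rare outcomes and rare carriers).
#'
#' @param y 0/1 outcome vector.
#' @param covariates covariate matrix (no intercept column) or `NULL`.
#' @param carrier 0/1 carrier vector.
#' @param conf_level confidence level (default 0.95).
#' @return list with `log_odds`, `se`, `ci` (length 2, log-odds scale),
#'   `or`, `or_ci`, `p` (Wald), `iterations`.
#' @export
firth_refit <- function(y, covariates, carrier, conf_level = 0.95) {
  X <- cbind(`(Intercept)` = 1,
             if (!is.null(covariates)) as.matrix(covariates),
             carrier = as.numeric(carrier))
  fit <- firth_logistic(X, y)
  j <- ncol(X)
  b <- fit$coefficients[j]
  se <- fit$se[j]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(b - zq * se, b + zq * se)
  list(log_odds = unname(b), se = unname(se), ci = unname(ci),
       or = exp(unname(b)), or_ci = exp(unname(ci)),
       p = 2 * stats::pnorm(-abs(b / se)),
       iterations = fit$iterations)
}

#' Run all masks for one gene-trait pair
#'
#' For each mask burden: score test, saddlepoint p-value (binary traits),
#' one-step effect estimate from the score model, the CMAC filter
#' (associations with cumulative minor allele count below `cmac_min` are
#' flagged `filtered` and excluded downstream), and a Firth refit of the
#' effect when the nominal p-value is below `firth_alpha` with OR > 1
#' (binary, unfiltered masks).
#'
#' @param null a `cm_null_model`.
#' @param burdens named list of `cm_burden` (from [build_burdens()]).
#' @param cmac_min CMAC filter threshold (default 20).
#' @param firth_alpha nominal significance triggering a Firth refit
#'   (default 0.05).
#' @param spa_switch saddlepoint fallback threshold (default 2).
#' @param gene,trait optional labels; defaults taken from the inputs.
#' @return data.frame, one row per mask: `gene, trait, mask_id, cmac,
#'   n_carriers, n_case_carriers, score, p_normal, p_spa, p, effect,
#'   ci_low, ci_high, firth_applied, filtered` (effects on the log-odds /
#'   linear scale; `p` is the nominal p-value used downstream: `p_spa`
#'   for binary traits, `p_normal` otherwise).
#' @export
run_gene_trait <- function(null, burdens, cmac_min = 20, firth_alpha = 0.05,
                           spa_switch = 2, gene = NULL, trait = NULL) {
  rows <- lapply(burdens, function(b) {
    st <- score_test(null, b)
    if (null$family == "binary") {
      sp <- spa_pvalue(null, b, switch = spa_switch)
      p_spa <- sp$p_spa
    } else {
      p_spa <- NA_real_
    }
    p_nominal <- if (null$family == "binary") p_spa else st$p_normal
    filtered <- b$cmac < cmac_min
    # One-step (score-based) effect; for linear models this equals the
    # exact covariate-adjusted coefficient.
    if (st$degenerate || st$var == 0) {
      eff <- NA_real_; ci <- c(NA_real_, NA_real_)
    } else {
      eff <- st$score / st$var
      se <- 1 / sqrt(st$var)
      ci <- c(eff - 1.96 * se, eff + 1.96 * se)
    }
    firth_applied <- FALSE
    if (null$family == "binary" && !filtered && !st$degenerate &&
        is.finite(p_nominal) && p_nominal < firth_alpha &&
        is.finite(eff) && eff > 0) {
      g <- align_carrier(null, b)
      fr <- firth_refit(null$y, null$X[, -1, drop = FALSE], g)
      eff <- fr$log_odds
      ci <- fr$ci
      firth_applied <- TRUE
    }
    data.frame(
      gene = if (!is.null(gene)) gene else b$gene,
      trait = if (!is.null(trait)) trait else null$trait,
      mask_id = b$mask_id, cmac = b$cmac,
      n_carriers = st$n_carriers, n_case_carriers = st$n_case_carriers,
      score = st$score, p_normal = st$p_normal, p_spa = p_spa,
      p = p_nominal, effect = eff, ci_low = ci[1], ci_high = ci[2],
      firth_applied = firth_applied, filtered = filtered,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
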