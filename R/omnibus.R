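# Cauchy (ACAT) omnibus combination across masks, FDR, and best-mask
# summaries per gene-trait pair.

#' Cauchy combination of p-values
#'
#' Combines k (possibly correlated) p-values into one omnibus p-value via
#' the Cauchy distribution test: `T = (1/k) sum_i w_i tan((0.5 - p_i) pi)`
#' and `p = P(Cauchy > T)`. Valid under arbitrary dependence among the
#' component tests. For `p_i < 1e-15` the numerically stable substitution
#' `tan((0.5 - p) pi) ~ 1/(p pi)` is used; p-values at or above 1 are
#' clipped to `1 - 1e-15`.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param weights optional non-negative weights (default equal); they are
#'   normalized to sum to 1.
#' @return combined p-value in (0, 1].
#' @examples
#' cauchy_combine(0.03)          # 0.03: single-p identity
#' cauchy_combine(c(0.5, 0.5))   # 0.5
#' @export
cauchy_combine <- function(pvals, weights = NULL) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0L) {
    cm_stop("cauchy_combine needs at least one p-value",
            class = "cm_empty_error")
  }
  if (any(pvals <= 0)) cm_stop("p-values must be positive")
  if (is.null(weights)) {
    weights <- rep(1 / length(pvals), length(pvals))
  } else {
    if (length(weights) != length(pvals) || any(weights < 0)) {
      cm_stop("weights must be non-negative and match pvals in length")
    }
    weights <- weights / sum(weights)
  }
  p <- pmin(pvals, 1 - 1e-15)
  small <- p < 1e-15
  terms <- numeric(length(p))
  terms[!small] <- tan((0.5 - p[!small]) * pi)
  terms[small] <- 1 / (p[small] * pi)
  T_stat <- sum(weights * terms)
  # Upper Cauchy tail; pcauchy is numerically stable in both tails.
  min(1, stats::pcauchy(T_stat, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment `q_(i) = min_{j >= i} m p_(j) / j`,
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Summarize one gene-trait pair across masks
#'
#' Drops CMAC-filtered masks, combines the remaining nominal p-values with
#' [cauchy_combine()], and reports the best mask: lowest nominal p, ties
#' broken by larger CMAC, then lexicographically smaller mask id. Positive
#' effects denote increased disease risk (or a higher trait value).
#'
#' @param results per-mask data.frame from [run_gene_trait()] for a single
#'   gene-trait pair.
#' @return one-row data.frame `gene, trait, p_cauchy, best_mask,
#'   best_effect, best_ci_low, best_ci_high, n_masks_used`, or `NULL` when
#'   every mask is filtered (the pair is dropped).
#' @export
summarize_gene_trait <- function(results) {
  keep <- results[!results$filtered & !is.na(results$p), , drop = FALSE]
  if (nrow(keep) == 0L) return(NULL)
  ord <- order(keep$p, -keep$cmac, keep$mask_id)
  best <- keep[ord[1], ]
  data.frame(
    gene = best$gene, trait = best$trait,
    p_cauchy = cauchy_combine(keep$p),
    best_mask = best$mask_id,
    best_effect = best$effect,
    best_ci_low = best$ci_low, best_ci_high = best$ci_high,
    n_masks_used = nrow(keep),
    stringsAsFactors = FALSE
  )
}

#' Omnibus table across gene-trait pairs
#'
#' Applies [summarize_gene_trait()] to each gene-trait pair of a combined
#' per-mask results table and attaches Benjamini-Hochberg q-values
#' computed within FDR families (e.g. disease endpoints vs quantitative
#' MRI traits are corrected separately).
#'
#' @param results row-bound per-mask results from [run_gene_trait()].
#' @param fdr_family optional named character vector mapping trait ->
#'   family label; traits missing from the map form one default family.
#' @return data.frame with one row per gene-trait pair and a `q_value`
#'   column; pairs whose masks were all filtered are dropped.
#' @export
omnibus_table <- function(results, fdr_family = NULL) {
  splits <- split(results, list(results$gene, results$trait), drop = TRUE)
  rows <- Filter(Negate(is.null), lapply(splits, summarize_gene_trait))
  if (length(rows) == 0L) {
    return(data.frame(gene = character(0), trait = character(0),
                      p_cauchy = numeric(0), q_value = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fam <- if (is.null(fdr_family)) rep("all", nrow(out)) else {
    f <- fdr_family[out$trait]
    f[is.na(f)] <- "all"
    f
  }
  out$q_value <- NA_real_
  for (f in unique(fam)) {
    i <- fam == f
    out$q_value[i] <- bh_fdr(out$p_cauchy[i])
  }
  out[order(out$p_cauchy), ]
}
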