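# Variant annotation: consequence classes, missense deleteriousness score,
# POPMAX population frequency.

# Controlled vocabulary for raw consequence strings. Protein-truncating
# classes are those LOFTEE evaluates; everything else collapses to
# missense or other.
PTV_CONSEQUENCES <- c(
  "stop_gained", "nonsense", "frameshift", "frameshift_variant",
  "splice_acceptor", "splice_acceptor_variant",
  "splice_donor", "splice_donor_variant"
)
OTHER_CONSEQUENCES <- c("other", "synonymous", "splice_region", "inframe_indel",
                        "start_lost", "stop_lost")
MISSENSE_CONSEQUENCES <- c("missense", "missense_variant")

# Continental populations over which POPMAX is taken. ASJ and FIN are
# bottleneck groups reported separately and deliberately excluded from the
# POPMAX maximum, mirroring the gnomAD "popmax" convention.
POPMAX_POPULATIONS <- c("afr", "amr", "eas", "nfe", "sas")

#' Missense deleteriousness score
#'
#' Scores a missense variant by the fraction of in-silico prediction tools
#' calling it damaging or deleterious: `n_damaging / n_predicting`. Variants
#' with fewer than `min_predictions` tool predictions receive `NA` and are
#' later excluded from missense masks.
#'
#' @param n_damaging integer vector, number of tools predicting a damaging
#'   or deleterious effect.
#' @param n_predicting integer vector, number of tools that gave any
#'   prediction for the variant (at most `tools_total`).
#' @param min_predictions minimum number of predictions required for a
#'   score; below it the score is `NA` (default 7).
#' @param tools_total size of the configured tool roster (default 31).
#' @return numeric vector of scores in `[0, 1]`, `NA` where too few tools
#'   predicted.
#' @examples
#' missense_score(14, 28)  # 0.5
#' missense_score(5, 6)    # NA: fewer than 7 predictions
#' @export
missense_score <- function(n_damaging, n_predicting, min_predictions = 7,
                           tools_total = 31) {
  if (min_predictions < 1) cm_stop("min_predictions must be >= 1")
  n <- max(length(n_damaging), length(n_predicting))
  n_damaging <- rep_len(as.numeric(n_damaging), n)
  n_predicting <- rep_len(as.numeric(n_predicting), n)
  bad <- !is.na(n_damaging) & !is.na(n_predicting) & n_damaging > n_predicting
  if (any(bad)) {
    cm_stop(sprintf(
      "invalid annotation: n_damaging > n_predicting for %d variant(s)",
      sum(bad)
    ), class = "cm_annotation_error")
  }
  if (any(n_predicting > tools_total, na.rm = TRUE)) {
    cm_stop(sprintf("n_predicting exceeds configured tool roster (%d)",
                    tools_total),
            class = "cm_annotation_error")
  }
  if (any(n_damaging < 0 | n_predicting < 0, na.rm = TRUE)) {
    cm_stop("tool counts must be non-negative", class = "cm_annotation_error")
  }
  score <- n_damaging / n_predicting
  score[is.na(n_predicting) | n_predicting < min_predictions] <- NA_real_
  score
}

#' Classify a raw consequence into PTV / missense / other
#'
#' High-confidence loss-of-function calls on truncating classes (nonsense,
#' frameshift, essential splice site) become `PTV`, unless predicted to
#' escape nonsense-mediated decay. LOF calls flagged as dubious are demoted
#' to `other` (i.e. removed from LOF sets). Non-canonical splice-region
#' variants are `other`.
#'
#' @param raw_consequence character vector from the documented vocabulary.
#' @param lof_confidence one of `"high"`, `"flagged"`, `"not_lof"`.
#' @param nmd_escape logical, predicted to escape nonsense-mediated decay.
#' @return character vector over `c("PTV", "missense", "other")`.
#' @export
classify_consequence <- function(raw_consequence, lof_confidence = "not_lof",
                                 nmd_escape = FALSE) {
  n <- length(raw_consequence)
  lof_confidence <- rep_len(lof_confidence, n)
  nmd_escape <- rep_len(nmd_escape, n)
  known <- c(PTV_CONSEQUENCES, MISSENSE_CONSEQUENCES, OTHER_CONSEQUENCES)
  unknown <- setdiff(unique(raw_consequence), known)
  if (length(unknown) > 0L) {
    cm_stop(sprintf(
      "unknown consequence term(s): %s; accepted terms are: %s",
      paste(unknown, collapse = ", "), paste(known, collapse = ", ")
    ), class = "cm_config_error")
  }
  bad_conf <- setdiff(unique(lof_confidence), c("high", "flagged", "not_lof"))
  if (length(bad_conf) > 0L) {
    cm_stop(sprintf("unknown lof_confidence value(s): %s",
                    paste(bad_conf, collapse = ", ")),
            class = "cm_config_error")
  }
  out <- rep("other", n)
  is_trunc <- raw_consequence %in% PTV_CONSEQUENCES
  out[is_trunc & lof_confidence == "high" & !nmd_escape] <- "PTV"
  out[raw_consequence %in% MISSENSE_CONSEQUENCES] <- "missense"
  out
}

#' POPMAX frequency across continental populations
#'
#' Maximum allele frequency over the five continental population groups
#' (African, Admixed American, East Asian, non-Finnish European, South
#' Asian). Missing populations count as zero; a variant unobserved in all
#' five has POPMAX 0.
#'
#' @param pop_freqs named numeric vector or list of per-population allele
#'   frequencies (names among `afr, amr, eas, nfe, sas`, case-insensitive;
#'   additional populations are ignored for the maximum).
#' @return a single frequency in `[0, 1]`.
#' @export
popmax <- function(pop_freqs) {
  if (length(pop_freqs) == 0L) return(0)
  freqs <- unlist(pop_freqs)
  if (any(is.na(freqs))) freqs <- freqs[!is.na(freqs)]
  if (length(freqs) == 0L) return(0)
  if (any(freqs < 0 | freqs > 1)) {
    cm_stop("population allele frequency outside [0, 1]",
            class = "cm_annotation_error")
  }
  keep <- tolower(names(freqs)) %in% POPMAX_POPULATIONS
  if (!any(keep)) return(0)
  max(freqs[keep])
}

#' Annotate a raw variant table
#'
#' Turns a raw annotation table into the analysis-ready classification:
#' consequence class (`PTV` / `missense` / `other`), missense
#' deleteriousness score, and POPMAX frequency. Expects one row per
#' variant; duplicate `variant_id`s are an error (variants are assumed
#' pre-restricted to canonical transcripts by the annotation producer).
#'
#' @param ann data.frame with columns `variant_id`, `gene`, `consequence`,
#'   `lof_confidence`, `nmd_escape`, and either `missense_score` or the
#'   pair `n_damaging` / `n_predicting`, plus per-population frequency
#'   columns `afr, amr, eas, nfe, sas` (missing columns treated as 0).
#' @param min_predictions minimum tool predictions for a missense score.
#' @param tools_total configured tool roster size, recorded in the result's
#'   attributes for provenance.
#' @return data.frame with columns `variant_id`, `gene`, `consequence`
#'   (classified), `missense_score`, `popmax`, and the per-population
#'   frequencies.
#' @export
annotate_variants <- function(ann, min_predictions = 7, tools_total = 31) {
  check_columns(ann, c("variant_id", "gene", "consequence", "lof_confidence",
                       "nmd_escape"), "annotation table")
  if (anyDuplicated(ann$variant_id)) {
    cm_stop(sprintf("duplicate variant_id(s): %s",
                    paste(unique(ann$variant_id[duplicated(ann$variant_id)]),
                          collapse = ", ")),
            class = "cm_annotation_error")
  }
  cls <- classify_consequence(ann$consequence, ann$lof_confidence,
                              as.logical(ann$nmd_escape))
  if ("missense_score" %in% names(ann)) {
    score <- as.numeric(ann$missense_score)
    if (any(score < 0 | score > 1, na.rm = TRUE)) {
      cm_stop("missense_score outside [0, 1]", class = "cm_annotation_error")
    }
  } else if (all(c("n_damaging", "n_predicting") %in% names(ann))) {
    score <- missense_score(ann$n_damaging, ann$n_predicting,
                            min_predictions, tools_total)
  } else {
    cm_stop(paste("annotation table needs either missense_score or",
                  "n_damaging and n_predicting columns"),
            class = "cm_schema_error")
  }
  score[cls != "missense"] <- NA_real_

  pops <- intersect(POPMAX_POPULATIONS, tolower(names(ann)))
  freq_mat <- matrix(0, nrow = nrow(ann), ncol = length(POPMAX_POPULATIONS),
                     dimnames = list(NULL, POPMAX_POPULATIONS))
  for (p in pops) {
    col <- names(ann)[tolower(names(ann)) == p][1]
    v <- as.numeric(ann[[col]])
    v[is.na(v)] <- 0
    freq_mat[, p] <- v
  }
  if (any(freq_mat < 0 | freq_mat > 1)) {
    cm_stop("population allele frequency outside [0, 1]",
            class = "cm_annotation_error")
  }
  out <- data.frame(
    variant_id = as.character(ann$variant_id),
    gene = as.character(ann$gene),
    consequence = cls,
    missense_score = score,
    popmax = apply(freq_mat, 1, max),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(freq_mat))
  attr(out, "tools_total") <- tools_total
  attr(out, "min_predictions") <- min_predictions
  out
}
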