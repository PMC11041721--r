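# Mask grid construction and dominant-model carrier collapsing.

#' Build the rare-variant mask grid
#'
#' Crosses frequency filters with a consequence/deleteriousness ladder.
#' The default grid is 2 frequency thresholds (POPMAX MAF < 0.1% and
#' < 0.001%) x 11 consequence filters (PTV-only, plus PTV together with
#' missense variants at deleteriousness score >= s for s in 1.0, 0.9, ...,
#' 0.1), giving 22 masks. Both axes are overridable.
#'
#' @param maf_thresholds numeric vector of strict POPMAX MAF upper bounds.
#' @param missense_ladder numeric vector of minimum missense scores; `NA`
#'   entries denote a PTV-only filter (missense excluded).
#' @param include_ptv logical, whether PTVs qualify in every filter
#'   (default `TRUE` for the whole ladder).
#' @return data.frame with one row per mask: `mask_id`, `maf_threshold`,
#'   `include_ptv`, `missense_min_score` (`NA` = missense excluded).
#' @examples
#' nrow(build_mask_grid())  # 22
#' @export
build_mask_grid <- function(maf_thresholds = c(0.001, 0.00001),
                            missense_ladder = c(NA, seq(1, 0.1, by = -0.1)),
                            include_ptv = TRUE) {
  if (any(maf_thresholds <= 0 | maf_thresholds > 1)) {
    cm_stop("maf_thresholds must lie in (0, 1]", class = "cm_config_error")
  }
  if (any(missense_ladder < 0 | missense_ladder > 1, na.rm = TRUE)) {
    cm_stop("missense_ladder scores must lie in [0, 1]",
            class = "cm_config_error")
  }
  grid <- expand.grid(
    missense_min_score = missense_ladder,
    maf_threshold = maf_thresholds,
    KEEP.OUT.ATTRS = FALSE
  )[, c("maf_threshold", "missense_min_score")]
  grid$include_ptv <- rep_len(include_ptv, nrow(grid))
  grid$mask_id <- sprintf(
    "maf%s_%s",
    formatC(grid$maf_threshold, format = "g"),
    ifelse(is.na(grid$missense_min_score), "ptv",
           sprintf("ptv_mis%s", formatC(grid$missense_min_score,
                                        format = "g")))
  )
  if (anyDuplicated(grid$mask_id)) {
    cm_stop("duplicate mask ids in grid", class = "cm_config_error")
  }
  grid[, c("mask_id", "maf_threshold", "include_ptv", "missense_min_score")]
}

#' Select variants qualifying under a mask
#'
#' A variant of the gene qualifies when its POPMAX frequency is strictly
#' below the mask's MAF threshold and it passes the consequence filter:
#' a PTV (when the mask includes PTVs) or a missense variant with
#' deleteriousness score at or above the mask's minimum. Missense variants
#' without a score (too few tool predictions) never qualify through the
#' missense branch.
#'
#' @param mask one row of [build_mask_grid()] (data.frame or list).
#' @param annotations annotated variant table from [annotate_variants()].
#' @param gene gene symbol.
#' @return character vector of qualifying `variant_id`s (possibly empty).
#' @export
select_qualifying <- function(mask, annotations, gene) {
  v <- annotations[annotations$gene == gene, , drop = FALSE]
  if (nrow(v) == 0L) return(character(0))
  rare <- v$popmax < mask$maf_threshold
  ptv_ok <- isTRUE(mask$include_ptv) & v$consequence == "PTV"
  mis_ok <- if (is.na(mask$missense_min_score)) {
    rep(FALSE, nrow(v))
  } else {
    v$consequence == "missense" & !is.na(v$missense_score) &
      v$missense_score >= mask$missense_min_score
  }
  v$variant_id[rare & (ptv_ok | mis_ok)]
}

#' Collapse genotypes to a dominant-model carrier burden
#'
#' Each sample is coded 1 when it carries at least one qualifying
#' alternate allele, 0 otherwise. The cumulative minor allele count (CMAC)
#' is the total number of qualifying alternate alleles across samples.
#' Missing dosages contribute nothing to either quantity and are tallied
#' in the result.
#'
#' @param genotypes numeric sample x variant dosage matrix (entries 0, 1,
#'   2 or `NA`) with variant ids as column names and sample ids as row
#'   names.
#' @param qualifying character vector of qualifying variant ids; ids
#'   absent from the matrix are skipped with a warning.
#' @param gene,mask_id optional labels attached to the result.
#' @return object of class `cm_burden`: list with `gene`, `mask_id`,
#'   `qualifying_variants`, `carrier` (named 0/1 vector), `cmac`,
#'   `n_missing` (missing dosage entries among qualifying variants).
#' @export
collapse_carriers <- function(genotypes, qualifying, gene = NA_character_,
                              mask_id = NA_character_) {
  absent <- setdiff(qualifying, colnames(genotypes))
  if (length(absent) > 0L) {
    cm_warn(sprintf("qualifying variant(s) absent from genotype matrix, skipped: %s",
                    paste(absent, collapse = ", ")))
    qualifying <- setdiff(qualifying, absent)
  }
  n <- nrow(genotypes)
  if (length(qualifying) == 0L) {
    carrier <- stats::setNames(integer(n), rownames(genotypes))
    return(structure(list(gene = gene, mask_id = mask_id,
                          qualifying_variants = character(0),
                          carrier = carrier, cmac = 0L, n_missing = 0L),
                     class = "cm_burden"))
  }
  G <- genotypes[, qualifying, drop = FALSE]
  n_missing <- sum(is.na(G))
  G[is.na(G)] <- 0
  dosage_sum <- rowSums(G)
  carrier <- as.integer(dosage_sum >= 1)
  names(carrier) <- rownames(genotypes)
  structure(list(
    gene = gene, mask_id = mask_id,
    qualifying_variants = qualifying,
    carrier = carrier,
    cmac = as.integer(sum(G)),
    n_missing = n_missing
  ), class = "cm_burden")
}

#' @export
print.cm_burden <- function(x, ...) {
  cat(sprintf("<cm_burden> gene=%s mask=%s variants=%d carriers=%d cmac=%d\n",
              x$gene, x$mask_id, length(x$qualifying_variants),
              sum(x$carrier), x$cmac))
  invisible(x)
}

#' Build burdens for every mask of a grid
#'
#' @param genotypes dosage matrix as in [collapse_carriers()].
#' @param annotations annotated variant table.
#' @param gene gene symbol.
#' @param grid mask grid from [build_mask_grid()].
#' @return named list of `cm_burden`, one per mask.
#' @export
build_burdens <- function(genotypes, annotations, gene,
                          grid = build_mask_grid()) {
  out <- lapply(seq_len(nrow(grid)), function(i) {
    mask <- grid[i, ]
    q <- select_qualifying(mask, annotations, gene)
    collapse_carriers(genotypes, q, gene = gene, mask_id = mask$mask_id)
  })
  stats::setNames(out, grid$mask_id)
}
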