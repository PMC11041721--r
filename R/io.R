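# Validated TSV readers/writers, a minimal VCF genotype reader, and run
# manifests. TSV is the canonical interchange format; variant ids are
# 1-based chrom:pos:ref:alt throughout.

read_tsv_checked <- function(path, required, what, ...) {
  if (!file.exists(path)) cm_stop(sprintf("file not found: %s", path))
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = c("", "NA"), ...))
  check_columns(df, required, what)
  df
}

#' Write a table as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a variant annotation table
#'
#' Tab-separated, one row per variant: `variant_id, gene, consequence,
#' lof_confidence, nmd_escape`, either `missense_score` or
#' `n_damaging`/`n_predicting`, and per-population frequency columns
#' (`afr, amr, eas, nfe, sas`). Missing values encoded as empty fields or
#' `NA`.
#'
#' @param path TSV path.
#' @param ... forwarded to [annotate_variants()].
#' @return analysis-ready annotation table.
#' @export
read_annotation_table <- function(path, ...) {
  df <- read_tsv_checked(path, c("variant_id", "gene", "consequence",
                                 "lof_confidence", "nmd_escape"),
                         "annotation table")
  annotate_variants(df, ...)
}

#' Read a genotype dosage matrix
#'
#' TSV with a `sample_id` column followed by one column per variant id;
#' entries 0/1/2/NA.
#'
#' @param path TSV path.
#' @return numeric matrix with sample ids as row names.
#' @export
read_genotype_matrix <- function(path) {
  df <- read_tsv_checked(path, "sample_id", "genotype matrix")
  ids <- as.character(df$sample_id)
  G <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(G) <- "numeric"
  bad <- !(G %in% c(0, 1, 2) | is.na(G))
  if (any(bad)) {
    cm_stop("genotype dosages must be 0, 1, 2 or NA",
            class = "cm_schema_error")
  }
  rownames(G) <- ids
  G
}

#' Write a genotype dosage matrix
#' @param G matrix as returned by [read_genotype_matrix()].
#' @param path output path.
#' @export
write_genotype_matrix <- function(G, path) {
  df <- data.frame(sample_id = rownames(G), as.data.frame(G),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read a phenotype/covariate table
#'
#' Requires `sample_id`; trait columns are 0/1/NA (binary) or real
#' (quantitative). Unknown columns are allowed (they may be covariates),
#' but requesting a trait not present raises an error naming the column.
#'
#' @param path TSV path.
#' @param traits optional character vector of trait columns that must be
#'   present.
#' @return data.frame.
#' @export
read_phenotype_table <- function(path, traits = NULL) {
  df <- read_tsv_checked(path, "sample_id", "phenotype table")
  if (!is.null(traits)) check_columns(df, traits, "phenotype table")
  df
}

#' Read kinship triples
#'
#' TSV with columns `id1, id2, coefficient`.
#' @param path TSV path.
#' @return data.frame of triples.
#' @export
read_kinship_triples <- function(path) {
  read_tsv_checked(path, c("id1", "id2", "coefficient"), "kinship triples")
}

#' Read a case table
#'
#' Mirrors the curated per-case schema: `case_id, gene, phenotype, sex,
#' zygosity, variant_class, age_onset, outcome, age_outcome`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_case_table <- function(path) {
  df <- read_tsv_checked(path, c("case_id", "gene", "outcome"),
                         "case table")
  valid_outcomes <- c("alive", "deceased", "transplant", "LVAD",
                      "fetal_termination", "unknown")
  bad <- setdiff(unique(df$outcome[!is.na(df$outcome)]), valid_outcomes)
  if (length(bad) > 0L) {
    cm_stop(sprintf("unknown outcome value(s): %s (accepted: %s)",
                    paste(bad, collapse = ", "),
                    paste(valid_outcomes, collapse = ", ")),
            class = "cm_schema_error")
  }
  both <- !is.na(df$age_onset) & !is.na(df$age_outcome)
  if (any(df$age_outcome[both] < df$age_onset[both])) {
    cm_stop("age_outcome must be >= age_onset where both are present",
            class = "cm_case_error")
  }
  df
}

#' Read a phase table
#'
#' TSV with columns `variant_id1, variant_id2, phase` (`cis`, `trans` or
#' `unphased`).
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phase_table <- function(path) {
  df <- read_tsv_checked(path, c("variant_id1", "variant_id2", "phase"),
                         "phase table")
  bad <- setdiff(unique(df$phase), c("cis", "trans", "unphased"))
  if (length(bad) > 0L) {
    cm_stop(sprintf("unknown phase value(s): %s", paste(bad, collapse = ", ")),
            class = "cm_schema_error")
  }
  df
}

#' Minimal VCF genotype reader
#'
#' Convenience reader for small VCFs: GT field only, biallelic records,
#' 1-based positions. Multiallelic records are rejected with a pointer to
#' pre-splitting. Requires the `vcfR` package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return dosage matrix (samples x variants) with `chrom:pos:ref:alt`
#'   column names.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    cm_stop("the vcfR package is required for VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    cm_stop(paste("multiallelic VCF record(s) found; split them into",
                  "biallelic records (e.g. `bcftools norm -m-`) first"),
            class = "cm_schema_error")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- function(x) {
    x <- sub(":.*", "", x)
    ifelse(is.na(x) | x %in% c("./.", "."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), numeric(1)))
  }
  D <- apply(gt, 2, dosage)
  if (is.null(dim(D))) D <- matrix(D, nrow = 1, dimnames = list(NULL, names(D)))
  G <- t(D)
  colnames(G) <- sprintf("%s:%s:%s:%s", fix$CHROM, fix$POS, fix$REF, fix$ALT)
  G
}

#' Write a run manifest
#'
#' Records the configuration, seeds, package version and input checksums
#' needed to reproduce a run bit-for-bit for its deterministic stages.
#'
#' @param path output JSON path.
#' @param config named list of thresholds and settings (echoed verbatim).
#' @param seeds named list/vector of seeds.
#' @param inputs character vector of input file paths (md5-summed).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = list(),
                           inputs = character(0)) {
  manifest <- list(
    package = "cmspectrum",
    version = as.character(utils::packageVersion("cmspectrum")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    seeds = seeds,
    inputs = if (length(inputs) > 0) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)),
                 stringsAsFactors = FALSE)
    } else NULL
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
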