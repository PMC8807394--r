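# Readers and writers for the native TSV formats, the VCF adapter, and the
# ELN risk rule derived from FLT3-ITD status.

#' Read a variant call table
#'
#' Native format: tab-separated with header
#' `patient_id  timepoint  gene  variant_id  vaf  assay`. An optional
#' `is_coding` column (TRUE/FALSE) is honored for WGS-style input. VAFs are
#' normalized to fractions; the default dialect expects percentages (a "3.0"
#' means 3\%), matching how panel pipelines usually report them.
#'
#' Rows with an unparseable VAF are rejected with a row-level warning and
#' returned in the `"rejected"` attribute; a missing mandatory column is a
#' hard error. Timepoint labels are resolved through an alias map.
#'
#' @param path path to the TSV file.
#' @param vafScale `"percent"` (default) or `"fraction"`.
#' @param timepointAliases named character vector mapping input labels to
#'   canonical timepoints; see [defaultTimepointAliases()].
#' @return data.frame of variant calls (possibly empty), with attribute
#'   `"rejected"` holding rejected input rows.
#' @export
readVariantTable <- function(path, vafScale = c("percent", "fraction"),
                             timepointAliases = defaultTimepointAliases()) {
  vafScale <- match.arg(vafScale)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty variant table: ", path)
    return(emptyVariantTable())
  }
  stopifnot_cols(raw, c("patient_id", "timepoint", "gene", "variant_id",
                        "vaf", "assay"), "variant table")
  tp <- normalizeTimepoint(raw$timepoint, timepointAliases)
  vaf_chr <- trimws(raw$vaf)
  vaf <- suppressWarnings(as.numeric(vaf_chr))
  is_blank <- vaf_chr == "" | toupper(vaf_chr) %in% c("NA", ".")
  bad <- !is_blank & is.na(vaf)
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected for unparseable VAF (rows ",
            paste(utils::head(which(bad), 10L), collapse = ", "), ")")
  }
  if (vafScale == "percent") vaf <- vaf / 100
  out <- data.frame(patient_id = trimws(raw$patient_id),
                    timepoint = tp,
                    gene = trimws(raw$gene),
                    variant_id = trimws(raw$variant_id),
                    vaf = vaf,
                    assay = toupper(trimws(raw$assay)),
                    is_germline = FALSE,
                    is_coding = if ("is_coding" %in% names(raw))
                      as.logical(raw$is_coding) else TRUE,
                    stringsAsFactors = FALSE)
  rejected <- out[bad, , drop = FALSE]
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

emptyVariantTable <- function() {
  data.frame(patient_id = character(), timepoint = character(),
             gene = character(), variant_id = character(),
             vaf = numeric(), assay = character(),
             is_germline = logical(), is_coding = logical(),
             stringsAsFactors = FALSE)
}

#' Write a variant call table
#'
#' Inverse of [readVariantTable()]; round-trips content up to column order.
#'
#' @param x variant data.frame.
#' @param path output path.
#' @param vafScale `"percent"` (default) or `"fraction"`.
#' @export
writeVariantTable <- function(x, path, vafScale = c("percent", "fraction")) {
  vafScale <- match.arg(vafScale)
  out <- x[, intersect(c("patient_id", "timepoint", "gene", "variant_id",
                         "vaf", "assay", "is_coding", "is_germline"),
                       names(x))]
  if (vafScale == "percent") out$vaf <- out$vaf * 100
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a patient manifest
#'
#' Tab-separated with header `patient_id  age  sex  karyotype_aberrant
#' flt3_itd  flt3_ratio  hsct  t_diagnosis  t_cmr  t_relapse
#' t_death_or_censor  death`. Time columns are either day offsets (numeric)
#' or calendar dates (`YYYY-MM-DD`); dates are converted to day offsets from
#' each patient's diagnosis date, since all endpoints are durations.
#'
#' Ordering violations (e.g. relapse before CMR) and a death flag without a
#' death/censor date are reported per patient as a single itemized error.
#'
#' @param path path to the TSV file.
#' @return data.frame of patient records with `eln_risk` derived from the
#'   FLT3-ITD fields.
#' @export
readPatientManifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot_cols(raw, c("patient_id", "age", "sex", "karyotype_aberrant",
                        "flt3_itd", "flt3_ratio", "hsct", "t_diagnosis",
                        "t_cmr", "t_relapse", "t_death_or_censor", "death"),
                 "patient manifest")
  parseTime <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "NA", ".")] <- NA
    num <- suppressWarnings(as.numeric(x))
    if (all(is.na(num) == is.na(x))) return(num)
    as.numeric(as.Date(x))  # calendar dates
  }
  t_diag <- parseTime(raw$t_diagnosis)
  t_cmr <- parseTime(raw$t_cmr)
  t_rel <- parseTime(raw$t_relapse)
  t_last <- parseTime(raw$t_death_or_censor)
  # re-express as day offsets from diagnosis
  p <- data.frame(patient_id = trimws(raw$patient_id),
                  age = as.numeric(raw$age),
                  sex = toupper(trimws(raw$sex)),
                  karyotype_aberrant = as.logical(raw$karyotype_aberrant),
                  flt3_itd = as.logical(raw$flt3_itd),
                  flt3_ratio = suppressWarnings(as.numeric(raw$flt3_ratio)),
                  hsct = toupper(trimws(raw$hsct)),
                  t_diagnosis = 0,
                  t_cmr = t_cmr - t_diag,
                  t_relapse = t_rel - t_diag,
                  t_death_or_censor = t_last - t_diag,
                  death = as.logical(raw$death),
                  stringsAsFactors = FALSE)
  p$eln_risk <- deriveElnRisk(p$flt3_itd, p$flt3_ratio)
  p <- p[, PATIENT_COLS]
  viol <- dateOrderViolations(p)
  if (length(viol)) {
    stop("manifest validation failed:\n  ", paste(viol, collapse = "\n  "))
  }
  p
}

#' Write a patient manifest
#'
#' @param p patient data.frame.
#' @param path output path.
#' @export
writePatientManifest <- function(p, path) {
  out <- p[, setdiff(PATIENT_COLS, "eln_risk")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ELN-style risk from FLT3-ITD status
#'
#' NPM1-mutated AML with normal karyotype is risk-stratified by the FLT3-ITD
#' allelic ratio: favorable without FLT3-ITD or with a ratio below 0.5,
#' intermediate with a ratio above 0.5. A ratio of exactly 0.5 is left
#' unclassified (NA): the bracketing used in clinical tables (< 0.5, > 0.5)
#' does not assign the boundary.
#'
#' @param itdPresent logical vector, FLT3-ITD detected by gene scan.
#' @param itdRatio numeric vector of allelic ratios (NA when no ITD).
#' @return character vector: `"FAVORABLE"`, `"INTERMEDIATE"` or `NA`.
#' @examples
#' deriveElnRisk(c(FALSE, TRUE, TRUE, TRUE), c(NA, 0.8, 0.2, 0.5))
#' @export
deriveElnRisk <- function(itdPresent, itdRatio) {
  if (any(!is.na(itdRatio) & itdRatio < 0)) stop("negative FLT3-ITD ratio")
  n <- length(itdPresent)
  out <- rep(NA_character_, n)
  out[!itdPresent] <- "FAVORABLE"
  has <- itdPresent & !is.na(itdRatio)
  out[has & itdRatio < 0.5] <- "FAVORABLE"
  out[has & itdRatio > 0.5] <- "INTERMEDIATE"
  out
}

#' Read one patient-timepoint VCF into the variant-table model
#'
#' Adapter for single-sample VCFs: variants become rows of the native table,
#' with the VAF taken from an `AF`-like FORMAT field, or computed from `AD`
#' when `AF` is absent. The gene symbol is taken from a `GENE=` INFO key (or
#' `ANN`'s first gene field). VCF is an ingestion convenience; the TSV model
#' stays the native format.
#'
#' @param path VCF file.
#' @param patientId patient the sample belongs to.
#' @param timepoint canonical timepoint label.
#' @param assay assay label, default `"PANEL"`.
#' @return variant data.frame rows (possibly zero).
#' @export
readVcfVariants <- function(path, patientId, timepoint, assay = "PANEL") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the VCF adapter needs the vcfR package")
  }
  timepoint <- normalizeTimepoint(timepoint)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(v@fix)
  if (n == 0L) return(emptyVariantTable())
  af <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "AF")[, 1L]))
  if (all(is.na(af))) {
    ad <- vcfR::extract.gt(v, "AD")[, 1L]
    parts <- strsplit(ad, ",", fixed = TRUE)
    af <- vapply(parts, function(x) {
      x <- suppressWarnings(as.numeric(x))
      if (length(x) < 2L || any(is.na(x)) || sum(x) == 0) return(NA_real_)
      x[2L] / sum(x)
    }, numeric(1))
  }
  info <- v@fix[, "INFO"]
  gene <- vapply(info, function(s) {
    m <- regmatches(s, regexec("(?:^|;)GENE=([^;]+)", s))[[1L]]
    if (length(m) == 2L) return(m[2L])
    m <- regmatches(s, regexec("(?:^|;)ANN=[^|]*\\|[^|]*\\|[^|]*\\|([^|;]+)",
                               s))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  keep <- !is.na(gene) & !is.na(af)
  data.frame(patient_id = patientId,
             timepoint = timepoint,
             gene = gene[keep],
             variant_id = paste0(v@fix[keep, "REF"], v@fix[keep, "POS"],
                                 v@fix[keep, "ALT"]),
             vaf = af[keep],
             assay = assay,
             is_germline = FALSE,
             is_coding = TRUE,
             stringsAsFactors = FALSE)
}

#' Read a panel gene list
#'
#' One gene symbol per line; blank lines and `#` comments ignored.
#'
#' @param path text file.
#' @return character vector of gene symbols.
#' @export
readPanelGenes <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
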