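#' AmlCohort: a longitudinal NPM1-mutated AML cohort
#'
#' Container for a cohort of NPM1-mutated AML patients sampled at up to three
#' timepoints (diagnosis, complete molecular remission, relapse). Holds the
#' patient manifest, the variant-call table and the gene panel, and enforces
#' the structural invariants every downstream operation relies on: all
#' variant rows resolve to a manifest patient, timepoints come from the fixed
#' three-level ordering, VAFs are fractions in \[0, 1\], and per-patient event
#' dates are ordered diagnosis <= CMR <= relapse <= last follow-up.
#'
#' @slot patients data.frame, one row per patient: `patient_id`, `age`,
#'   `sex` ("M"/"F"), `karyotype_aberrant` (logical), `flt3_itd` (logical),
#'   `flt3_ratio` (numeric or NA), `eln_risk`, `hsct`
#'   ("NONE"/"UPFRONT"/"AFTER_RELAPSE"), day offsets `t_diagnosis`, `t_cmr`,
#'   `t_relapse` (NA when no relapse), `t_death_or_censor`, and `death`
#'   (logical).
#' @slot variants data.frame, one row per observed variant call:
#'   `patient_id`, `timepoint`, `gene`, `variant_id`, `vaf` (fraction, NA for
#'   presence-only assays), `assay` ("PANEL"/"WGS"/"GENE_SCAN"),
#'   `is_germline` (logical), `is_coding` (logical).
#' @slot panelGenes character vector of panel gene symbols (may be empty for
#'   WGS-style cohorts).
#' @slot provenance free-text description of where the cohort came from.
#'
#' @seealso [readVariantTable()], [readPatientManifest()],
#'   [buildReferenceFixture()], [simulateCohort()]
#' @export
setClass("AmlCohort",
         representation(patients = "data.frame",
                        variants = "data.frame",
                        panelGenes = "character",
                        provenance = "character"))

PATIENT_COLS <- c("patient_id", "age", "sex", "karyotype_aberrant",
                  "flt3_itd", "flt3_ratio", "eln_risk", "hsct",
                  "t_diagnosis", "t_cmr", "t_relapse",
                  "t_death_or_censor", "death")

VARIANT_COLS <- c("patient_id", "timepoint", "gene", "variant_id",
                  "vaf", "assay", "is_germline", "is_coding")

validAmlCohort <- function(object) {
  p <- object@patients
  v <- object@variants
  msg <- character()
  miss <- setdiff(PATIENT_COLS, names(p))
  if (length(miss)) msg <- c(msg, paste("patients missing columns:",
                                        paste(miss, collapse = ", ")))
  missv <- setdiff(VARIANT_COLS, names(v))
  if (length(missv)) msg <- c(msg, paste("variants missing columns:",
                                         paste(missv, collapse = ", ")))
  if (length(msg)) return(msg)

  if (anyDuplicated(p$patient_id))
    msg <- c(msg, "duplicated patient_id in manifest")
  orphan <- setdiff(unique(v$patient_id), p$patient_id)
  if (length(orphan))
    msg <- c(msg, paste("variant rows for unknown patient(s):",
                        paste(utils::head(orphan, 5L), collapse = ", ")))
  badtp <- setdiff(unique(v$timepoint), TIMEPOINTS)
  if (length(badtp))
    msg <- c(msg, paste("invalid timepoint(s):", paste(badtp, collapse = ", ")))
  if (nrow(v)) {
    okvaf <- is.na(v$vaf) | (v$vaf >= 0 & v$vaf <= 1)
    if (!all(okvaf))
      msg <- c(msg, "vaf outside [0, 1]; did you forget percent conversion?")
    if (any(v$gene == "" | is.na(v$gene)))
      msg <- c(msg, "empty gene symbol in variants")
    bada <- setdiff(unique(v$assay), ASSAYS)
    if (length(bada))
      msg <- c(msg, paste("invalid assay value(s):",
                          paste(bada, collapse = ", ")))
  }
  # one record per patient per timepoint is a sample-level notion; variant
  # tables legitimately hold many rows per (patient, timepoint). The date
  # skeleton carries the per-timepoint uniqueness instead.
  ord <- dateOrderViolations(p)
  if (length(ord)) msg <- c(msg, ord)
  if (length(msg)) msg else TRUE
}

dateOrderViolations <- function(p) {
  msg <- character()
  for (i in seq_len(nrow(p))) {
    r <- p[i, ]
    times <- c(r$t_diagnosis, r$t_cmr, r$t_relapse, r$t_death_or_censor)
    lab <- c("t_diagnosis", "t_cmr", "t_relapse", "t_death_or_censor")
    keep <- !is.na(times)
    tt <- times[keep]
    if (length(tt) > 1L && any(diff(tt) < 0)) {
      msg <- c(msg, paste0("patient ", r$patient_id,
                           ": event dates out of order (",
                           paste(lab[keep], "=", tt, collapse = ", "), ")"))
    }
    if (isTRUE(r$death) && is.na(r$t_death_or_censor)) {
      msg <- c(msg, paste0("patient ", r$patient_id,
                           ": death = TRUE but no t_death_or_censor"))
    }
  }
  msg
}

#' Construct an AmlCohort
#'
#' @param patients patient manifest data.frame (see [AmlCohort-class]).
#' @param variants variant-call data.frame; `is_germline`/`is_coding` are
#'   added (FALSE/TRUE) when absent.
#' @param panelGenes character vector of panel gene symbols.
#' @param provenance free-text provenance string.
#' @return A validated [AmlCohort-class] object.
#' @examples
#' fx <- buildReferenceFixture()
#' fx
#' @export
AmlCohort <- function(patients, variants, panelGenes = character(),
                      provenance = "") {
  stopifnot_cols(patients, setdiff(PATIENT_COLS, "eln_risk"), "patient manifest")
  if (!"eln_risk" %in% names(patients)) {
    patients$eln_risk <- deriveElnRisk(patients$flt3_itd, patients$flt3_ratio)
  }
  stopifnot_cols(variants, setdiff(VARIANT_COLS, c("is_germline", "is_coding")),
                 "variant table")
  if (!"is_germline" %in% names(variants))
    variants$is_germline <- rep(FALSE, nrow(variants))
  if (!"is_coding" %in% names(variants))
    variants$is_coding <- rep(TRUE, nrow(variants))
  patients <- as.data.frame(patients)[, PATIENT_COLS]
  variants <- as.data.frame(variants)[, VARIANT_COLS]
  rownames(patients) <- NULL
  rownames(variants) <- NULL
  obj <- methods::new("AmlCohort", patients = patients, variants = variants,
                      panelGenes = as.character(panelGenes),
                      provenance = provenance)
  err <- validAmlCohort(obj)
  if (!isTRUE(err)) stop("invalid cohort:\n  ", paste(err, collapse = "\n  "))
  obj
}

setValidity("AmlCohort", validAmlCohort)

#' @describeIn AmlCohort-class patient manifest accessor
#' @param x an `AmlCohort`
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))

#' @rdname AmlCohort-class
#' @export
setMethod("patients", "AmlCohort", function(x) x@patients)

#' @describeIn AmlCohort-class variant table accessor
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname AmlCohort-class
#' @export
setMethod("variants", "AmlCohort", function(x) x@variants)

#' @describeIn AmlCohort-class panel gene accessor
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname AmlCohort-class
#' @export
setMethod("panelGenes", "AmlCohort", function(x) x@panelGenes)

#' @describeIn AmlCohort-class replace the variant table (used by filters)
#' @param value replacement variant data.frame
#' @export
setGeneric("variants<-", function(x, value) standardGeneric("variants<-"))

#' @rdname AmlCohort-class
#' @export
setMethod("variants<-", "AmlCohort", function(x, value) {
  x@variants <- as.data.frame(value)[, VARIANT_COLS]
  rownames(x@variants) <- NULL
  methods::validObject(x)
  x
})

setMethod("show", "AmlCohort", function(object) {
  p <- object@patients
  v <- object@variants
  cat("AmlCohort with", nrow(p), "patients and", nrow(v), "variant calls\n")
  tp <- table(factor(v$timepoint, levels = TIMEPOINTS))
  cat("  calls per timepoint:",
      paste(names(tp), tp, sep = "=", collapse = ", "), "\n")
  cat("  relapsed:", sum(!is.na(p$t_relapse)),
      "| relapse samples:", length(relapseSamplePatients(object)), "\n")
  if (length(object@panelGenes))
    cat("  panel:", length(object@panelGenes), "genes\n")
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

#' Patients with a sequenced relapse sample
#'
#' A patient may relapse clinically without a relapse sample being available;
#' relapse-timepoint analyses are restricted to patients with at least one
#' variant call (including the NPM1 index mutation) at the RELAPSE timepoint.
#'
#' @param cohort an [AmlCohort-class]
#' @return character vector of patient ids.
#' @export
relapseSamplePatients <- function(cohort) {
  v <- variants(cohort)
  sort(unique(v$patient_id[v$timepoint == "RELAPSE"]))
}

#' Timepoints with an available sample, per patient
#'
#' Every patient in a CMR-defined cohort has diagnosis and CMR samples by
#' design; a RELAPSE sample is available when the patient has any variant
#' call at RELAPSE. Used by the germline filter, whose "across all
#' timepoints" rule refers to available samples, not to calendar events.
#'
#' @param cohort an [AmlCohort-class]
#' @return named list mapping patient_id to a character vector of timepoints.
#' @export
availableTimepoints <- function(cohort) {
  ids <- patients(cohort)$patient_id
  rel <- relapseSamplePatients(cohort)
  out <- lapply(ids, function(id) {
    if (id %in% rel) TIMEPOINTS else TIMEPOINTS[1:2]
  })
  names(out) <- ids
  out
}
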