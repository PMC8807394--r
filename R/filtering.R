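# Variant-retention rules: cross-timepoint germline exclusion, detection
# cutoffs, and panel / coding-region restriction.

#' Filtering configuration
#'
#' @param vafCutoffCmr detection cutoff at CMR as a fraction; default 0.01,
#'   i.e. variants with VAF below 1\% at CMR are treated as not detected
#'   (the cutoff itself is inclusive: VAF >= 1\% is detected).
#' @param vafCutoffDiagnosis,vafCutoffRelapse cutoffs applied at the other
#'   timepoints; default to the CMR cutoff for symmetry.
#' @param germlineTolerance half-width of the germline VAF bands around 0.5
#'   (heterozygous) and 1.0 (homozygous); default 0.05, a standard heuristic
#'   at panel depth. Must lie in (0, 0.25).
#' @param strictGermlineCenter if TRUE a candidate must match one consistent
#'   center across timepoints; the default (FALSE) lets observations match
#'   either center (a 0.49 then 0.98 pattern can reflect LOH).
#' @param restrictToPanel drop genes outside the panel (never NPM1, never
#'   gene-scan calls).
#' @param wgsMode for WGS-style cohorts: disable the panel restriction and
#'   honor the per-row `is_coding` flag instead.
#' @return object of class `FilterConfig`.
#' @export
filterConfig <- function(vafCutoffCmr = 0.01,
                         vafCutoffDiagnosis = vafCutoffCmr,
                         vafCutoffRelapse = vafCutoffCmr,
                         germlineTolerance = 0.05,
                         strictGermlineCenter = FALSE,
                         restrictToPanel = FALSE,
                         wgsMode = FALSE) {
  if (!(germlineTolerance > 0 && germlineTolerance < 0.25))
    stop("germlineTolerance must be in (0, 0.25)")
  if (!(vafCutoffCmr > 0 && vafCutoffCmr < 0.5 - germlineTolerance))
    stop("vafCutoffCmr must sit below the lower germline band (0.5 - tol)")
  structure(list(vaf_cutoff_cmr = vafCutoffCmr,
                 vaf_cutoff_diagnosis = vafCutoffDiagnosis,
                 vaf_cutoff_relapse = vafCutoffRelapse,
                 germline_tolerance = germlineTolerance,
                 strict_germline_center = strictGermlineCenter,
                 restrict_to_panel = restrictToPanel,
                 wgs_mode = wgsMode),
            class = "FilterConfig")
}

inGermlineBand <- function(vaf, tol) {
  het <- abs(vaf - 0.5) <= tol
  hom <- abs(vaf - 1.0) <= tol
  cbind(het = het, hom = hom)
}

#' Flag putative germline variants by cross-timepoint VAF
#'
#' Paired sampling lets germline variants be recognized without a matched
#' normal: a heterozygous (homozygous) germline variant sits near 50\%
#' (100\%) VAF at every timepoint, while somatic clones wax and wane. A
#' matched variant (same patient, gene, variant_id) is flagged germline iff
#' it is observed at every available timepoint of its patient and every
#' observation lies within tolerance of 0.5 or of 1.0. Absence at any
#' available timepoint, or one observation outside both bands, disqualifies.
#'
#' Presence-only calls (gene scan, no VAF) are never flagged.
#'
#' @param variants variant data.frame (one or many patients).
#' @param available named list from [availableTimepoints()] giving, per
#'   patient, the timepoints with a sample.
#' @param config a [filterConfig()].
#' @return `variants` with `is_germline` set.
#' @export
flagGermline <- function(variants, available, config = filterConfig()) {
  v <- variants
  if (nrow(v) == 0L) return(v)
  v$is_germline <- FALSE
  tol <- config$germline_tolerance
  novaf <- is.na(v$vaf)
  if (any(novaf)) {
    warning("presence-only calls (no VAF) are never flagged germline (",
            sum(novaf), " row(s))")
  }
  key <- paste(v$patient_id, v$gene, v$variant_id, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    pid <- v$patient_id[idx[1L]]
    need <- available[[pid]]
    if (is.null(need)) need <- TIMEPOINTS[1:2]
    seen <- unique(v$timepoint[idx])
    if (!all(need %in% seen)) next           # absent somewhere: somatic
    vafs <- v$vaf[idx]
    if (anyNA(vafs)) next                    # presence-only never flagged
    bands <- inGermlineBand(vafs, tol)
    if (config$strict_germline_center) {
      germ <- all(bands[, "het"]) || all(bands[, "hom"])
    } else {
      germ <- all(bands[, "het"] | bands[, "hom"])
    }
    if (germ) v$is_germline[idx] <- TRUE
  }
  v
}

#' Apply per-timepoint detection cutoffs
#'
#' Variants whose VAF falls below the configured cutoff at their timepoint
#' are treated as not detected and removed. The CMR cutoff is the published
#' one (>= 1\% detected); diagnosis and relapse default to the same value.
#' Presence-only calls (no VAF) pass through.
#'
#' @inheritParams flagGermline
#' @return filtered variant data.frame.
#' @export
applyDetectionCutoff <- function(variants, config = filterConfig()) {
  if (nrow(variants) == 0L) return(variants)
  cut <- c(DIAGNOSIS = config$vaf_cutoff_diagnosis,
           CMR = config$vaf_cutoff_cmr,
           RELAPSE = config$vaf_cutoff_relapse)[variants$timepoint]
  keep <- is.na(variants$vaf) | variants$vaf >= cut
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict calls to the gene panel (or to coding regions)
#'
#' Panel cohorts: keep variants whose gene is on the panel, plus the NPM1
#' index mutation and gene-scan (FLT3-ITD) calls, which are tracked outside
#' the panel chemistry. WGS cohorts: the panel restriction is meaningless;
#' the per-row `is_coding` flag is honored instead.
#'
#' @param variants variant data.frame.
#' @param panel character vector of panel genes.
#' @param wgsMode honor `is_coding` instead of the panel.
#' @return filtered variant data.frame.
#' @export
restrictToPanel <- function(variants, panel, wgsMode = FALSE) {
  if (nrow(variants) == 0L) return(variants)
  if (wgsMode) {
    keep <- variants$is_coding | variants$assay == "GENE_SCAN"
  } else {
    if (length(panel) == 0L) stop("panel restriction enabled with empty panel")
    keep <- variants$gene %in% panel |
      variants$gene == "NPM1" |
      variants$assay == "GENE_SCAN"
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full retention pipeline on a cohort
#'
#' Order: germline flagging (needs all timepoints, so it runs before any
#' removal), detection cutoffs, then panel/coding restriction. Germline rows
#' are dropped unless `keepGermline = TRUE`, in which case they stay with
#' `is_germline = TRUE` set (downstream trajectory/stratification operations
#' exclude them either way).
#'
#' @param cohort an [AmlCohort-class].
#' @param config a [filterConfig()].
#' @param keepGermline keep flagged rows in the table.
#' @return the cohort with a filtered variant table.
#' @export
filterVariants <- function(cohort, config = filterConfig(),
                           keepGermline = FALSE) {
  v <- variants(cohort)
  v <- flagGermline(v, availableTimepoints(cohort), config)
  if (!keepGermline) v <- v[!v$is_germline, , drop = FALSE]
  v <- applyDetectionCutoff(v, config)
  if (config$wgs_mode) {
    v <- restrictToPanel(v, character(), wgsMode = TRUE)
  } else if (config$restrict_to_panel) {
    v <- restrictToPanel(v, panelGenes(cohort))
  }
  variants(cohort) <- v
  cohort
}
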