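# Matching mutations across timepoints and classifying their trajectories.

CMR_LABELS <- c("LOST", "PERSISTENT", "ACQUIRED")
RELAPSE_PATTERNS <- c("D_ONLY", "D_CMR", "D_CMR_R", "D_R",
                      "CMR_R", "R_ONLY", "CMR_ONLY")

#' Match variant observations into cross-timepoint events
#'
#' Observations of one patient sharing (gene, variant_id) across timepoints
#' form one trajectory event. When the variant_id is blank on one side and
#' the patient has exactly one identified variant chain in that gene, the
#' blank observations fall back to gene-level matching (with a warning);
#' with two or more distinct identified variants in the gene, blanks form
#' their own event. Two same-gene, different-id observations at one
#' timepoint stay two events. Duplicate observations of one variant at one
#' timepoint collapse to the maximum VAF.
#'
#' NPM1 (the index mutation), germline-flagged rows and presence-only
#' gene-scan calls are excluded from events.
#'
#' @param variants variant data.frame (already filtered).
#' @param relapsePatients character vector of patients with a relapse
#'   sample; events of other patients get `has_relapse_sample = FALSE` and
#'   no relapse pattern.
#' @return data.frame of events: `patient_id`, `gene`, `variant_id`,
#'   `at_d`, `at_cmr`, `at_r`, `vaf_d`, `vaf_cmr`, `vaf_r`,
#'   `has_relapse_sample`, `cmr_label`, `relapse_pattern`.
#' @export
matchEvents <- function(variants, relapsePatients = character()) {
  v <- variants[!variants$is_germline &
                  variants$gene != "NPM1" &
                  variants$assay != "GENE_SCAN", , drop = FALSE]
  out <- list()
  if (nrow(v)) {
    pg <- paste(v$patient_id, v$gene, sep = "\r")
    fellBack <- FALSE
    for (k in unique(pg)) {
      rows <- v[pg == k, , drop = FALSE]
      ids <- unique(rows$variant_id[nzchar(rows$variant_id)])
      if (length(ids) == 1L && any(!nzchar(rows$variant_id))) {
        rows$variant_id <- ids      # gene-level fallback
        fellBack <- TRUE
      }
      for (id in unique(rows$variant_id)) {
        obs <- rows[rows$variant_id == id, , drop = FALSE]
        vafAt <- function(tp) {
          x <- obs$vaf[obs$timepoint == tp]
          if (length(x) == 0L) NA_real_ else suppressWarnings(max(x, na.rm = TRUE))
        }
        out[[length(out) + 1L]] <- data.frame(
          patient_id = obs$patient_id[1L], gene = obs$gene[1L],
          variant_id = id,
          at_d = "DIAGNOSIS" %in% obs$timepoint,
          at_cmr = "CMR" %in% obs$timepoint,
          at_r = "RELAPSE" %in% obs$timepoint,
          vaf_d = vafAt("DIAGNOSIS"), vaf_cmr = vafAt("CMR"),
          vaf_r = vafAt("RELAPSE"),
          stringsAsFactors = FALSE)
      }
    }
    if (fellBack)
      warning("blank variant_id matched to the gene's single identified variant")
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(), gene = character(),
               variant_id = character(), at_d = logical(),
               at_cmr = logical(), at_r = logical(), vaf_d = numeric(),
               vaf_cmr = numeric(), vaf_r = numeric(),
               stringsAsFactors = FALSE)
  ev$has_relapse_sample <- ev$patient_id %in% relapsePatients
  ev$cmr_label <- classifyCmr(ev)
  ev$relapse_pattern <- classifyRelapsePattern(ev)
  rownames(ev) <- NULL
  ev
}

#' Classify the diagnosis-to-CMR trajectory of events
#'
#' LOST: present at diagnosis, absent at CMR. PERSISTENT: present at both.
#' ACQUIRED: present at CMR only. Events present at neither (relapse-only
#' observations) get `NA`: they have no diagnosis-to-CMR trajectory.
#' A CMR observation removed by the detection cutoff counts as absent, so a
#' diagnosis mutation dropping below 1\% at CMR classifies as LOST.
#'
#' @param events event data.frame from [matchEvents()].
#' @return character vector of labels.
#' @export
classifyCmr <- function(events) {
  if (nrow(events) == 0L) return(character())
  nowhere <- !events$at_d & !events$at_cmr & !events$at_r
  if (any(nowhere)) stop("event present at no timepoint should not exist")
  ifelse(events$at_d & !events$at_cmr, "LOST",
         ifelse(events$at_d & events$at_cmr, "PERSISTENT",
                ifelse(events$at_cmr, "ACQUIRED", NA_character_)))
}

#' Presence signature over the three timepoints
#'
#' Exhaustive over the seven non-empty signatures of (diagnosis, CMR,
#' relapse) presence. The vector form is exported so the enumeration can be
#' tested directly.
#'
#' @param d,cmr,r logical vectors of presence.
#' @return character vector of pattern names (`D_ONLY`, `D_CMR`, `D_CMR_R`,
#'   `D_R`, `CMR_R`, `R_ONLY`, `CMR_ONLY`).
#' @export
patternFromPresence <- function(d, cmr, r) {
  code <- paste0(as.integer(d), as.integer(cmr), as.integer(r))
  map <- c(`100` = "D_ONLY", `110` = "D_CMR", `111` = "D_CMR_R",
           `101` = "D_R", `011` = "CMR_R", `001` = "R_ONLY",
           `010` = "CMR_ONLY")
  out <- unname(map[code])
  if (any(code == "000")) stop("empty presence signature")
  out
}

#' Classify three-timepoint relapse patterns
#'
#' Defined only for events of patients with a relapse sample; others get
#' `NA`.
#'
#' @param events event data.frame.
#' @return character vector of patterns.
#' @export
classifyRelapsePattern <- function(events) {
  if (nrow(events) == 0L) return(character())
  out <- rep(NA_character_, nrow(events))
  has <- events$has_relapse_sample
  if (any(has)) {
    out[has] <- patternFromPresence(events$at_d[has], events$at_cmr[has],
                                    events$at_r[has])
  }
  out
}

#' Per-gene trajectory pattern summaries
#'
#' Aggregates diagnosis-to-CMR labels over the cohort's events: fractions of
#' lost / persistent / acquired per gene, and a pattern class when the gene
#' has at least `minEvents` events: `MOSTLY_LOST` if the lost fraction
#' reaches `dominanceThreshold`, `MOSTLY_ACQUIRED` analogously, else
#' `HETEROGENEOUS`. The default threshold 0.70 places a gene lost in 71\% of
#' events in the mostly-lost group.
#'
#' @param events event data.frame.
#' @param minEvents minimum events for a pattern class (default 2).
#' @param dominanceThreshold fraction needed for a `MOSTLY_*` class.
#' @return data.frame: `gene`, `n_events`, `frac_lost`, `frac_persistent`,
#'   `frac_acquired`, `pattern_class` (NA below `minEvents`).
#' @export
summarizeGenePatterns <- function(events, minEvents = 2,
                                  dominanceThreshold = 0.70) {
  ev <- events[!is.na(events$cmr_label), , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(gene = character(), n_events = integer(),
                      frac_lost = numeric(), frac_persistent = numeric(),
                      frac_acquired = numeric(),
                      pattern_class = character(), stringsAsFactors = FALSE))
  }
  genes <- sort(unique(ev$gene))
  rows <- lapply(genes, function(g) {
    lab <- ev$cmr_label[ev$gene == g]
    n <- length(lab)
    fl <- mean(lab == "LOST"); fp <- mean(lab == "PERSISTENT")
    fa <- mean(lab == "ACQUIRED")
    cls <- if (n >= minEvents) {
      if (fl >= dominanceThreshold) "MOSTLY_LOST"
      else if (fa >= dominanceThreshold) "MOSTLY_ACQUIRED"
      else "HETEROGENEOUS"
    } else NA_character_
    data.frame(gene = g, n_events = n, frac_lost = fl, frac_persistent = fp,
               frac_acquired = fa, pattern_class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build classified trajectory events for a cohort
#'
#' Convenience wrapper: [matchEvents()] with the cohort's relapse-sample set.
#'
#' @param cohort an [AmlCohort-class] (filter first with [filterVariants()]).
#' @return classified event data.frame.
#' @export
buildEvents <- function(cohort) {
  matchEvents(variants(cohort), relapseSamplePatients(cohort))
}
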