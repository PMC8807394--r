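# Gene categorization schemes (DTA, CHIP5, CHIP6) and patient stratification
# at CMR and relapse, plus the inductive derivation of a scheme from
# trajectory patterns.

DTA_GENES <- c("DNMT3A", "TET2", "ASXL1")
CHIP5_GENES <- c("DNMT3A", "TET2", "IDH1", "IDH2", "SRSF2")
CHIP6_GENES <- sort(c(CHIP5_GENES, "ASXL1"))

#' Gene categorization scheme
#'
#' Three fixed schemes plus a custom one. `CHIP5` is the panel-cohort
#' definition of CHIP-like genes (DNMT3A, TET2, IDH1, IDH2, SRSF2 — ASXL1
#' excluded as a rarity in NPM1-mutated AML); `CHIP6` adds ASXL1 (the
#' WGS-cohort variant); `DTA` is the classical DNMT3A/TET2/ASXL1 split. All
#' non-CHIP (non-DTA) genes are CHOP-like (NON_DTA): the positive set and
#' its complement partition the non-NPM1 gene universe.
#'
#' @param name `"CHIP5"`, `"CHIP6"`, `"DTA"` or `"CUSTOM"`.
#' @param chipGenes for `"CUSTOM"`: the CHIP-like gene set.
#' @return object of class `GeneScheme` with fields `name`, `chip_genes`,
#'   and the stratum labels it produces.
#' @examples
#' categorizeGene("ASXL1", geneScheme("CHIP5"))  # CHOP
#' categorizeGene("ASXL1", geneScheme("CHIP6"))  # CHIP
#' @export
geneScheme <- function(name = c("CHIP5", "CHIP6", "DTA", "CUSTOM"),
                       chipGenes = NULL) {
  name <- match.arg(name)
  chip <- switch(name,
                 CHIP5 = CHIP5_GENES,
                 CHIP6 = CHIP6_GENES,
                 DTA = DTA_GENES,
                 CUSTOM = {
                   if (is.null(chipGenes) || length(chipGenes) == 0L)
                     stop("CUSTOM scheme needs chipGenes")
                   sort(unique(chipGenes))
                 })
  if ("NPM1" %in% chip) stop("NPM1 is the index mutation, never categorized")
  labels <- if (name == "DTA") {
    c(none = "NONE", pos = "DTA_ONLY", neg = "NON_DTA")
  } else {
    c(none = "NONE", pos = "CHIP_ONLY", neg = "CHOP")
  }
  structure(list(name = name, chip_genes = chip, labels = labels),
            class = "GeneScheme")
}

#' Categorize a gene under a scheme
#'
#' Deterministic set membership; NPM1 is never categorized (error).
#'
#' @param gene gene symbol(s).
#' @param scheme a [geneScheme()].
#' @return `"CHIP"`/`"CHOP"` (or `"DTA"`/`"NON_DTA"` under the DTA scheme).
#' @export
categorizeGene <- function(gene, scheme = geneScheme("CHIP5")) {
  if (any(gene == "NPM1"))
    stop("NPM1 is the index mutation, never categorized")
  if (any(!nzchar(gene))) stop("empty gene symbol")
  pos <- if (scheme$name == "DTA") "DTA" else "CHIP"
  neg <- if (scheme$name == "DTA") "NON_DTA" else "CHOP"
  ifelse(gene %in% scheme$chip_genes, pos, neg)
}

basisString <- function(ev) {
  if (nrow(ev) == 0L) return("")
  paste(paste0(ev$gene, ":", ev$cmr_label), collapse = ";")
}

#' Stratify patients at CMR by persistent/acquired mutations
#'
#' Considers only PERSISTENT and ACQUIRED events (what is detectable in the
#' remission sample). `NONE` when a patient has no such event; the negative
#' (CHOP / NON_DTA) stratum when any such event's gene falls outside the
#' scheme's CHIP set — the oncogenic category dominates — else the positive
#' stratum (CHIP_ONLY / DTA_ONLY). Separate persistent-only and
#' acquired-only views are available through `basis`.
#'
#' @param events classified event data.frame.
#' @param scheme a [geneScheme()].
#' @param patientIds full patient universe (patients without events are
#'   `NONE`).
#' @param basis which events count: `"either"` (default), `"persistent"`,
#'   `"acquired"`.
#' @return data.frame: `patient_id`, `scheme`, `cmr_stratum`, `basis` (the
#'   gene:label pairs driving the call).
#' @export
stratifyPatientsCmr <- function(events, scheme, patientIds,
                                basis = c("either", "persistent", "acquired")) {
  basis <- match.arg(basis)
  want <- switch(basis, either = c("PERSISTENT", "ACQUIRED"),
                 persistent = "PERSISTENT", acquired = "ACQUIRED")
  ev <- events[!is.na(events$cmr_label) & events$cmr_label %in% want, ,
               drop = FALSE]
  rows <- lapply(patientIds, function(pid) {
    mine <- ev[ev$patient_id == pid, , drop = FALSE]
    stratum <- if (nrow(mine) == 0L) {
      scheme$labels[["none"]]
    } else if (any(!(mine$gene %in% scheme$chip_genes))) {
      scheme$labels[["neg"]]
    } else {
      scheme$labels[["pos"]]
    }
    data.frame(patient_id = pid, scheme = scheme$name,
               cmr_stratum = stratum, basis = basisString(mine),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratify relapse-sample patients by CHOP-like mutations at relapse
#'
#' Default semantics: a patient is in the `CHOP` relapse stratum when any
#' CHOP-gene event is present at relapse (patterns `D_CMR_R`, `D_R`,
#' `CMR_R`, `R_ONLY`); else `NO_CHOP`. With `acquiredOnly = TRUE` only
#' events absent at diagnosis count (`CMR_R`, `R_ONLY`) — the
#' "acquired oncogenic mutations at relapse" reading.
#'
#' @param events classified event data.frame.
#' @param scheme a [geneScheme()].
#' @param acquiredOnly restrict to events absent at diagnosis.
#' @return data.frame: `patient_id`, `scheme`, `relapse_stratum`, `basis`.
#' @export
stratifyPatientsRelapse <- function(events, scheme, acquiredOnly = FALSE) {
  ev <- events[events$has_relapse_sample, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events from patients with a relapse sample")
  atR <- if (acquiredOnly) c("CMR_R", "R_ONLY") else
    c("D_CMR_R", "D_R", "CMR_R", "R_ONLY")
  ids <- sort(unique(ev$patient_id))
  rows <- lapply(ids, function(pid) {
    mine <- ev[ev$patient_id == pid &
                 ev$relapse_pattern %in% atR &
                 !(ev$gene %in% scheme$chip_genes), , drop = FALSE]
    data.frame(patient_id = pid, scheme = scheme$name,
               relapse_stratum = if (nrow(mine)) "CHOP" else "NO_CHOP",
               basis = if (nrow(mine))
                 paste(paste0(mine$gene, ":", mine$relapse_pattern),
                       collapse = ";") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive a CHIP/CHOP scheme from observed trajectory patterns
#'
#' Inductive counterpart of the fixed schemes, run on the relapse subcohort
#' (three-timepoint resolution). Per gene with at least `minEvents` events
#' among relapse-sample patients: if the fraction of events present at all
#' three timepoints (`D_CMR_R`) reaches `modalThreshold`, the gene is
#' proposed CHIP-like (a persistent premalignant clone); else if the
#' combined fraction gained at CMR and persistent at relapse or de novo at
#' relapse (`CMR_R` + `R_ONLY`) reaches the threshold, it is proposed
#' CHOP-like; remaining genes are labeled by their diagnosis-to-CMR pattern
#' class (`MOSTLY_LOST` and `MOSTLY_ACQUIRED` propose CHOP,
#' `HETEROGENEOUS` stays unclassified). The proposal is reported alongside
#' the fixed schemes, never silently substituted.
#'
#' @param events classified event data.frame (whole cohort; the function
#'   restricts to relapse-sample patients).
#' @param minEvents minimum relapse-subcohort events per gene (default 2).
#' @param modalThreshold modal-signature fraction (default 0.5).
#' @param dominanceThreshold threshold for the fallback diagnosis-to-CMR
#'   class (default 0.7).
#' @return list: `chip`, `chop`, `unclassified` (gene vectors) and `table`
#'   (per-gene fractions), or an empty proposal with a `notice` when no gene
#'   reaches `minEvents`.
#' @export
deriveSchemeFromPatterns <- function(events, minEvents = 2,
                                     modalThreshold = 0.5,
                                     dominanceThreshold = 0.7) {
  sub <- events[events$has_relapse_sample & !is.na(events$relapse_pattern), ,
                drop = FALSE]
  counts <- table(sub$gene)
  genes <- sort(names(counts[counts >= minEvents]))
  if (length(genes) == 0L) {
    return(list(chip = character(), chop = character(),
                unclassified = character(),
                table = NULL,
                notice = "insufficient relapse data: no gene meets minEvents"))
  }
  pat <- summarizeGenePatterns(sub, minEvents = minEvents,
                               dominanceThreshold = dominanceThreshold)
  rows <- lapply(genes, function(g) {
    pp <- sub$relapse_pattern[sub$gene == g]
    n <- length(pp)
    fChip <- mean(pp == "D_CMR_R")
    fGain <- mean(pp %in% c("CMR_R", "R_ONLY"))
    cls <- pat$pattern_class[match(g, pat$gene)]
    proposal <- if (fChip >= modalThreshold) "CHIP"
    else if (fGain >= modalThreshold) "CHOP"
    else if (!is.na(cls) && cls %in% c("MOSTLY_LOST", "MOSTLY_ACQUIRED")) "CHOP"
    else "UNCLASSIFIED"
    data.frame(gene = g, n_events = n, frac_d_cmr_r = fChip,
               frac_gained = fGain, d_cmr_class = cls,
               proposal = proposal, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(chip = tab$gene[tab$proposal == "CHIP"],
       chop = tab$gene[tab$proposal == "CHOP"],
       unclassified = tab$gene[tab$proposal == "UNCLASSIFIED"],
       table = tab)
}
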