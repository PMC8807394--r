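# Deterministic reference fixture: a 150-patient cohort expanded from the
# published aggregate counts, so every pipeline stage is testable without
# access to patient-level data. The expansion is one frozen
# constraint-satisfying solution (found once by brute-force search over
# integer event counts; see the methods vignette), not a claim about the
# true patient-level data. Survival times are synthetic.

# frozen per-gene diagnosis->CMR event counts (lost / persistent / acquired)
FIXTURE_TRIPLES <- list(
  DNMT3A = c(20, 38, 10),   # 68 events -> 29/56/15 %
  TET2 = c(15, 9, 5),       # 29 events -> 52/31/17 %
  SRSF2 = c(13, 11, 5),     # 29 events -> 45/38/17 %
  IDH1 = c(17, 3, 1),       # 81 % lost
  IDH2 = c(22, 7, 2),       # 71 % lost
  NRAS = c(32, 0, 0), `FLT3-TKD` = c(26, 0, 0), PTPN11 = c(19, 0, 1),
  CEBPA = c(11, 0, 1), WT1 = c(14, 0, 3), GATA2 = c(12, 0, 0),
  KRAS = c(10, 0, 0), STAG2 = c(10, 0, 0), EZH2 = c(4, 1, 0),
  BCOR = c(7, 0, 0), TP53 = c(0, 0, 2), CSNK1A1 = c(0, 0, 1),
  SETBP1 = c(0, 0, 1), RUNX1 = c(0, 0, 4))

# patient-role assignments (patient indices 1..150)
FIXTURE_PERSISTENT <- list(DNMT3A = 1:38, TET2 = 32:40, SRSF2 = 41:51,
                           IDH1 = 52:54, IDH2 = 55:61, EZH2 = 62)
FIXTURE_ACQUIRED <- list(DNMT3A = c(3:8, 64:67), TET2 = c(9:11, 68:69),
                         SRSF2 = c(50, 50, 51, 61, 63), IDH1 = 50,
                         IDH2 = c(51, 61), PTPN11 = 41, CEBPA = 42,
                         WT1 = c(42, 48, 49), TP53 = c(43, 44),
                         RUNX1 = c(43, 45, 47, 49), CSNK1A1 = 45,
                         SETBP1 = 46)
# lost events pinned to relapse-subcohort patients (the rest are spread
# deterministically over the remaining patients)
FIXTURE_LOST_IN_S <- list(DNMT3A = 41:46, TET2 = 47:48, IDH2 = c(49, 52),
                          IDH1 = 53, SRSF2 = 54:55, PTPN11 = 56:58,
                          WT1 = 59:60, CEBPA = 62, GATA2 = 34,
                          NRAS = c(2, 12:15, 70), `FLT3-TKD` = 16:19,
                          BCOR = 32:33)
# relapse-timepoint presence
FIXTURE_DCR <- list(DNMT3A = c(1, 2, 12:19, 32:36), TET2 = 32:39,
                    SRSF2 = 41:48, IDH1 = 52:54, IDH2 = 55:60, EZH2 = 62)
FIXTURE_R_ONLY <- list(DNMT3A = 52:58, TET2 = c(59, 60, 62, 41:43),
                       IDH2 = 44:46, IDH1 = 47:48, SRSF2 = 1:2,
                       PTPN11 = 1:2, WT1 = c(1, 70), CEBPA = 2,
                       GATA2 = c(1, 2, 70), RUNX1 = 70)
FIXTURE_NRAS_DR_PATIENT <- 70L   # NRAS lost at CMR, re-emerging at relapse

fixtureRelapseSampleSet <- function() {
  sort(c(1:2, 12:19, 32:39, 41:49, 52:54, 55:60, 62, 70))
}

fixtureRelapsedSet <- function() {
  sort(c(fixtureRelapseSampleSet(), 3:8, 20:25, 50, 61))
}

#' Build the frozen reference fixture cohort
#'
#' A fully deterministic 150-patient NPM1-mutated AML cohort whose
#' patient-level variant table is a constraint-satisfying expansion of
#' published aggregate counts: 301 non-NPM1 diagnosis mutations, 105 CMR
#' mutations, 81 patients without and 69 with persistent/acquired CMR
#' mutations, 40 patients with persisting DTA and 22 with persisting
#' non-DTA mutations, 23 with persistent-or-acquired non-DTA mutations, 10
#' CHOP-stratum and 59 CHIP-only patients (CHIP5 scheme), 52 relapses with
#' 38 sequenced relapse samples carrying 84 mutations, 13 of the 38 in the
#' relapse CHOP stratum, and per-gene diagnosis-to-CMR trajectory fractions
#' for DNMT3A (29/56/15), TET2 (52/31/17) and SRSF2 (45/38/17) realized by
#' integer event counts. Every load re-runs the full constraint self-check.
#'
#' Survival times, VAF values and demographics are synthetic scaffolding:
#' the fixture pins mutation bookkeeping, not outcome statistics.
#'
#' @return an [AmlCohort-class].
#' @examples
#' fx <- buildReferenceFixture()
#' nrow(patients(fx))
#' @export
buildReferenceFixture <- function() {
  n <- 150L
  S <- fixtureRelapseSampleSet()
  relapsed <- fixtureRelapsedSet()

  ev <- list()
  addEvent <- function(pi, gene, vid, d, cmr, r) {
    ev[[length(ev) + 1L]] <<- data.frame(pi = pi, gene = gene,
                                         variant_id = vid, at_d = d,
                                         at_cmr = cmr, at_r = r,
                                         stringsAsFactors = FALSE)
  }
  for (g in names(FIXTURE_PERSISTENT)) {
    for (pi in FIXTURE_PERSISTENT[[g]]) {
      addEvent(pi, g, sprintf("%s.p%03d", g, pi), TRUE, TRUE,
               pi %in% (FIXTURE_DCR[[g]] %||% integer()))
    }
  }
  for (g in names(FIXTURE_ACQUIRED)) {
    pis <- FIXTURE_ACQUIRED[[g]]
    for (j in seq_along(pis)) {
      pi <- pis[j]
      # acquired CHOP-gene events of CMR-CHOP patients persist at relapse
      atR <- pi %in% S && !(g %in% CHIP5_GENES)
      addEvent(pi, g, sprintf("%s.a%03d.%d", g, pi, j), FALSE, TRUE, atR)
    }
  }
  for (g in names(FIXTURE_LOST_IN_S)) {
    for (pi in FIXTURE_LOST_IN_S[[g]]) {
      atR <- g == "NRAS" && pi == FIXTURE_NRAS_DR_PATIENT
      addEvent(pi, g, sprintf("%s.l%03d", g, pi), TRUE, FALSE, atR)
    }
  }
  for (g in names(FIXTURE_R_ONLY)) {
    for (pi in FIXTURE_R_ONLY[[g]]) {
      addEvent(pi, g, sprintf("%s.r%03d", g, pi), FALSE, FALSE, TRUE)
    }
  }
  # spread the remaining lost events over patients outside the relapse
  # subcohort, cycling deterministically
  nonS <- setdiff(seq_len(n), S)
  offset <- 0L
  for (g in names(FIXTURE_TRIPLES)) {
    remaining <- FIXTURE_TRIPLES[[g]][1L] -
      length(FIXTURE_LOST_IN_S[[g]] %||% integer())
    if (remaining <= 0L) next
    slots <- nonS[((offset + seq_len(remaining) - 1L) %% length(nonS)) + 1L]
    for (pi in slots) addEvent(pi, g, sprintf("%s.l%03d", g, pi),
                               TRUE, FALSE, FALSE)
    offset <- offset + remaining + 3L
  }
  events <- do.call(rbind, ev)

  # deterministic VAFs
  vafD <- 0.38 + 0.002 * ((events$pi * 3L +
                             as.integer(factor(events$gene))) %% 30L)
  vafCmr <- ifelse(events$at_d, 0.02 + 0.003 * (events$pi %% 20L),
                   0.012 + 0.002 * (events$pi %% 15L))
  vafR <- 0.25 + 0.005 * (events$pi %% 30L)

  mkRows <- function(sel, tp, vaf) {
    e <- events[sel, , drop = FALSE]
    data.frame(patient_id = sprintf("P%03d", e$pi), timepoint = tp,
               gene = e$gene, variant_id = e$variant_id, vaf = vaf[sel],
               assay = "PANEL", is_germline = FALSE, is_coding = TRUE,
               stringsAsFactors = FALSE)
  }
  # NPM1: second hit (below the founder clone) for most co-mutated patients
  maxco <- rep(NA_real_, n)
  dvaf <- tapply(vafD[events$at_d], events$pi[events$at_d], max)
  maxco[as.integer(names(dvaf))] <- dvaf
  npm1 <- ifelse(is.na(maxco), 0.40,
                 ifelse(seq_len(n) %% 10L == 0L, pmin(0.52, maxco + 0.05),
                        pmax(0.05, maxco - 0.06)))
  itd <- seq_len(n) <= 51L
  itdR <- sort(intersect(S, which(itd)))[1:11]

  vtab <- rbind(
    mkRows(events$at_d, "DIAGNOSIS", vafD),
    mkRows(events$at_cmr, "CMR", vafCmr),
    mkRows(events$at_r, "RELAPSE", vafR),
    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               timepoint = "DIAGNOSIS", gene = "NPM1", variant_id = "W288fs",
               vaf = npm1, assay = "PANEL", is_germline = FALSE,
               is_coding = TRUE, stringsAsFactors = FALSE),
    data.frame(patient_id = sprintf("P%03d", S), timepoint = "RELAPSE",
               gene = "NPM1", variant_id = "W288fs",
               vaf = 0.30 + 0.004 * (S %% 20L), assay = "PANEL",
               is_germline = FALSE, is_coding = TRUE, stringsAsFactors = FALSE),
    data.frame(patient_id = sprintf("P%03d", which(itd)),
               timepoint = "DIAGNOSIS", gene = "FLT3", variant_id = "ITD",
               vaf = NA_real_, assay = "GENE_SCAN", is_germline = FALSE,
               is_coding = TRUE, stringsAsFactors = FALSE),
    data.frame(patient_id = sprintf("P%03d", itdR), timepoint = "RELAPSE",
               gene = "FLT3", variant_id = "ITD", vaf = NA_real_,
               assay = "GENE_SCAN", is_germline = FALSE, is_coding = TRUE,
               stringsAsFactors = FALSE))

  i <- seq_len(n)
  ratio <- rep(NA_real_, n)
  ratio[1:31] <- round(0.55 + 0.02 * (1:31 %% 20L), 2)   # intermediate
  ratio[32:48] <- round(0.10 + 0.02 * (1:17), 2)         # favorable, < 0.5
  ratio[49:51] <- 0.5                                    # boundary -> NA risk
  isRel <- i %in% relapsed
  t_cmr <- 90 + (i %% 60L)
  t_rel <- ifelse(isRel, t_cmr + 200 + 10 * (i %% 40L), NA_real_)
  dead <- (isRel & (i %% 3L != 0L)) | (!isRel & (i %% 11L == 0L))
  t_last <- ifelse(isRel & dead, t_rel + 120 + 15 * (i %% 12L),
                   ifelse(isRel, t_rel + 400 + 10 * (i %% 30L),
                          ifelse(dead, 600 + 8 * i, 1100 + 5 * i)))
  hsct <- rep("NONE", n)
  hsct[relapsed[1:27]] <- "AFTER_RELAPSE"
  upCand <- setdiff(i, relapsed[1:27])
  hsct[upCand[seq_len(34)]] <- "UPFRONT"

  ptab <- data.frame(patient_id = sprintf("P%03d", i),
                     age = 19 + ((i * 37L) %% 64L),
                     sex = ifelse(i <= 73L, "M", "F"),
                     karyotype_aberrant = i > 136L,
                     flt3_itd = itd, flt3_ratio = ratio,
                     eln_risk = deriveElnRisk(itd, ratio), hsct = hsct,
                     t_diagnosis = 0, t_cmr = t_cmr, t_relapse = t_rel,
                     t_death_or_censor = t_last, death = dead,
                     stringsAsFactors = FALSE)

  cohort <- AmlCohort(ptab, vtab,
                      panelGenes = unique(c(names(FIXTURE_TRIPLES), "RUNX1",
                                            "NPM1")),
                      provenance = "frozen reference fixture (synthetic expansion of published aggregate counts)")
  checkReferenceFixture(cohort)
  cohort
}

#' Verify the reference fixture against its frozen constraints
#'
#' Runs the actual pipeline (default filtering, event matching, CMR and
#' relapse classification, CHIP5/DTA stratification) on the cohort and
#' checks every frozen aggregate. Called on every [buildReferenceFixture()]
#' load; exported so the self-check is testable on its own.
#'
#' @param cohort the fixture cohort.
#' @return (invisibly) a named list of the recomputed aggregates.
#' @export
checkReferenceFixture <- function(cohort) {
  # the gene-scan rows trigger the (expected) presence-only warning
  fc <- suppressWarnings(filterVariants(cohort, filterConfig()))
  v <- variants(fc)
  evs <- buildEvents(fc)
  ids <- patients(fc)$patient_id
  pa <- evs[!is.na(evs$cmr_label) &
              evs$cmr_label %in% c("PERSISTENT", "ACQUIRED"), , drop = FALSE]
  persistent <- evs[!is.na(evs$cmr_label) & evs$cmr_label == "PERSISTENT", ,
                    drop = FALSE]
  chip5 <- geneScheme("CHIP5")
  strata <- stratifyPatientsCmr(evs, chip5, ids)
  relStrata <- stratifyPatientsRelapse(evs, chip5)
  tri <- function(g) {
    lab <- evs$cmr_label[evs$gene == g & !is.na(evs$cmr_label)]
    c(lost = sum(lab == "LOST"), pers = sum(lab == "PERSISTENT"),
      acq = sum(lab == "ACQUIRED"))
  }
  agg <- list(
    n_patients = length(ids),
    n_diag = sum(v$timepoint == "DIAGNOSIS" & v$gene != "NPM1" &
                   v$assay != "GENE_SCAN"),
    n_cmr = sum(v$timepoint == "CMR" & v$gene != "NPM1"),
    n_cmr_pos = length(unique(pa$patient_id)),
    n_pers_dta = length(unique(
      persistent$patient_id[persistent$gene %in% DTA_GENES])),
    n_pers_nondta = length(unique(
      persistent$patient_id[!(persistent$gene %in% DTA_GENES)])),
    n_pa_nondta = length(unique(pa$patient_id[!(pa$gene %in% DTA_GENES)])),
    n_chop = sum(strata$cmr_stratum == "CHOP"),
    n_chip_only = sum(strata$cmr_stratum == "CHIP_ONLY"),
    n_relapsed = sum(!is.na(patients(fc)$t_relapse)),
    n_relapse_samples = length(relapseSamplePatients(fc)),
    n_relapse_mut = sum(v$timepoint == "RELAPSE" & v$gene != "NPM1" &
                          v$assay != "GENE_SCAN"),
    n_relapse_chop = sum(relStrata$relapse_stratum == "CHOP"),
    dnmt3a = tri("DNMT3A"), tet2 = tri("TET2"), srsf2 = tri("SRSF2"))
  expect <- list(n_patients = 150L, n_diag = 301L, n_cmr = 105L,
                 n_cmr_pos = 69L, n_pers_dta = 40L, n_pers_nondta = 22L,
                 n_pa_nondta = 23L, n_chop = 10L, n_chip_only = 59L,
                 n_relapsed = 52L, n_relapse_samples = 38L,
                 n_relapse_mut = 84L, n_relapse_chop = 13L,
                 dnmt3a = c(lost = 20L, pers = 38L, acq = 10L),
                 tet2 = c(lost = 15L, pers = 9L, acq = 5L),
                 srsf2 = c(lost = 13L, pers = 11L, acq = 5L))
  for (k in names(expect)) {
    if (!isTRUE(all(agg[[k]] == expect[[k]]))) {
      stop("fixture self-check failed for ", k, ": got ",
           paste(agg[[k]], collapse = "/"), ", expected ",
           paste(expect[[k]], collapse = "/"))
    }
  }
  pcts <- list(dnmt3a = pct(agg$dnmt3a, sum(agg$dnmt3a)),
               tet2 = pct(agg$tet2, sum(agg$tet2)),
               srsf2 = pct(agg$srsf2, sum(agg$srsf2)))
  stopifnot(all(pcts$dnmt3a == c(29, 56, 15)),
            all(pcts$tet2 == c(52, 31, 17)),
            all(pcts$srsf2 == c(45, 38, 17)))
  invisible(agg)
}
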