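# Stochastic synthetic cohorts with ground truth: the statistical structure
# the analysis assumes, under configurable mutation frequencies, trajectory
# probabilities, relapse rate, clonal ordering and stratum-dependent hazards.

#' Default per-gene generative model
#'
#' One row per gene: probability of mutation at diagnosis (`p_diag`),
#' conditional probability that a diagnosis mutation is lost by CMR
#' (`p_lost`; persistence is the complement), and the per-patient
#' probability of acquiring a new mutation of the gene at CMR
#' (`p_acquire`). Defaults emulate the published diagnosis frequencies and
#' diagnosis-to-CMR trajectory fractions of NPM1-mutated AML: DTA and
#' splicing/IDH genes persist or are acquired at remission, signalling genes
#' are lost with the blast clone, and a small set (TP53, CSNK1A1, SETBP1)
#' appears only at remission.
#'
#' @return data.frame: `gene`, `p_diag`, `p_lost`, `p_acquire`.
#' @export
defaultGeneModel <- function() {
  tab <- rbind(
    c("DNMT3A",   .20, .34, .033),
    c("IDH2",     .14, .92, .007),
    c("TET2",     .11, .63, .035),
    c("IDH1",     .10, .95, .007),
    c("NRAS",     .09, 1.0, .000),
    c("FLT3-TKD", .07, 1.0, .000),
    c("PTPN11",   .07, .95, .007),
    c("SRSF2",    .04, .54, .034),
    c("CEBPA",    .04, .92, .007),
    c("WT1",      .03, 1.0, .007),
    c("GATA2",    .02, 1.0, .000),
    c("KRAS",     .02, 1.0, .000),
    c("STAG2",    .02, 1.0, .000),
    c("EZH2",     .02, .80, .000),
    c("RUNX1",    .02, 1.0, .013),
    c("BCOR",     .01, 1.0, .000),
    c("TP53",     .00, 1.0, .013),
    c("CSNK1A1",  .00, 1.0, .007),
    c("SETBP1",   .00, 1.0, .007))
  data.frame(gene = tab[, 1L],
             p_diag = as.numeric(tab[, 2L]),
             p_lost = as.numeric(tab[, 3L]),
             p_acquire = as.numeric(tab[, 4L]),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' The defaults are the study conditions the pipeline is meant for: a
#' 150-patient NPM1-mutated CMR cohort, published per-gene diagnosis
#' frequencies and trajectory probabilities, a 34\% relapse rate with
#' relapse samples for 73\% of relapses, NPM1 usually a second hit below the
#' founder co-mutation VAF, and exponential survival with a hazard
#' multiplier for the oncogenic (CHOP) CMR stratum and none for the
#' CHIP-only stratum.
#'
#' @param n_patients cohort size.
#' @param gene_model per-gene model, see [defaultGeneModel()].
#' @param p_relapse probability of clinical relapse.
#' @param p_relapse_sample probability a relapse is sequenced.
#' @param second_hit_fraction baseline fraction of co-mutated patients in
#'   whom NPM1 is the later (second) hit.
#' @param second_hit_age_beta log-odds increase of second-hit status per
#'   decade of age above 57 (older patients carry older founder clones).
#' @param second_hit_acquire_mult multiplier on acquisition probabilities
#'   for second-hit patients (an underlying premalignant clone keeps
#'   producing mutations at remission).
#' @param acquire_scale global multiplier on all acquisition probabilities
#'   (used by enrichment presets; default 1).
#' @param founder_vaf_shape1,founder_vaf_shape2 Beta parameters of founder
#'   co-mutation VAFs at diagnosis (mode about 0.4).
#' @param hazard_base baseline death hazard, events per year, acting after
#'   CMR is reached.
#' @param hr_chop,hr_chip hazard multipliers for the CHOP and CHIP-only CMR
#'   strata (CHIP persistence is non-prognostic: default 1).
#' @param censor_min_years,censor_max_years administrative censoring window
#'   (uniform), measured from diagnosis.
#' @param r_persist probability a CMR-detectable mutation is still present
#'   at relapse; `r_reappear` the probability a lost mutation re-emerges;
#'   `r_denovo_scale` scales per-gene acquisition for de novo relapse hits.
#' @param germline_rate per-patient probability of one injected germline
#'   variant (0 disables); `germline_tolerance` the half-width of the VAF
#'   bands it is drawn in.
#' @param flt3_itd_prob probability of FLT3-ITD at diagnosis (gene scan,
#'   presence-only).
#' @return object of class `SimConfig`.
#' @export
simConfig <- function(n_patients = 150,
                      gene_model = defaultGeneModel(),
                      p_relapse = 0.34,
                      p_relapse_sample = 0.73,
                      second_hit_fraction = 0.80,
                      second_hit_age_beta = 0.5,
                      second_hit_acquire_mult = 1.5,
                      acquire_scale = 1,
                      founder_vaf_shape1 = 9,
                      founder_vaf_shape2 = 13,
                      hazard_base = 0.20,
                      hr_chop = 3.0,
                      hr_chip = 1.0,
                      censor_min_years = 1,
                      censor_max_years = 8,
                      r_persist = 0.8,
                      r_reappear = 0.05,
                      r_denovo_scale = 1,
                      germline_rate = 0,
                      germline_tolerance = 0.05,
                      flt3_itd_prob = 0.34) {
  cfg <- list(n_patients = as.integer(n_patients), gene_model = gene_model,
              p_relapse = p_relapse, p_relapse_sample = p_relapse_sample,
              second_hit_fraction = second_hit_fraction,
              second_hit_age_beta = second_hit_age_beta,
              second_hit_acquire_mult = second_hit_acquire_mult,
              acquire_scale = acquire_scale,
              founder_vaf_shape1 = founder_vaf_shape1,
              founder_vaf_shape2 = founder_vaf_shape2,
              hazard_base = hazard_base, hr_chop = hr_chop,
              hr_chip = hr_chip,
              censor_min_years = censor_min_years,
              censor_max_years = censor_max_years,
              r_persist = r_persist, r_reappear = r_reappear,
              r_denovo_scale = r_denovo_scale,
              germline_rate = germline_rate,
              germline_tolerance = germline_tolerance,
              flt3_itd_prob = flt3_itd_prob)
  probs <- c(cfg$p_relapse, cfg$p_relapse_sample, cfg$second_hit_fraction,
             cfg$r_persist, cfg$r_reappear, cfg$germline_rate,
             cfg$flt3_itd_prob, gene_model$p_diag, gene_model$p_lost,
             gene_model$p_acquire)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$n_patients < 1L) stop("n_patients must be positive")
  if (cfg$hazard_base <= 0 || cfg$hr_chop <= 0 || cfg$hr_chip <= 0)
    stop("hazards must be positive")
  if (cfg$censor_min_years <= 0 ||
      cfg$censor_max_years <= cfg$censor_min_years)
    stop("censoring window invalid")
  structure(cfg, class = "SimConfig")
}

#' Simulate a synthetic NPM1-mutated AML cohort with ground truth
#'
#' Per patient: diagnosis mutations are drawn per gene, founder VAFs from a
#' Beta distribution, and NPM1 is placed below (second hit) or above the
#' maximum co-mutation VAF according to an age-linked logistic model. Each
#' diagnosis mutation is lost or persists at CMR; new mutations are
#' acquired per gene (second-hit patients acquire more). The CHIP5 CMR
#' stratum implied by the generated events scales an exponential death
#' hazard; relapse, relapse sampling and relapse-timepoint mutations follow
#' the configured rates. Optionally one germline variant per selected
#' patient is injected in the 50\%/100\% VAF bands at all sampled
#' timepoints.
#'
#' With the same seed the output is identical; ground-truth labels and
#' strata use the same definitions as the analysis pipeline, so running the
#' pipeline on a clean simulation recovers them exactly.
#'
#' @param config a [simConfig()].
#' @param seed integer seed (required: the contract is reproducibility).
#' @return list: `cohort` (an [AmlCohort-class]), `truth_events`
#'   (per-event true labels), `truth_patients` (per-patient second-hit flag,
#'   strata, hazard multiplier), `truth_germline` (injected spikes, possibly
#'   empty).
#' @export
simulateCohort <- function(config = simConfig(), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  n <- config$n_patients
  gm <- config$gene_model
  ids <- sprintf("S%04d", seq_len(n))

  age <- pmin(82, pmax(19, round(stats::rnorm(n, 57, 13))))
  sex <- ifelse(stats::runif(n) < 0.49, "M", "F")
  kary <- stats::runif(n) < 0.09
  itd <- stats::runif(n) < config$flt3_itd_prob
  ratio <- ifelse(itd, round(stats::runif(n, 0.1, 1.2), 2), NA_real_)

  # diagnosis mutations, per gene
  ev <- list()
  for (g in seq_len(nrow(gm))) {
    hit <- which(stats::runif(n) < gm$p_diag[g])
    if (length(hit) == 0L) next
    vafD <- pmax(0.02, stats::rbeta(length(hit), config$founder_vaf_shape1,
                                    config$founder_vaf_shape2))
    ev[[length(ev) + 1L]] <- data.frame(
      pi = hit, gene = gm$gene[g],
      variant_id = sprintf("%s.d%04d", gm$gene[g], hit),
      at_d = TRUE, at_cmr = FALSE, at_r = FALSE,
      vaf_d = vafD, vaf_cmr = NA_real_, vaf_r = NA_real_,
      p_lost = gm$p_lost[g], stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(pi = integer(), gene = character(), variant_id = character(),
               at_d = logical(), at_cmr = logical(), at_r = logical(),
               vaf_d = numeric(), vaf_cmr = numeric(), vaf_r = numeric(),
               p_lost = numeric(), stringsAsFactors = FALSE)

  # NPM1 placement and second-hit status (age-linked logistic)
  maxco <- rep(NA_real_, n)
  if (nrow(events)) {
    agg <- tapply(events$vaf_d, events$pi, max)
    maxco[as.integer(names(agg))] <- agg
  }
  lin <- stats::qlogis(config$second_hit_fraction) +
    config$second_hit_age_beta * (age - 57) / 10
  secondHit <- !is.na(maxco) & stats::runif(n) < stats::plogis(lin)
  npm1 <- numeric(n)
  below <- pmax(0.02, maxco - stats::runif(n, 0.05, 0.25))
  above <- pmin(0.60, maxco + stats::runif(n, 0.05, 0.20))
  npm1[secondHit] <- below[secondHit]
  npm1[!secondHit & !is.na(maxco)] <- above[!secondHit & !is.na(maxco)]
  npm1[is.na(maxco)] <- pmax(0.02, stats::rbeta(sum(is.na(maxco)),
                                                config$founder_vaf_shape1,
                                                config$founder_vaf_shape2))

  # diagnosis -> CMR evolution
  if (nrow(events)) {
    persists <- stats::runif(nrow(events)) >= events$p_lost
    events$at_cmr <- persists
    events$vaf_cmr[persists] <- stats::runif(sum(persists), 0.012, 0.15)
  }
  acqMult <- ifelse(secondHit, config$second_hit_acquire_mult, 1) *
    config$acquire_scale
  for (g in seq_len(nrow(gm))) {
    pAcq <- pmin(0.95, gm$p_acquire[g] * acqMult)
    hit <- which(stats::runif(n) < pAcq)
    if (length(hit) == 0L) next
    events <- rbind(events, data.frame(
      pi = hit, gene = gm$gene[g],
      variant_id = sprintf("%s.a%04d", gm$gene[g], hit),
      at_d = FALSE, at_cmr = TRUE, at_r = FALSE,
      vaf_d = NA_real_, vaf_cmr = stats::runif(length(hit), 0.011, 0.08),
      vaf_r = NA_real_, p_lost = NA_real_, stringsAsFactors = FALSE))
  }

  # CHIP5 stratum implied by the generated events drives the hazard
  stratum <- rep("NONE", n)
  if (nrow(events)) {
    pa <- events[events$at_cmr, , drop = FALSE]
    for (i in unique(pa$pi)) {
      genes <- pa$gene[pa$pi == i]
      stratum[i] <- if (any(!(genes %in% CHIP5_GENES))) "CHOP" else "CHIP_ONLY"
    }
  }
  mult <- c(NONE = 1, CHIP_ONLY = config$hr_chip,
            CHOP = config$hr_chop)[stratum]

  # survival: death hazard acts once CMR is reached (a CMR-defined cohort)
  t_cmr <- round(stats::runif(n, 75, 180))
  censorDay <- round(stats::runif(n, config$censor_min_years * 365,
                                  config$censor_max_years * 365))
  deathDay <- t_cmr + stats::rexp(n, rate = config$hazard_base * mult / 365)
  death <- deathDay < censorDay
  t_last <- round(pmin(deathDay, censorDay))

  relapse <- stats::runif(n) < config$p_relapse
  t_rel <- rep(NA_real_, n)
  u <- stats::runif(n, 0.15, 0.85)
  t_rel[relapse] <- round(t_cmr[relapse] +
                            u[relapse] * (t_last[relapse] - t_cmr[relapse]))
  sampled <- relapse & stats::runif(n) < config$p_relapse_sample

  # relapse-timepoint mutations
  if (nrow(events)) {
    detectable <- events$at_cmr
    stay <- stats::runif(nrow(events)) < config$r_persist
    back <- stats::runif(nrow(events)) < config$r_reappear
    events$at_r <- sampled[events$pi] &
      ((detectable & stay) | (!detectable & back))
  }
  for (g in seq_len(nrow(gm))) {
    pDn <- pmin(0.95, gm$p_acquire[g] * config$r_denovo_scale)
    hit <- which(sampled & stats::runif(n) < pDn)
    if (length(hit) == 0L) next
    events <- rbind(events, data.frame(
      pi = hit, gene = gm$gene[g],
      variant_id = sprintf("%s.r%04d", gm$gene[g], hit),
      at_d = FALSE, at_cmr = FALSE, at_r = TRUE,
      vaf_d = NA_real_, vaf_cmr = NA_real_, vaf_r = NA_real_,
      p_lost = NA_real_, stringsAsFactors = FALSE))
  }
  if (nrow(events) && any(events$at_r))
    events$vaf_r[events$at_r] <- stats::runif(sum(events$at_r), 0.15, 0.45)

  # truth labels (same definitions the pipeline applies)
  truth_events <- NULL
  if (nrow(events)) {
    truth_events <- data.frame(
      patient_id = ids[events$pi], gene = events$gene,
      variant_id = events$variant_id,
      cmr_label = ifelse(events$at_d & !events$at_cmr, "LOST",
                         ifelse(events$at_d & events$at_cmr, "PERSISTENT",
                                ifelse(events$at_cmr, "ACQUIRED",
                                       NA_character_))),
      relapse_pattern = NA_character_, stringsAsFactors = FALSE)
    has <- sampled[events$pi]
    truth_events$relapse_pattern[has] <-
      patternFromPresence(events$at_d[has], events$at_cmr[has],
                          events$at_r[has])
  } else {
    truth_events <- data.frame(patient_id = character(), gene = character(),
                               variant_id = character(),
                               cmr_label = character(),
                               relapse_pattern = character(),
                               stringsAsFactors = FALSE)
  }
  relStratum <- rep(NA_character_, n)
  relStratum[sampled] <- "NO_CHOP"
  if (nrow(events)) {
    chopR <- events[events$at_r & !(events$gene %in% CHIP5_GENES), ,
                    drop = FALSE]
    relStratum[intersect(which(sampled), unique(chopR$pi))] <- "CHOP"
  }

  # assemble variant rows
  rowsFor <- function(sel, tp, vafcol) {
    e <- events[sel, , drop = FALSE]
    data.frame(patient_id = ids[e$pi], timepoint = tp, gene = e$gene,
               variant_id = e$variant_id, vaf = e[[vafcol]], assay = "PANEL",
               is_germline = FALSE, is_coding = TRUE, stringsAsFactors = FALSE)
  }
  vtab <- rbind(
    if (nrow(events)) rowsFor(events$at_d, "DIAGNOSIS", "vaf_d"),
    if (nrow(events)) rowsFor(events$at_cmr, "CMR", "vaf_cmr"),
    if (nrow(events)) rowsFor(events$at_r, "RELAPSE", "vaf_r"),
    data.frame(patient_id = ids, timepoint = "DIAGNOSIS", gene = "NPM1",
               variant_id = "W288fs", vaf = npm1, assay = "PANEL",
               is_germline = FALSE, is_coding = TRUE, stringsAsFactors = FALSE),
    data.frame(patient_id = ids[sampled], timepoint = "RELAPSE",
               gene = "NPM1", variant_id = "W288fs",
               vaf = stats::runif(sum(sampled), 0.2, 0.45), assay = "PANEL",
               is_germline = FALSE, is_coding = TRUE, stringsAsFactors = FALSE),
    data.frame(patient_id = ids[itd], timepoint = "DIAGNOSIS", gene = "FLT3",
               variant_id = "ITD", vaf = NA_real_, assay = "GENE_SCAN",
               is_germline = FALSE, is_coding = TRUE, stringsAsFactors = FALSE))

  hsct <- rep("NONE", n)
  hsct[stats::runif(n) < 0.23] <- "UPFRONT"
  hsct[relapse & hsct == "NONE" & stats::runif(n) < 0.55] <- "AFTER_RELAPSE"

  ptab <- data.frame(patient_id = ids, age = age, sex = sex,
                     karyotype_aberrant = kary, flt3_itd = itd,
                     flt3_ratio = ratio,
                     eln_risk = deriveElnRisk(itd, ratio), hsct = hsct,
                     t_diagnosis = 0, t_cmr = t_cmr, t_relapse = t_rel,
                     t_death_or_censor = t_last, death = death,
                     stringsAsFactors = FALSE)

  truth_germline <- data.frame(patient_id = character(), gene = character(),
                               variant_id = character(),
                               stringsAsFactors = FALSE)
  cohort <- AmlCohort(ptab, vtab, panelGenes = unique(c(gm$gene, "NPM1")),
                      provenance = sprintf("simulateCohort(seed = %d)",
                                           as.integer(seed)))
  if (config$germline_rate > 0) {
    inj <- injectGermline(cohort, rate = config$germline_rate,
                          tolerance = config$germline_tolerance,
                          seed = NULL)  # continue the active RNG stream
    cohort <- inj$cohort
    truth_germline <- inj$truth
  }

  truth_patients <- data.frame(patient_id = ids, second_hit = secondHit,
                               cmr_stratum_chip5 = stratum,
                               relapse_stratum_chip5 = relStratum,
                               hazard_mult = unname(mult),
                               stringsAsFactors = FALSE)
  list(cohort = cohort, truth_events = truth_events,
       truth_patients = truth_patients, truth_germline = truth_germline)
}

#' Inject labeled germline spikes into a cohort
#'
#' Adds, for each selected patient, one variant present at all of the
#' patient's sampled timepoints with VAFs drawn strictly inside the
#' heterozygous (around 0.5) or homozygous (around 1.0) germline band, so
#' the germline filter's recall on the spikes is 100\% by construction.
#'
#' @param cohort an [AmlCohort-class].
#' @param rate per-patient spike probability in \[0, 1\].
#' @param tolerance band half-width; draws stay within 0.8 x tolerance.
#' @param seed integer seed, or NULL to continue the caller's RNG stream.
#' @return list: `cohort` (with spikes appended) and `truth` (data.frame of
#'   spiked `patient_id`, `gene`, `variant_id`).
#' @export
injectGermline <- function(cohort, rate, tolerance = 0.05, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- patients(cohort)
  avail <- availableTimepoints(cohort)
  glGenes <- c("FAT1", "TTN", "NF1", "APC", "ATM")
  pick <- which(stats::runif(nrow(p)) < rate)
  truth <- data.frame(patient_id = character(), gene = character(),
                      variant_id = character(), stringsAsFactors = FALSE)
  if (length(pick)) {
    rows <- list()
    for (j in seq_along(pick)) {
      i <- pick[j]
      pid <- p$patient_id[i]
      gene <- glGenes[(j - 1L) %% length(glGenes) + 1L]
      vid <- sprintf("rs%06d", j)
      center <- if (stats::runif(1) < 0.9) 0.5 else 1.0
      tps <- avail[[pid]]
      vaf <- center + stats::runif(length(tps), -0.8, 0.8) * tolerance
      vaf <- pmin(vaf, 1)
      rows[[j]] <- data.frame(patient_id = pid, timepoint = tps, gene = gene,
                              variant_id = vid, vaf = vaf, assay = "PANEL",
                              is_germline = FALSE, is_coding = TRUE,
                              stringsAsFactors = FALSE)
      truth <- rbind(truth, data.frame(patient_id = pid, gene = gene,
                                       variant_id = vid,
                                       stringsAsFactors = FALSE))
    }
    variants(cohort) <- rbind(variants(cohort), do.call(rbind, rows))
  }
  list(cohort = cohort, truth = truth)
}
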