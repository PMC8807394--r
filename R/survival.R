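# Endpoint construction and survival statistics. Kaplan-Meier, log-rank and
# Cox fitting are delegated to the survival package (Efron ties by default);
# this module owns endpoint semantics, grouping, and result shaping.

#' Build survival endpoints from the patient manifest
#'
#' EFS: time to relapse or death, whichever first, measured from diagnosis
#' by default (`efsOrigin = "cmr"` measures from the CMR date instead). OS:
#' time to death from diagnosis. OS after relapse: from the relapse date to
#' death or censoring, defined only for relapsed patients. Censoring is at
#' the last follow-up for all endpoints.
#'
#' @param patientTable patient manifest data.frame (day offsets).
#' @param efsOrigin `"diagnosis"` (default) or `"cmr"`.
#' @return data.frame: `patient_id`, `efs_time`, `efs_event`, `os_time`,
#'   `os_event`, `os_after_relapse_time`, `os_after_relapse_event` (NA for
#'   non-relapsed patients). Times in days.
#' @export
buildEndpoints <- function(patientTable, efsOrigin = c("diagnosis", "cmr")) {
  efsOrigin <- match.arg(efsOrigin)
  p <- patientTable
  bad <- !is.na(p$t_relapse) & p$death &
    !is.na(p$t_death_or_censor) & p$t_death_or_censor < p$t_relapse
  if (any(bad)) {
    stop("death before relapse for patient(s): ",
         paste(p$patient_id[bad], collapse = ", "))
  }
  origin <- if (efsOrigin == "diagnosis") p$t_diagnosis else p$t_cmr
  relapsed <- !is.na(p$t_relapse)
  efs_stop <- ifelse(relapsed, p$t_relapse, p$t_death_or_censor)
  efs_event <- relapsed | p$death
  out <- data.frame(
    patient_id = p$patient_id,
    efs_time = efs_stop - origin,
    efs_event = efs_event,
    os_time = p$t_death_or_censor - p$t_diagnosis,
    os_event = p$death,
    os_after_relapse_time = ifelse(relapsed,
                                   p$t_death_or_censor - p$t_relapse,
                                   NA_real_),
    os_after_relapse_event = ifelse(relapsed, p$death, NA),
    stringsAsFactors = FALSE)
  if (any(out$efs_time < 0 | out$os_time < 0, na.rm = TRUE))
    stop("negative endpoint time; check the manifest date skeleton")
  out
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with risk table. With an all-censored input the
#' curve is identically 1 and a notice is issued.
#'
#' @param times nonnegative times.
#' @param events logical/0-1 event indicators.
#' @return data.frame: `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (right-continuous step values), with `S(0) = 1` implied.
#' @export
kmEstimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L,
            all(times >= 0))
  if (sum(events) == 0L) message("all observations censored; S(t) = 1")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Evaluate a KM step function
#'
#' @param km output of [kmEstimate()].
#' @param t times at which to evaluate `S(t)`.
#' @return numeric vector.
#' @export
kmSurvAt <- function(km, t) {
  vapply(t, function(x) {
    idx <- which(km$time <= x)
    if (length(idx) == 0L) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Log-rank test, with pairwise comparisons for more than two groups
#'
#' Standard log-rank chi-square with k-1 degrees of freedom; with more than
#' two groups, all pairwise two-group tests are reported unadjusted (the
#' convention used when pairwise p values accompany a global curve).
#'
#' @param times,events as in [kmEstimate()].
#' @param groups group labels (at least two non-empty groups).
#' @return list: `statistic`, `df`, `p_value`, and `pairwise` (data.frame
#'   `group1`, `group2`, `statistic`, `p_value`; NULL for two groups).
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.factor(groups)
  tab <- table(groups)
  if (length(tab) < 2L || any(tab == 0L))
    stop("log-rank needs at least two non-empty groups")
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ groups)
  df <- length(tab) - 1L
  res <- list(statistic = unname(sd$chisq), df = df,
              p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
              pairwise = NULL)
  if (length(tab) > 2L) {
    combs <- utils::combn(levels(groups), 2L)
    pw <- apply(combs, 2L, function(pair) {
      sel <- groups %in% pair
      s2 <- survival::survdiff(
        survival::Surv(times[sel], as.integer(events[sel])) ~
          droplevels(groups[sel]))
      c(statistic = unname(s2$chisq),
        p_value = stats::pchisq(s2$chisq, 1L, lower.tail = FALSE))
    })
    res$pairwise <- data.frame(group1 = combs[1L, ], group2 = combs[2L, ],
                               statistic = pw["statistic", ],
                               p_value = pw["p_value", ],
                               stringsAsFactors = FALSE)
  }
  res
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization via `survival::coxph` with Efron tie
#' handling by default (day-granularity data produce ties; Breslow is
#' available by flag). Rows with missing covariate values are dropped
#' listwise and the count reported. Monotone likelihood (perfect separation)
#' is flagged and the affected CI reported as unbounded.
#'
#' @param data data.frame holding times, events and covariates.
#' @param timeCol,eventCol column names of the endpoint.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return data.frame of per-covariate results: `term`, `coef`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `n_events`, `separation`;
#'   attributes `score` (model log-rank score statistic), `loglik`,
#'   `n_dropped`.
#' @export
coxFit <- function(data, timeCol, eventCol, covariates,
                   ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  cols <- c(timeCol, eventCol, covariates)
  stopifnot_cols(data, cols, "endpoint data")
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  nDropped <- nrow(data) - nrow(d)
  if (sum(d[[eventCol]]) < length(covariates))
    stop("fewer events than covariates")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", timeCol, ", as.integer(", eventCol, ")) ~ ",
    paste(covariates, collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  coefs <- s$coefficients
  ci <- s$conf.int
  sep <- abs(coefs[, "coef"]) > 10 |
    (warned & coefs[, "se(coef)"] > 100)
  out <- data.frame(term = rownames(coefs),
                    coef = coefs[, "coef"],
                    hr = coefs[, "exp(coef)"],
                    ci_low = ci[, "lower .95"],
                    ci_high = ci[, "upper .95"],
                    p_value = coefs[, "Pr(>|z|)"],
                    n = fit$n, n_events = fit$nevent,
                    separation = sep,
                    stringsAsFactors = FALSE)
  if (any(sep)) {
    out$ci_low[sep] <- 0
    out$ci_high[sep] <- Inf
    warning("monotone likelihood suspected for: ",
            paste(out$term[sep], collapse = ", "),
            "; CI reported as unbounded")
  }
  rownames(out) <- NULL
  attr(out, "score") <- unname(fit$score)
  attr(out, "loglik") <- fit$loglik
  attr(out, "n_dropped") <- nDropped
  out
}

#' Run the published model suite on a stratified cohort
#'
#' Emits, as one result table: (i) global and pairwise log-rank tests of EFS
#' and OS across the three CMR strata; (ii) univariate Cox fits of the
#' oncogenic-stratum indicator for EFS and OS; (iii) a multivariate Cox
#' model of OS with the oncogenic-at-CMR indicator, allogeneic HSCT (any),
#' aberrant karyotype, sex and age per decade; and (iv) OS after relapse by
#' relapse stratum (log-rank plus univariate Cox) when relapse strata are
#' supplied.
#'
#' @param cohort an [AmlCohort-class].
#' @param strata CMR strata from [stratifyPatientsCmr()].
#' @param relapseStrata optional relapse strata from
#'   [stratifyPatientsRelapse()].
#' @param efsOrigin passed to [buildEndpoints()].
#' @return data.frame of rows `endpoint`, `grouping`, `method`, `term`,
#'   `hr`, `ci_low`, `ci_high`, `statistic`, `p_value`, `n`; attribute
#'   `"multivariate_score"` holds the multivariate model's log-rank score
#'   statistic (the model-comparison number).
#' @export
runPaperModels <- function(cohort, strata, relapseStrata = NULL,
                           efsOrigin = "diagnosis") {
  p <- patients(cohort)
  ep <- buildEndpoints(p, efsOrigin = efsOrigin)
  d <- merge(ep, strata, by = "patient_id")
  d <- merge(d, p[, c("patient_id", "age", "sex", "karyotype_aberrant",
                      "hsct")], by = "patient_id")
  negLabel <- setdiff(unique(d$cmr_stratum), c("NONE"))
  negLabel <- if ("CHOP" %in% negLabel) "CHOP" else "NON_DTA"
  d$onc_at_cmr <- as.integer(d$cmr_stratum == negLabel)
  d$hsct_any <- as.integer(d$hsct != "NONE")
  d$male <- as.integer(d$sex == "M")
  d$age_dec <- d$age / 10
  d$kary_ab <- as.integer(d$karyotype_aberrant)

  rows <- list()
  addRow <- function(endpoint, grouping, method, term = NA, hr = NA,
                     lo = NA, hi = NA, stat = NA, pval = NA, n = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      endpoint = endpoint, grouping = grouping, method = method,
      term = term, hr = hr, ci_low = lo, ci_high = hi, statistic = stat,
      p_value = pval, n = n, stringsAsFactors = FALSE)
  }

  for (endpoint in c("EFS", "OS")) {
    tcol <- if (endpoint == "EFS") "efs_time" else "os_time"
    ecol <- if (endpoint == "EFS") "efs_event" else "os_event"
    lr <- logrankTest(d[[tcol]], d[[ecol]], d$cmr_stratum)
    addRow(endpoint, "cmr_stratum (global)", "LOGRANK",
           stat = lr$statistic, pval = lr$p_value, n = nrow(d))
    if (!is.null(lr$pairwise)) {
      for (i in seq_len(nrow(lr$pairwise))) {
        addRow(endpoint,
               paste0(lr$pairwise$group1[i], " vs ", lr$pairwise$group2[i]),
               "LOGRANK", stat = lr$pairwise$statistic[i],
               pval = lr$pairwise$p_value[i])
      }
    }
    cf <- coxFit(d, tcol, ecol, "onc_at_cmr")
    addRow(endpoint, paste0(negLabel, " at CMR vs rest"), "COX_UNIV",
           term = "onc_at_cmr", hr = cf$hr, lo = cf$ci_low, hi = cf$ci_high,
           stat = cf$coef, pval = cf$p_value, n = cf$n)
  }

  mv <- coxFit(d, "os_time", "os_event",
               c("onc_at_cmr", "hsct_any", "kary_ab", "male", "age_dec"))
  for (i in seq_len(nrow(mv))) {
    addRow("OS", "multivariate", "COX_MULTIV", term = mv$term[i],
           hr = mv$hr[i], lo = mv$ci_low[i], hi = mv$ci_high[i],
           stat = mv$coef[i], pval = mv$p_value[i], n = mv$n[i])
  }

  if (!is.null(relapseStrata)) {
    dr <- merge(ep, relapseStrata, by = "patient_id")
    dr <- dr[!is.na(dr$os_after_relapse_time), , drop = FALSE]
    if (length(unique(dr$relapse_stratum)) == 2L) {
      lr <- logrankTest(dr$os_after_relapse_time, dr$os_after_relapse_event,
                        dr$relapse_stratum)
      addRow("OS_AFTER_RELAPSE", "relapse_stratum", "LOGRANK",
             stat = lr$statistic, pval = lr$p_value, n = nrow(dr))
      dr$chop <- as.integer(dr$relapse_stratum == "CHOP")
      cf <- coxFit(dr, "os_after_relapse_time", "os_after_relapse_event",
                   "chop")
      addRow("OS_AFTER_RELAPSE", "CHOP at relapse vs NO_CHOP", "COX_UNIV",
             term = "chop", hr = cf$hr, lo = cf$ci_low, hi = cf$ci_high,
             stat = cf$coef, pval = cf$p_value, n = cf$n)
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "multivariate_score") <- attr(mv, "score")
  out
}
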