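# Clonal-hierarchy inference at diagnosis: VAF ordering and the NPM1
# second-hit call.

#' Call NPM1 second-hit status from diagnosis VAFs
#'
#' In an exponentially growing leukemia the ancestral clone carries every
#' later hit, so a mutation with a clearly higher VAF than NPM1 places NPM1
#' later in the clonal hierarchy ("second hit"). The comparator is the
#' maximum co-mutation VAF: a single ancestral clone suffices. A margin
#' (default 0.02) guards against sampling noise at panel depth; margin 0
#' reproduces the naive strict comparison.
#'
#' Germline-flagged and presence-only calls are excluded. Patients without
#' any eligible co-mutation are indeterminate (`NA`). A patient lacking an
#' NPM1 diagnosis call is an error: the cohort is NPM1-mutated by definition.
#'
#' @param variants variant data.frame (diagnosis rows are used).
#' @param margin VAF excess required to call NPM1 a second hit.
#' @return data.frame: `patient_id`, `npm1_vaf`, `max_comut_vaf`,
#'   `max_comut_gene`, `second_hit` (logical, NA = indeterminate),
#'   `margin_used`.
#' @export
callNpm1SecondHit <- function(variants, margin = 0.02) {
  d <- variants[variants$timepoint == "DIAGNOSIS" & !variants$is_germline, ,
                drop = FALSE]
  ids <- sort(unique(d$patient_id))
  rows <- lapply(ids, function(pid) {
    p <- d[d$patient_id == pid, , drop = FALSE]
    npm1 <- p$vaf[p$gene == "NPM1" & !is.na(p$vaf)]
    if (length(npm1) == 0L) {
      stop("patient ", pid, " has no NPM1 diagnosis call with a VAF; ",
           "the cohort is NPM1-mutated by definition")
    }
    npm1 <- max(npm1)
    co <- p[p$gene != "NPM1" & !is.na(p$vaf), , drop = FALSE]
    if (nrow(co) == 0L) {
      return(data.frame(patient_id = pid, npm1_vaf = npm1,
                        max_comut_vaf = NA_real_,
                        max_comut_gene = NA_character_,
                        second_hit = NA, margin_used = margin,
                        stringsAsFactors = FALSE))
    }
    i <- which.max(co$vaf)
    data.frame(patient_id = pid, npm1_vaf = npm1,
               max_comut_vaf = co$vaf[i], max_comut_gene = co$gene[i],
               second_hit = (co$vaf[i] - npm1) > margin,
               margin_used = margin, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank diagnosis mutations by descending VAF
#'
#' A simple clonal ordering of one patient's diagnostic sample: stable sort
#' by descending VAF; exact ties share a rank and are listed alphabetically.
#'
#' @param variants variant data.frame of one patient (diagnosis rows with a
#'   VAF are used; germline-flagged rows excluded).
#' @return data.frame: `gene`, `variant_id`, `vaf`, `rank` (min-rank for
#'   ties).
#' @export
rankClonalOrder <- function(variants) {
  d <- variants[variants$timepoint == "DIAGNOSIS" & !variants$is_germline &
                  !is.na(variants$vaf), , drop = FALSE]
  if (nrow(d) == 0L) stop("no diagnosis variants with a VAF")
  if (length(unique(d$patient_id)) > 1L)
    stop("rankClonalOrder works on one patient at a time")
  ord <- order(-d$vaf, d$gene, d$variant_id)
  d <- d[ord, , drop = FALSE]
  rnk <- rank(-d$vaf, ties.method = "min")
  out <- data.frame(gene = d$gene, variant_id = d$variant_id, vaf = d$vaf,
                    rank = as.integer(rnk), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohort-level associations of the NPM1 second-hit call
#'
#' Compares second-hit versus non-second-hit patients on age and on the
#' number of persistent + acquired mutations at CMR, with rank-based
#' two-sample (Wilcoxon) tests. Indeterminate patients are excluded. A group
#' with fewer than two patients skips the comparison with a notice.
#'
#' @param calls output of [callNpm1SecondHit()].
#' @param patientTable patient manifest data.frame (for `age`).
#' @param events classified events (for the CMR mutation-burden comparison).
#' @return list with elements `age` and `cmr_burden`, each either a list
#'   (`statistic`, `p_value`, group medians, n) or a skip notice string; and
#'   `n_second_hit` / `n_not_second_hit`.
#' @export
associateSecondHit <- function(calls, patientTable, events) {
  det <- calls[!is.na(calls$second_hit), , drop = FALSE]
  grp <- split(det$patient_id, det$second_hit)
  nTrue <- length(grp[["TRUE"]] %||% character())
  nFalse <- length(grp[["FALSE"]] %||% character())
  cmp <- function(values, ids) {
    x <- values[match(grp[["TRUE"]], ids)]
    y <- values[match(grp[["FALSE"]], ids)]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
      return("comparison skipped: a group has fewer than 2 patients")
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         median_second_hit = stats::median(x),
         median_not_second_hit = stats::median(y),
         n = c(second_hit = length(x), not_second_hit = length(y)))
  }
  burden <- vapply(patientTable$patient_id, function(pid) {
    sum(events$patient_id == pid &
          events$cmr_label %in% c("PERSISTENT", "ACQUIRED"), na.rm = TRUE)
  }, numeric(1))
  list(age = cmp(patientTable$age, patientTable$patient_id),
       cmr_burden = cmp(burden, patientTable$patient_id),
       n_second_hit = nTrue, n_not_second_hit = nFalse)
}
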