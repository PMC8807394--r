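# Small builders used across the suite.

vrow <- function(patient, tp, gene, vid = "", vaf = NA_real_,
                 assay = "PANEL") {
  data.frame(patient_id = patient, timepoint = tp, gene = gene,
             variant_id = vid, vaf = vaf, assay = assay,
             is_germline = FALSE, is_coding = TRUE, stringsAsFactors = FALSE)
}

vrows <- function(...) do.call(rbind, list(...))

mkPatients <- function(ids, t_relapse = NA_real_, death = FALSE,
                       t_last = 1000) {
  n <- length(ids)
  data.frame(patient_id = ids, age = 57, sex = "F",
             karyotype_aberrant = FALSE, flt3_itd = FALSE,
             flt3_ratio = NA_real_, eln_risk = "FAVORABLE", hsct = "NONE",
             t_diagnosis = 0, t_cmr = 100,
             t_relapse = rep_len(t_relapse, n),
             t_death_or_censor = rep_len(t_last, n),
             death = rep_len(death, n), stringsAsFactors = FALSE)
}

mkCohort <- function(variants, ids = unique(variants$patient_id), ...) {
  AmlCohort(mkPatients(ids, ...), variants,
            panelGenes = unique(c(variants$gene, "NPM1")))
}

# availability map for bare variant tables (diagnosis + CMR for everyone)
avail2 <- function(ids) {
  out <- lapply(ids, function(i) c("DIAGNOSIS", "CMR"))
  names(out) <- ids
  out
}
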