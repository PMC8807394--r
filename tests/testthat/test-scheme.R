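test_that("gene categorization follows the scheme definitions", {
  expect_equal(categorizeGene("DNMT3A", geneScheme("CHIP5")), "CHIP")
  expect_equal(categorizeGene("PTPN11", geneScheme("CHIP5")), "CHOP")
  expect_equal(categorizeGene("ASXL1", geneScheme("CHIP5")), "CHOP")
  expect_equal(categorizeGene("ASXL1", geneScheme("CHIP6")), "CHIP")
  expect_equal(categorizeGene("TET2", geneScheme("DTA")), "DTA")
  expect_equal(categorizeGene("IDH1", geneScheme("DTA")), "NON_DTA")
  expect_error(categorizeGene("NPM1", geneScheme("CHIP5")), "index mutation")
  expect_error(geneScheme("CUSTOM"), "chipGenes")
})

test_that("every gene falls in exactly one category under each scheme", {
  universe <- c(defaultGeneModel()$gene, "ASXL1", "ZRSR2")
  for (nm in c("CHIP5", "CHIP6", "DTA")) {
    sch <- geneScheme(nm)
    cat <- categorizeGene(universe, sch)
    expect_true(all(cat %in% c("CHIP", "CHOP", "DTA", "NON_DTA")))
    pos <- if (nm == "DTA") "DTA" else "CHIP"
    expect_setequal(universe[cat == pos],
                    intersect(universe, sch$chip_genes))
  }
  # DTA and CHIP5 agree on DNMT3A and TET2
  expect_equal(categorizeGene(c("DNMT3A", "TET2"), geneScheme("DTA")) ==
                 "DTA",
               categorizeGene(c("DNMT3A", "TET2"), geneScheme("CHIP5")) ==
                 "CHIP")
})

mkEv <- function(patient, gene, label,
                 pattern = NA_character_, hasRel = !is.na(pattern)) {
  data.frame(patient_id = patient, gene = gene,
             variant_id = paste0(gene, ".", label, ".", patient),
             at_d = isTRUE(label %in% c("LOST", "PERSISTENT")),
             at_cmr = isTRUE(label %in% c("PERSISTENT", "ACQUIRED")),
             at_r = isTRUE(pattern %in% c("D_CMR_R", "D_R", "CMR_R",
                                          "R_ONLY")),
             vaf_d = NA_real_, vaf_cmr = NA_real_, vaf_r = NA_real_,
             has_relapse_sample = hasRel,
             cmr_label = if (is.null(label)) NA_character_ else label,
             relapse_pattern = pattern, stringsAsFactors = FALSE)
}

test_that("CMR stratification uses persistent/acquired events with CHOP dominance", {
  sch <- geneScheme("CHIP5")
  ev <- rbind(mkEv("P1", "DNMT3A", "LOST"),               # lost only -> NONE
              mkEv("P2", "DNMT3A", "PERSISTENT"),
              mkEv("P2", "TET2", "ACQUIRED"),             # all CHIP
              mkEv("P3", "DNMT3A", "PERSISTENT"),
              mkEv("P3", "WT1", "ACQUIRED"))              # CHOP dominates
  st <- stratifyPatientsCmr(ev, sch, c("P1", "P2", "P3", "P4"))
  expect_equal(st$cmr_stratum, c("NONE", "CHIP_ONLY", "CHOP", "NONE"))
  expect_match(st$basis[st$patient_id == "P3"], "WT1:ACQUIRED")
  # the same patient under the DTA scheme: IDH1 is non-DTA
  ev2 <- mkEv("P5", "IDH1", "PERSISTENT")
  expect_equal(stratifyPatientsCmr(ev2, geneScheme("DTA"),
                                   "P5")$cmr_stratum, "NON_DTA")
  expect_equal(stratifyPatientsCmr(ev2, sch, "P5")$cmr_stratum, "CHIP_ONLY")
})

test_that("persistent-only and acquired-only views restrict the basis", {
  sch <- geneScheme("CHIP5")
  ev <- rbind(mkEv("P1", "WT1", "ACQUIRED"),
              mkEv("P1", "DNMT3A", "PERSISTENT"))
  expect_equal(stratifyPatientsCmr(ev, sch, "P1",
                                   basis = "persistent")$cmr_stratum,
               "CHIP_ONLY")
  expect_equal(stratifyPatientsCmr(ev, sch, "P1",
                                   basis = "acquired")$cmr_stratum, "CHOP")
})

test_that("adding a CHOP event never moves a patient out of CHOP", {
  sch <- geneScheme("CHIP5")
  base <- rbind(mkEv("P1", "DNMT3A", "PERSISTENT"),
                mkEv("P1", "NRAS", "ACQUIRED"))
  st1 <- stratifyPatientsCmr(base, sch, "P1")$cmr_stratum
  expect_equal(st1, "CHOP")
  more <- rbind(base, mkEv("P1", "TP53", "ACQUIRED"))
  expect_equal(stratifyPatientsCmr(more, sch, "P1")$cmr_stratum, "CHOP")
})

test_that("relapse stratification keys on CHOP genes present at relapse", {
  sch <- geneScheme("CHIP5")
  ev <- rbind(mkEv("P1", "WT1", NA_character_, "R_ONLY"),
              mkEv("P2", "TET2", "PERSISTENT", "D_CMR_R"),
              mkEv("P3", "NRAS", "LOST", "D_ONLY"))
  st <- stratifyPatientsRelapse(ev, sch)
  expect_equal(st$relapse_stratum[st$patient_id == "P1"], "CHOP")
  expect_equal(st$relapse_stratum[st$patient_id == "P2"], "NO_CHOP")
  expect_equal(st$relapse_stratum[st$patient_id == "P3"], "NO_CHOP")
  # acquired-only semantics ignore CHOP events already present at diagnosis
  ev2 <- mkEv("P4", "RUNX1", "PERSISTENT", "D_CMR_R")
  expect_equal(stratifyPatientsRelapse(ev2, sch)$relapse_stratum, "CHOP")
  expect_equal(stratifyPatientsRelapse(ev2, sch,
                                       acquiredOnly = TRUE)$relapse_stratum,
               "NO_CHOP")
  expect_error(stratifyPatientsRelapse(mkEv("P9", "WT1", "LOST"), sch),
               "relapse sample")
})

test_that("scheme derivation handles degenerate inputs", {
  # a single always-lost gene proposes CHOP via the fallback rule
  ev <- rbind(mkEv("P1", "NRAS", "LOST", "D_ONLY"),
              mkEv("P2", "NRAS", "LOST", "D_ONLY"))
  sch <- deriveSchemeFromPatterns(ev)
  expect_equal(sch$chop, "NRAS")
  expect_length(sch$chip, 0L)
  # nothing reaches minEvents: empty proposal with notice
  out <- deriveSchemeFromPatterns(mkEv("P1", "NRAS", "LOST", "D_ONLY"))
  expect_match(out$notice, "insufficient")
  expect_length(out$chip, 0L)
})
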