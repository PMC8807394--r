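test_that("filter configuration enforces its own consistency", {
  expect_error(filterConfig(germlineTolerance = 0.3), "0, 0.25")
  expect_error(filterConfig(vafCutoffCmr = 0.46), "germline band")
  cfg <- filterConfig()
  expect_equal(cfg$vaf_cutoff_cmr, 0.01)
  expect_equal(cfg$germline_tolerance, 0.05)
})

test_that("germline flagging requires all timepoints in a VAF band", {
  av <- avail2("P1")
  av$P1 <- c("DIAGNOSIS", "CMR", "RELAPSE")
  # heterozygous across three timepoints
  v <- vrows(vrow("P1", "DIAGNOSIS", "ATM", "rs1", 0.49),
             vrow("P1", "CMR", "ATM", "rs1", 0.51),
             vrow("P1", "RELAPSE", "ATM", "rs1", 0.50))
  expect_true(all(flagGermline(v, av)$is_germline))
  # far from both centers: somatic
  av2 <- avail2("P1")
  v <- vrows(vrow("P1", "DIAGNOSIS", "DNMT3A", "m1", 0.40),
             vrow("P1", "CMR", "DNMT3A", "m1", 0.02))
  expect_false(any(flagGermline(v, av2)$is_germline))
  # one timepoint outside the band disqualifies
  v <- vrows(vrow("P1", "DIAGNOSIS", "DNMT3A", "m1", 0.52),
             vrow("P1", "CMR", "DNMT3A", "m1", 0.04))
  expect_false(any(flagGermline(v, av2)$is_germline))
  # homozygous center
  v <- vrows(vrow("P1", "DIAGNOSIS", "ATM", "rs2", 0.98),
             vrow("P1", "CMR", "ATM", "rs2", 1.00))
  expect_true(all(flagGermline(v, av2)$is_germline))
  # absence at an available timepoint disqualifies even a 50% VAF
  v <- vrow("P1", "DIAGNOSIS", "ATM", "rs3", 0.50)
  expect_false(any(flagGermline(v, av2)$is_germline))
})

test_that("mixed centers qualify by default but not in strict mode", {
  av <- avail2("P1")
  v <- vrows(vrow("P1", "DIAGNOSIS", "ATM", "rs1", 0.49),
             vrow("P1", "CMR", "ATM", "rs1", 0.98))
  expect_true(all(flagGermline(v, av)$is_germline))
  strict <- filterConfig(strictGermlineCenter = TRUE)
  expect_false(any(flagGermline(v, av, strict)$is_germline))
})

test_that("presence-only calls are never flagged and warn once", {
  av <- avail2("P1")
  v <- vrows(vrow("P1", "DIAGNOSIS", "FLT3", "ITD", NA, "GENE_SCAN"),
             vrow("P1", "CMR", "FLT3", "ITD", NA, "GENE_SCAN"))
  expect_warning(out <- flagGermline(v, av), "presence-only")
  expect_false(any(out$is_germline))
})

test_that("germline flagging is invariant to row order", {
  av <- avail2(c("P1", "P2"))
  v <- vrows(vrow("P1", "DIAGNOSIS", "ATM", "rs1", 0.49),
             vrow("P1", "CMR", "ATM", "rs1", 0.51),
             vrow("P2", "DIAGNOSIS", "DNMT3A", "m1", 0.45),
             vrow("P2", "CMR", "DNMT3A", "m1", 0.03))
  a <- flagGermline(v, av)
  set.seed(1)
  perm <- sample(nrow(v))
  b <- flagGermline(v[perm, ], av)
  b <- b[order(match(paste(b$patient_id, b$timepoint),
                     paste(a$patient_id, a$timepoint))), ]
  expect_equal(a$is_germline, b$is_germline)
})

test_that("detection cutoffs are inclusive at the boundary", {
  v <- vrows(vrow("P1", "CMR", "DNMT3A", "m1", 0.005),
             vrow("P1", "CMR", "TET2", "m2", 0.01),
             vrow("P1", "DIAGNOSIS", "NRAS", "m3", 0.40),
             vrow("P1", "DIAGNOSIS", "FLT3", "ITD", NA, "GENE_SCAN"))
  out <- applyDetectionCutoff(v, filterConfig())
  expect_false("DNMT3A" %in% out$gene)   # 0.5% at CMR: not detected
  expect_true("TET2" %in% out$gene)      # exactly 1%: detected (>= cutoff)
  expect_true("NRAS" %in% out$gene)
  expect_true("FLT3" %in% out$gene)      # presence-only passes
})

test_that("panel restriction keeps NPM1 and gene-scan calls", {
  v <- vrows(vrow("P1", "DIAGNOSIS", "ZZZ9", "m1", 0.30),
             vrow("P1", "DIAGNOSIS", "NPM1", "W288fs", 0.35),
             vrow("P1", "DIAGNOSIS", "DNMT3A", "m2", 0.42),
             vrow("P1", "DIAGNOSIS", "FLT3", "ITD", NA, "GENE_SCAN"))
  out <- restrictToPanel(v, c("DNMT3A", "TET2"))
  expect_setequal(out$gene, c("NPM1", "DNMT3A", "FLT3"))
  expect_error(restrictToPanel(v, character()), "empty panel")
  # WGS mode honors the coding flag instead of the panel
  v$is_coding <- c(FALSE, TRUE, TRUE, TRUE)
  wgs <- restrictToPanel(v, character(), wgsMode = TRUE)
  expect_false("ZZZ9" %in% wgs$gene)
})

test_that("each retention filter is idempotent", {
  set.seed(42)
  sim <- simulateCohort(simConfig(n_patients = 60, germline_rate = 0.3),
                        seed = 42)
  co <- sim$cohort
  av <- availableTimepoints(co)
  cfg <- filterConfig()
  v <- variants(co)
  g1 <- suppressWarnings(flagGermline(v, av, cfg))
  g2 <- suppressWarnings(flagGermline(g1, av, cfg))
  expect_identical(g1, g2)
  c1 <- applyDetectionCutoff(g1, cfg)
  expect_identical(c1, applyDetectionCutoff(c1, cfg))
  p1 <- restrictToPanel(c1, panelGenes(co))
  expect_identical(p1, restrictToPanel(p1, panelGenes(co)))
})

test_that("injected germline spikes are fully recalled, somatic calls kept", {
  sim <- simulateCohort(simConfig(n_patients = 120, germline_rate = 1),
                        seed = 11)
  co <- sim$cohort
  flagged <- suppressWarnings(
    flagGermline(variants(co), availableTimepoints(co), filterConfig()))
  spikes <- paste(sim$truth_germline$patient_id, sim$truth_germline$gene,
                  sim$truth_germline$variant_id)
  keys <- paste(flagged$patient_id, flagged$gene, flagged$variant_id)
  # recall: every spiked observation flagged
  expect_true(all(flagged$is_germline[keys %in% spikes]))
  # specificity: no somatic call below 40% VAF is flagged
  somatic <- !(keys %in% spikes) & !is.na(flagged$vaf) & flagged$vaf < 0.4
  expect_false(any(flagged$is_germline[somatic]))
})
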