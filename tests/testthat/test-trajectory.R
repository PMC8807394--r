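test_that("events match on (gene, variant_id) with gene-level fallback", {
  # exact key match across timepoints -> one persistent event
  v <- vrows(vrow("P1", "DIAGNOSIS", "DNMT3A", "R882H", 0.42),
             vrow("P1", "CMR", "DNMT3A", "R882H", 0.03))
  ev <- matchEvents(v)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$cmr_label, "PERSISTENT")
  expect_equal(ev$vaf_d, 0.42)
  # diagnosis-only singleton -> lost
  ev <- matchEvents(vrow("P1", "DIAGNOSIS", "TET2", "Q810*", 0.30))
  expect_equal(ev$cmr_label, "LOST")
  # blank id at CMR falls back to the single identified chain, with warning
  v <- vrows(vrow("P1", "DIAGNOSIS", "DNMT3A", "R882H", 0.42),
             vrow("P1", "CMR", "DNMT3A", "", 0.03))
  expect_warning(ev <- matchEvents(v), "blank variant_id")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$cmr_label, "PERSISTENT")
  # two distinct ids at one timepoint stay two events
  v <- vrows(vrow("P1", "CMR", "DNMT3A", "R882H", 0.03),
             vrow("P1", "CMR", "DNMT3A", "S714C", 0.02))
  expect_equal(nrow(matchEvents(v)), 2L)
  # with two identified chains, blanks form their own event (no fallback)
  v <- vrows(vrow("P1", "DIAGNOSIS", "DNMT3A", "R882H", 0.42),
             vrow("P1", "DIAGNOSIS", "DNMT3A", "S714C", 0.40),
             vrow("P1", "CMR", "DNMT3A", "", 0.03))
  expect_equal(nrow(matchEvents(v)), 3L)
})

test_that("index mutation, germline and gene-scan calls never form events", {
  v <- vrows(vrow("P1", "DIAGNOSIS", "NPM1", "W288fs", 0.35),
             vrow("P1", "DIAGNOSIS", "FLT3", "ITD", NA, "GENE_SCAN"),
             vrow("P1", "DIAGNOSIS", "DNMT3A", "R882H", 0.42))
  g <- vrow("P1", "DIAGNOSIS", "ATM", "rs1", 0.5)
  g$is_germline <- TRUE
  ev <- matchEvents(rbind(v, g))
  expect_equal(ev$gene, "DNMT3A")
})

test_that("a CMR observation removed by the cutoff classifies as LOST", {
  v <- vrows(vrow("P1", "DIAGNOSIS", "IDH2", "R140Q", 0.38),
             vrow("P1", "CMR", "IDH2", "R140Q", 0.005))
  kept <- applyDetectionCutoff(v, filterConfig())
  ev <- matchEvents(kept)
  expect_equal(ev$cmr_label, "LOST")
})

test_that("relapse patterns enumerate all seven presence signatures", {
  grid <- expand.grid(d = c(TRUE, FALSE), cmr = c(TRUE, FALSE),
                      r = c(TRUE, FALSE))
  grid <- grid[rowSums(grid) > 0L, ]
  got <- patternFromPresence(grid$d, grid$cmr, grid$r)
  want <- apply(grid, 1L, function(x) {
    paste(c("D", "CMR", "R")[as.logical(x)], collapse = "_")
  })
  want[want == "D_CMR_R"] <- "D_CMR_R"
  want[want == "CMR"] <- "CMR_ONLY"
  want[want == "D"] <- "D_ONLY"
  want[want == "R"] <- "R_ONLY"
  expect_equal(got, unname(want))
  expect_equal(sort(unique(got)), sort(c("D_ONLY", "D_CMR", "D_CMR_R",
                                         "D_R", "CMR_R", "R_ONLY",
                                         "CMR_ONLY")))
  expect_error(patternFromPresence(FALSE, FALSE, FALSE), "empty presence")
})

test_that("CMR labels agree with relapse patterns on shared prefixes", {
  grid <- expand.grid(d = c(TRUE, FALSE), cmr = c(TRUE, FALSE),
                      r = c(TRUE, FALSE))
  grid <- grid[rowSums(grid) > 0L, ]
  ev <- data.frame(patient_id = "P1", gene = "X",
                   variant_id = as.character(seq_len(nrow(grid))),
                   at_d = grid$d, at_cmr = grid$cmr, at_r = grid$r,
                   vaf_d = NA_real_, vaf_cmr = NA_real_, vaf_r = NA_real_,
                   has_relapse_sample = TRUE, stringsAsFactors = FALSE)
  ev$cmr_label <- classifyCmr(ev)
  ev$relapse_pattern <- classifyRelapsePattern(ev)
  expect_true(all(ev$cmr_label[startsWith(ev$relapse_pattern, "D_CMR")] ==
                    "PERSISTENT"))
  expect_true(all(ev$cmr_label[ev$relapse_pattern %in%
                                 c("D_ONLY", "D_R")] == "LOST"))
  expect_true(all(ev$cmr_label[ev$relapse_pattern %in%
                                 c("CMR_R", "CMR_ONLY")] == "ACQUIRED"))
  expect_true(is.na(ev$cmr_label[ev$relapse_pattern == "R_ONLY"]))
})

test_that("gene pattern summaries classify dominance correctly", {
  mk <- function(gene, lost, pers, acq) {
    lab <- rep(c("LOST", "PERSISTENT", "ACQUIRED"), c(lost, pers, acq))
    data.frame(patient_id = paste0("P", seq_along(lab)), gene = gene,
               variant_id = as.character(seq_along(lab)),
               at_d = lab != "ACQUIRED", at_cmr = lab != "LOST",
               at_r = FALSE, vaf_d = NA_real_, vaf_cmr = NA_real_,
               vaf_r = NA_real_, has_relapse_sample = FALSE,
               cmr_label = lab, relapse_pattern = NA_character_,
               stringsAsFactors = FALSE)
  }
  ev <- rbind(mk("IDH2", 22, 7, 2),      # 71% lost
              mk("DNMT3A", 10, 19, 5),   # 29/56/15: heterogeneous
              mk("TP53", 0, 0, 3),       # all acquired
              mk("RARE", 1, 0, 0))       # below minEvents
  s <- summarizeGenePatterns(ev, minEvents = 2, dominanceThreshold = 0.70)
  expect_equal(s$pattern_class[s$gene == "IDH2"], "MOSTLY_LOST")
  expect_equal(s$pattern_class[s$gene == "DNMT3A"], "HETEROGENEOUS")
  expect_equal(s$pattern_class[s$gene == "TP53"], "MOSTLY_ACQUIRED")
  expect_true(is.na(s$pattern_class[s$gene == "RARE"]))
  sums <- s$frac_lost + s$frac_persistent + s$frac_acquired
  expect_equal(sums, rep(1, nrow(s)))
  expect_equal(s$n_events[s$gene == "IDH2"], 31L)
})

test_that("cohort summaries are invariant to patient and row order", {
  sim <- simulateCohort(simConfig(n_patients = 80), seed = 5)
  ev <- buildEvents(sim$cohort)
  s1 <- summarizeGenePatterns(ev)
  set.seed(2)
  s2 <- summarizeGenePatterns(ev[sample(nrow(ev)), ])
  expect_equal(s1, s2)
})
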