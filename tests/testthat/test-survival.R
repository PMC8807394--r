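test_that("endpoints follow the event-time skeleton", {
  p <- mkPatients("P1", t_relapse = 300, death = TRUE, t_last = 500)
  ep <- buildEndpoints(p)
  expect_equal(ep$efs_time, 300); expect_true(ep$efs_event)
  expect_equal(ep$os_time, 500); expect_true(ep$os_event)
  expect_equal(ep$os_after_relapse_time, 200)
  expect_true(ep$os_after_relapse_event)
  # no relapse, alive
  ep <- buildEndpoints(mkPatients("P2", t_last = 1200))
  expect_equal(ep$efs_time, 1200); expect_false(ep$efs_event)
  expect_true(is.na(ep$os_after_relapse_time))
  # relapse then censored alive
  ep <- buildEndpoints(mkPatients("P3", t_relapse = 300, t_last = 900))
  expect_equal(ep$os_after_relapse_time, 600)
  expect_false(ep$os_after_relapse_event)
  # death recorded before the relapse date is a data error
  bad <- mkPatients("P4", t_relapse = 300, death = TRUE, t_last = 500)
  bad$t_death_or_censor <- 250
  expect_error(buildEndpoints(bad), "out of order|death before relapse")
  # EFS can be measured from the CMR date instead
  ep <- buildEndpoints(mkPatients("P5", t_relapse = 300, t_last = 900),
                       efsOrigin = "cmr")
  expect_equal(ep$efs_time, 200)
})

test_that("KM estimates match hand-computed product limits", {
  # one subject, event at 5
  km <- kmEstimate(5, TRUE)
  expect_equal(kmSurvAt(km, c(4.9, 5, 6)), c(1, 0, 0))
  # {1 event, 2 censored, 3 event}: S = 2/3 on [1,3), 0 at 3
  km <- kmEstimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(kmSurvAt(km, c(0.5, 1, 2.5, 3)), c(1, 2/3, 2/3, 0))
  expect_equal(km$n_risk[km$time == 3], 1)
  # all censored
  expect_message(km <- kmEstimate(c(1, 2), c(FALSE, FALSE)), "censored")
  expect_equal(kmSurvAt(km, 1:3), c(1, 1, 1))
})

test_that("without censoring KM equals the empirical survival function", {
  set.seed(31)
  for (i in 1:5) {
    tt <- sample(1:50, 20, replace = TRUE)
    km <- kmEstimate(tt, rep(TRUE, 20))
    grid <- seq(0, 55, by = 0.5)
    emp <- vapply(grid, function(g) mean(tt > g), numeric(1))
    expect_equal(kmSurvAt(km, grid), emp)
  }
})

test_that("log-rank behaves at the null and rejects clear separation", {
  tt <- c(1, 2, 3, 4, 5)
  # two identical groups: statistic at the null center
  lr <- logrankTest(c(tt, tt), rep(TRUE, 10), rep(c("A", "B"), each = 5))
  expect_lt(lr$statistic, 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-6)
  # all A events before any B event
  lr <- logrankTest(c(1:5, 11:15), rep(TRUE, 10), rep(c("A", "B"), each = 5))
  expect_lt(lr$p_value, 0.01)
  # three groups: global + three pairwise rows
  g3 <- rep(c("A", "B", "C"), each = 5)
  lr <- logrankTest(c(1:5, 6:10, 11:15), rep(TRUE, 15), g3)
  expect_equal(lr$df, 2L)
  expect_equal(nrow(lr$pairwise), 3L)
  expect_error(logrankTest(tt, rep(TRUE, 5), rep("A", 5)), "two non-empty")
})

test_that("two-group log-rank equals the Cox score test on tie-free data", {
  set.seed(8)
  tt <- sort(runif(40, 1, 100))       # distinct times: no ties
  ee <- rep(TRUE, 40)
  gg <- sample(rep(0:1, 20))
  lr <- logrankTest(tt, ee, gg)
  d <- data.frame(t = tt, e = ee, x = gg)
  cf <- coxFit(d, "t", "e", "x")
  expect_equal(lr$statistic, attr(cf, "score"), tolerance = 1e-6)
})

test_that("Cox coefficients match a numeric partial-likelihood oracle", {
  # 4 subjects, all events, binary covariate: maximize the exact partial
  # likelihood by golden-section search, independent of any Cox code.
  # The covariate alternates across the event order so the maximum is
  # finite (a covariate separating early from late deaths has a monotone
  # partial likelihood and no MLE).
  d <- data.frame(t = 1:4, e = TRUE, x = c(1, 0, 0, 1))
  neglogPL <- function(b) {
    risk <- exp(b * d$x)
    -sum(vapply(1:4, function(i) {
      log(risk[i] / sum(risk[d$t >= d$t[i]]))
    }, numeric(1)))
  }
  oracle <- stats::optimize(neglogPL, c(-5, 5), tol = 1e-10)$minimum
  cf <- coxFit(d, "t", "e", "x")
  expect_equal(cf$coef, oracle, tolerance = 1e-6)
  # a null covariate gives HR ~ 1
  d2 <- data.frame(t = c(1:6, 1:6), e = TRUE,
                   x = rep(0:1, each = 6))
  cf2 <- coxFit(d2, "t", "e", "x")
  expect_equal(cf2$hr, 1, tolerance = 1e-8)
})

test_that("swapping group labels inverts the hazard ratio", {
  set.seed(12)
  d <- data.frame(t = rexp(60, rate = 0.1), e = TRUE,
                  x = rep(0:1, each = 30))
  d$t[d$x == 1] <- d$t[d$x == 1] / 2
  a <- coxFit(d, "t", "e", "x")
  d$x <- 1 - d$x
  b <- coxFit(d, "t", "e", "x")
  expect_equal(a$hr, 1 / b$hr, tolerance = 1e-8)
})

test_that("Cox fit reports deletions, tie options and failure modes", {
  set.seed(4)
  d <- data.frame(t = round(rexp(50, 0.1)) + 1, e = TRUE,
                  x = rnorm(50))
  d$x[1:3] <- NA
  cf <- coxFit(d, "t", "e", "x")
  expect_equal(attr(cf, "n_dropped"), 3L)
  expect_equal(cf$n, 47)
  cb <- coxFit(d, "t", "e", "x", ties = "breslow")
  expect_false(isTRUE(all.equal(cf$coef, cb$coef)))  # ties present
  expect_error(coxFit(data.frame(t = 1, e = TRUE, x = 1), "t", "e",
                      c("x", "t")), "fewer events")
  # perfect separation flagged with unbounded CI
  sep <- data.frame(t = c(1, 2, 3, 10, 11, 12), e = TRUE,
                    x = c(1, 1, 1, 0, 0, 0))
  expect_warning(cs <- coxFit(sep, "t", "e", "x"), "monotone likelihood")
  expect_true(cs$separation)
  expect_equal(cs$ci_high, Inf)
})

test_that("the model suite emits the full stratified result table", {
  fx <- buildReferenceFixture()
  fc <- suppressWarnings(filterVariants(fx))
  ev <- buildEvents(fc)
  sch <- geneScheme("CHIP5")
  strata <- stratifyPatientsCmr(ev, sch, patients(fc)$patient_id)
  rel <- stratifyPatientsRelapse(ev, sch)
  res <- runPaperModels(fc, strata, rel)
  expect_true(all(c("EFS", "OS", "OS_AFTER_RELAPSE") %in% res$endpoint))
  expect_equal(sum(res$method == "COX_MULTIV"), 5L)  # five covariates
  expect_equal(sum(res$method == "LOGRANK" &
                     res$grouping == "cmr_stratum (global)"), 2L)
  # three strata produce three pairwise rows per endpoint
  expect_equal(sum(res$method == "LOGRANK" & grepl(" vs ", res$grouping)), 6L)
  expect_true(is.numeric(attr(res, "multivariate_score")))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  ok <- !is.na(res$hr)
  expect_true(all(res$ci_low[ok] <= res$hr[ok] + 1e-12))
  expect_true(all(res$hr[ok] <= res$ci_high[ok] + 1e-12))
})

test_that("the multivariate model recovers a planted stratum hazard", {
  cfg <- simConfig(n_patients = 500, acquire_scale = 6, hr_chop = 3)
  sim <- simulateCohort(cfg, seed = 77)
  co <- sim$cohort
  ev <- buildEvents(suppressWarnings(filterVariants(co)))
  strata <- stratifyPatientsCmr(ev, geneScheme("CHIP5"),
                                patients(co)$patient_id)
  res <- runPaperModels(co, strata)
  mv <- res[res$method == "COX_MULTIV" & res$term == "onc_at_cmr", ]
  expect_gt(mv$hr, 1.5)
  expect_true(mv$ci_low <= 3 && 3 <= mv$ci_high)
})
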