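test_that("cohort generation respects sizes, ranges and determinism", {
  co <- simulateCohort(10, seed = 1)
  expect_equal(nrow(co), 30)
  expect_equal(as.vector(table(co$group)), rep(10L, 3))
  expect_true(all(co$hr_max >= 160 & co$hr_max <= 210))
  expect_true(all(co$vo2max_t1 >= 45 & co$vo2max_t1 <= 80))
  expect_true(all(co$hr_at_1p5 < 0.9 * co$hr_max))
  ## VO2max near the group entry means (~60 mL/min/kg)
  mu <- tapply(co$vo2max_t1, co$group, mean)
  expect_true(all(abs(mu - 60) < 6))

  expect_equal(nrow(simulateCohort(2, seed = 7)), 6)
  expect_error(simulateCohort(1, seed = 1), "nPerGroup")

  co2 <- simulateCohort(10, seed = 1)
  expect_identical(co, co2)
  co3 <- simulateCohort(10, seed = 2)
  expect_false(identical(co$hr_max, co3$hr_max))
})

test_that("schedules implement the shock-microcycle protocol", {
  for (g in c("HSM", "HSM_LIT")) {
    s <- simulateSchedule(g)
    hiit <- s[s$kind == "HIIT", ]
    expect_equal(nrow(hiit), 10)
    expect_true(all(hiit$study_day %in% 1:7))
    expect_equal(sum(hiit$study_day == 4), 0)
    expect_equal(as.vector(table(factor(hiit$study_day,
                                        levels = c(2, 3, 6, 7)))),
                 rep(2L, 4))
    expect_true(all(hiit$planned_minutes == 40))
  }
  hsm <- simulateSchedule("HSM")
  expect_equal(sum(hsm$kind == "LIT"), 0)
  lit <- simulateSchedule("HSM_LIT")
  lit <- lit[lit$kind == "LIT", ]
  expect_equal(sum(lit$planned_minutes), 300)  # +75% of 400 HIIT minutes
  cg <- simulateSchedule("CG")
  expect_equal(sum(cg$kind == "HIIT"), 0)
  ## schedule count invariant independent of the session-volume seed
  for (s in c(3, 99)) {
    co <- simulateCohort(2, seed = s)
    ses <- cohortSessions(co, seed = s)
    hsum <- tapply(ses$kind == "HIIT", ses$participant_id, sum)
    expect_true(all(hsum[co$participant_id[co$group != "CG"]] == 10))
  }
})

test_that("HR traces follow the session structure", {
  co <- simulateCohort(2, seed = 1)
  p <- co[co$group == "HSM", ][1, ]
  hiit <- data.frame(study_day = 1, slot = "AM", kind = "HIIT",
                     planned_minutes = 40)
  tr <- simulateHRTrace(hiit, p, seed = 3)
  expect_equal(nrow(tr), 2400)
  expect_true(all(tr$hr > 40 & tr$hr <= p$hr_max))
  expect_equal(tr$t_s, 0:2399)
  ## interval bouts average 90-95% HRmax
  bouts <- c(601:840, 991:1230, 1381:1620, 1771:2010, 2161:2400)
  expect_gte(mean(tr$hr[bouts]), 0.90 * p$hr_max)
  expect_lte(mean(tr$hr[bouts]), 0.95 * p$hr_max)

  ## zero noise: bout samples sit exactly at the configured fraction
  tr0 <- simulateHRTrace(hiit, p, seed = 3, noiseSd = 0,
                         hiitFraction = 0.92)
  expect_equal(unique(tr0$hr[bouts]), 0.92 * p$hr_max, tolerance = 1e-12)

  lit <- data.frame(study_day = 1, slot = "AM", kind = "LIT",
                    planned_minutes = 30)
  trl <- simulateHRTrace(lit, p, seed = 4)
  expect_equal(nrow(trl), 1800)
  expect_true(all(trl$hr < p$hr_at_1p5))  # strictly sub-threshold

  pbad <- p; pbad$hr_max <- NA_real_
  expect_error(simulateHRTrace(hiit, pbad, seed = 1), "hr_max")
  expect_error(simulateHRTrace(hiit, p, seed = 1, hiitFraction = 0.99),
               "hiitFraction")
})

test_that("incremental tests have 1.5 km/h stages and bracket the threshold", {
  co <- simulateCohort(3, seed = 5)
  for (i in c(1, 5)) {
    st <- simulateIncrementalTest(co[i, ], seed = i)
    expect_equal(unique(round(diff(st$speed), 10)), 1.5)
    expect_true(all(diff(st$lactate) >= 0))
    expect_lt(st$lactate[1], 1.5)
    expect_gt(max(st$lactate), 1.5)
  }
  st1 <- simulateIncrementalTest(co[1, ], seed = 9)
  st2 <- simulateIncrementalTest(co[1, ], seed = 9)
  expect_identical(st1, st2)
})

test_that("biomarker panel has full coverage and planted-null symmetry", {
  st <- sharedStudy()
  lf <- longForm(st$panel)
  expect_equal(nrow(lf), 30 * 9 * 32)
  expect_true(all(lf$value > 0))
  expect_equal(sort(unique(lf$marker)), sort(panelMarkers()))

  ## config must cover requested markers
  expect_error(
    simulateBiomarkers(st$participants, nullEffectConfig("CK"),
                       seed = 1, markers = c("CK", "nope")),
    "nope")

  ## all shifts zero: group log-means agree within Monte-Carlo error
  diffs <- vapply(1:12, function(i) {
    co <- simulateCohort(10, seed = 3000 + i)
    pan <- simulateBiomarkers(co, nullEffectConfig("urea"), seed = 3000 + i)
    lf <- longForm(pan)
    iv <- lf[lf$phase == "intervention", ]
    mean(log(iv$value[iv$group == "HSM"])) -
      mean(log(iv$value[iv$group == "CG"]))
  }, numeric(1))
  ## per-replicate SE of the group difference: sqrt(2 * sigma_b^2 / 10)
  info <- markerPanelInfo()
  sb <- info$sigma_subject[info$marker == "urea"]
  sw <- info$sigma_within[info$marker == "urea"]
  se <- sqrt(2 * (sb^2 + sw^2 / 4) / 10) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se)
})

test_that("self-reports stay on their scales and track load", {
  st <- sharedStudy()
  sr <- st$selfReports
  expect_true(all(sr$soreness >= 0 & sr$soreness <= 100))
  expect_true(all(sr$pain >= 0 & sr$pain <= 100))
  expect_true(all(sr$wellbeing >= 0 & sr$wellbeing <= 100))
  expect_true(all(sr$fatigue >= 1 & sr$fatigue <= 10))
  expect_true(all(sr$sleep >= 1 & sr$sleep <= 7))
  ## soreness rises with the previous-day load
  al <- sharedAligned()
  expect_gt(cor(al$soreness, al$exp_trimp_7), 0.3)
})

test_that("study generation is deterministic end to end", {
  s1 <- simulateStudy(nPerGroup = 2, seed = 11, traces = FALSE,
                      markers = c("CK", "RBC"))
  s2 <- simulateStudy(nPerGroup = 2, seed = 11, traces = FALSE,
                      markers = c("CK", "RBC"))
  expect_identical(s1$participants, s2$participants)
  expect_identical(longForm(s1$panel), longForm(s2$panel))
  expect_identical(s1$selfReports, s2$selfReports)
  expect_identical(s1$plannedDaily, s2$plannedDaily)
})

test_that("dropout removes whole samples but never T0", {
  co <- simulateCohort(5, seed = 2)
  cfg <- effectConfig(markers = markerPanelInfo()[1:3, ], dropout = 0.3)
  pan <- simulateBiomarkers(co, cfg, seed = 2)
  cd <- SummarizedExperiment::colData(pan)
  expect_lt(ncol(pan), 15 * 9)
  expect_equal(sum(cd$timepoint == "T0"), 15)
})
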