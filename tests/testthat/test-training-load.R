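test_that("zone model recovers the exact affine case and 90% HRmax", {
  st <- data.frame(speed = c(9, 10.5, 12, 13.5),
                   lactate = c(0.8, 1.1, 1.5, 2.4),
                   hr = 100 + 5 * c(9, 10.5, 12, 13.5))
  zm <- fitZoneModel(st, hrMax = 190)
  expect_equal(zm@speedAt1p5, 12)
  expect_equal(zm@hrZ1Z2, 160)       # HR = 100 + 5 * 12
  expect_equal(zm@hrZ2Z3, 171)       # 0.90 * 190
  expect_equal(zm@weights, c(1, 2, 3))
})

test_that("zone model errors when the threshold is not bracketed", {
  st <- data.frame(speed = c(9, 10.5, 12), lactate = c(0.5, 0.8, 1.2),
                   hr = c(140, 150, 160))
  expect_error(fitZoneModel(st, hrMax = 190), "not bracketed")
  st2 <- data.frame(speed = c(9, 10.5, 12), lactate = c(1.6, 2, 3),
                    hr = c(140, 150, 160))
  expect_error(fitZoneModel(st2, hrMax = 190), "not bracketed")
  expect_error(fitZoneModel(st[1:2, ], hrMax = 190), "3 stages")
  ## lactate-anchored HR above 90% HRmax -> inconsistent model
  st3 <- data.frame(speed = c(9, 10.5, 12), lactate = c(0.9, 1.2, 1.6),
                    hr = c(170, 180, 190))
  expect_error(fitZoneModel(st3, hrMax = 195), "inconsistent")
})

test_that("zone model matches an independent least-squares oracle on noisy stages", {
  co <- simulateCohort(3, seed = 3)
  p <- co[2, ]
  st <- simulateIncrementalTest(p, seed = 3)
  zm <- fitZoneModel(st, p$hr_max)
  ## independent recomputation: normal equations + manual interpolation
  idx <- which(st$lactate >= 1.5)[1]
  v <- st$speed[idx - 1] + (1.5 - st$lactate[idx - 1]) *
    (st$speed[idx] - st$speed[idx - 1]) /
    (st$lactate[idx] - st$lactate[idx - 1])
  beta <- lsOracle(st$speed, st$hr)
  expect_equal(zm@hrZ1Z2, unname(beta[1] + beta[2] * v),
               tolerance = 1e-10)
  ## and it stays close to the generating physiology
  expect_lt(abs(zm@hrZ1Z2 - p$hr_at_1p5), 3)
})

test_that("zone times and TRIMP reproduce piecewise-constant traces exactly", {
  zm <- new("ZoneModel", hrZ1Z2 = 150, hrZ2Z3 = 171, hrMax = 190)
  ## 40 min entirely below both boundaries
  zt <- zoneTimes(rep(140, 40 * 60), zm)
  expect_equal(c(zt$minutes_z1, zt$minutes_z2, zt$minutes_z3), c(40, 0, 0))
  expect_equal(zt$trimp, 40)
  ## 10 min z1 + 20 min z3 + 10 min z1
  hr <- c(rep(140, 600), rep(180, 1200), rep(140, 600))
  zt <- zoneTimes(hr, zm)
  expect_equal(c(zt$minutes_z1, zt$minutes_z2, zt$minutes_z3), c(20, 0, 20))
  expect_equal(zt$trimp, 80)
  ## boundary samples: lower-inclusive at each zone start
  expect_equal(zoneTimes(rep(150, 60), zm)$minutes_z2, 1)
  expect_equal(zoneTimes(rep(171, 60), zm)$minutes_z3, 1)
  expect_error(zoneTimes(numeric(0), zm), "empty")
})

test_that("session TRIMP is the weighted zone sum", {
  expect_equal(sessionTRIMP(c(20, 0, 20)), 80)
  expect_equal(sessionTRIMP(c(40, 0, 0)), 40)
  expect_equal(sessionTRIMP(c(0, 0, 0)), 0)
  expect_equal(sessionTRIMP(c(10, 10, 10), weights = c(1, 1, 1)), 30)
  expect_error(sessionTRIMP(c(-1, 0, 0)), "negative")
})

test_that("TRIMP strictly increases when a minute moves to a higher zone", {
  base <- c(10, 20, 10)
  for (from in 1:2) for (to in (from + 1):3) {
    moved <- base
    moved[from] <- moved[from] - 1
    moved[to] <- moved[to] + 1
    expect_gt(sessionTRIMP(moved), sessionTRIMP(base))
  }
})

test_that("a planted 0.92 HRmax interval session spends ~20 min in zone 3", {
  co <- simulateCohort(2, seed = 8)
  p <- co[co$group == "HSM", ][1, ]
  spec <- data.frame(study_day = 1, slot = "AM", kind = "HIIT",
                     planned_minutes = 40)
  tr <- simulateHRTrace(spec, p, seed = 8, hiitFraction = 0.92)
  st <- simulateIncrementalTest(p, seed = 8)
  zm <- fitZoneModel(st, p$hr_max)
  zt <- zoneTimes(tr, zm)
  ## oracle: direct sample count against the same boundary
  expect_equal(zt$minutes_z3, sum(tr$hr >= zm@hrZ2Z3) / 60)
  expect_gte(zt$minutes_z3, 18)
  expect_lte(zt$minutes_z3, 22)
  expect_equal(zt$minutes_z1 + zt$minutes_z2 + zt$minutes_z3, 40)
})

test_that("expTRIMP follows the recursion, fixed point and bounds", {
  expect_equal(expTRIMP(c(80, 0, 80), N = 7), c(80, 60, 65))
  for (N in c(3, 5, 7))
    expect_equal(expTRIMP(rep(55, 12), N = N), rep(55, 12))
  ## zero-initialized variant
  expect_equal(expTRIMP(c(80, 0), N = 7, init = "zero"), c(20, 15))
  expect_error(expTRIMP(numeric(0), N = 7), "empty")
  expect_error(expTRIMP(c(1, 2), N = 0), "positive")
  ## boundedness: min(loads) <= e_t <= max(loads)
  set.seed(41)
  for (rep in 1:5) {
    loads <- runif(30, 0, 200)
    for (N in c(3, 5, 7)) {
      e <- expTRIMP(loads, N)
      expect_true(all(e >= min(loads) - 1e-12 & e <= max(loads) + 1e-12))
    }
  }
})

test_that("the as-printed recursion variant is reproduced verbatim and diverges", {
  loads <- c(10, 0, 0, 0, 0)
  lam <- 2 / (7 + 1)
  e <- numeric(5); e[1] <- loads[1]
  for (t in 2:5) e[t] <- loads[t] * lam + (1 - lam) + e[t - 1]
  expect_equal(expTRIMP(loads, N = 7, variant = "as-printed"), e)
  ## it keeps growing even with zero load - the audit rationale
  long <- expTRIMP(rep(0, 50), N = 7, variant = "as-printed")
  expect_true(all(diff(long) > 0))
})

test_that("daily load fills rest days with zero and still decays the EWMA", {
  sl <- data.frame(participant_id = "P01", study_day = c(-9, -9, -7),
                   trimp = c(40, 40, 80))
  dl <- dailyLoad(sl, days = -9:-5, N = 7)
  expect_equal(dl$trimp, c(80, 0, 80, 0, 0))
  expect_equal(dl$exp_trimp_7, expTRIMP(c(80, 0, 80, 0, 0), 7))
  expect_error(dailyLoad(sl, days = c(-9, -7)), "contiguous")
})

test_that("zone partition is exact for arbitrary traces", {
  zm <- new("ZoneModel", hrZ1Z2 = 150, hrZ2Z3 = 171, hrMax = 190)
  set.seed(7)
  for (rep in 1:5) {
    hr <- runif(1234, 60, 190)
    zt <- zoneTimes(hr, zm)
    expect_equal(zt$minutes_z1 + zt$minutes_z2 + zt$minutes_z3,
                 length(hr) / 60)
  }
})
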