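test_that("aligned table lags load by one day and carries VO2max forward", {
  st <- sharedStudy()
  al <- sharedAligned()
  expect_lte(nrow(al), 240)
  expect_false("T0" %in% al$timepoint)
  ## blood draw on study day 7 (T3) gets the day-6 expTRIMP
  dl <- st$plannedDaily
  i <- which(al$participant_id == "P01" & al$timepoint == "T3")
  expect_equal(al$exp_trimp_7[i],
               dl$exp_trimp_7[dl$participant_id == "P01" &
                                dl$study_day == 6])
  ## D4 carries the T1 VO2max; T5 carries its own test
  vo <- st$vo2max
  j <- which(al$participant_id == "P02" & al$timepoint == "D4")
  expect_equal(al$vo2max[j],
               vo$vo2max[vo$participant_id == "P02" & vo$timepoint == "T1"])
  k <- which(al$participant_id == "P02" & al$timepoint == "T5")
  expect_equal(al$vo2max[k],
               vo$vo2max[vo$participant_id == "P02" & vo$timepoint == "T5"])
  ## the carry-forward map is total: every row has exactly one value
  expect_true(all(is.finite(al$vo2max)))
  ## missing prior-day load drops the row with a message
  dl2 <- dl[dl$study_day != 6, ]
  expect_message(
    al2 <- buildAlignedTable(st$panel, dl2, st$selfReports, st$vo2max),
    "dropped")
  expect_equal(nrow(al2), nrow(al) - 30)
})

test_that("pearson matrix is exact on linear relations and symmetric", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  d <- data.frame(participant_id = "P01", group = "CG",
                  timepoint = "T1", study_day = 1,
                  a = x, b = 2 * x + 1, c = -x,
                  d = c(2, 1, 4, 3, 6, 5, 8, 7))
  cm <- pearsonMatrix(d, vars = c("a", "b", "c", "d"))
  r <- corValues(cm)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(unname(corCounts(cm)["a", "b"]), 8L)
  ## zero variance is flagged, not silently dropped
  d$e <- 5
  expect_warning(cm2 <- pearsonMatrix(d, vars = c("a", "b", "e")),
                 "zero variance")
  expect_true(is.na(corValues(cm2)["a", "e"]))
})

test_that("strength classes follow the published bands", {
  expect_equal(strengthClass(c(0.1, -0.2, 0.295)), rep("low", 3))
  expect_equal(strengthClass(c(0.3, -0.45, 0.495)), rep("moderate", 3))
  expect_equal(strengthClass(c(0.5, -0.9, 1)), rep("strong", 3))
})

test_that("rankings are significance-filtered, sorted, and typed", {
  info <- markerPanelInfo()
  info <- info[info$marker %in% c("CK", "urea", "RBC"), ]
  info$load_rho <- c("CK" = 0.45, "urea" = 0.3, "RBC" = -0.3)[info$marker]
  cfg <- effectConfig(markers = info)
  co <- simulateCohort(10, seed = 31)
  pan <- simulateBiomarkers(co, cfg, seed = 31)
  al <- suppressMessages(buildAlignedTable(
    pan, plannedDailyLoad(co, seed = 31),
    simulateSelfReports(co, seed = 31), simulateVO2max(co, seed = 31)))
  cm <- pearsonMatrix(al, vars = c("CK", "urea", "RBC", "exp_trimp_7"))
  rk <- rankAgainst(cm, "exp_trimp_7")
  expect_equal(rk$marker[1], "CK")
  expect_equal(rk$marker[nrow(rk)], "RBC")
  expect_true(all(diff(rk$r) <= 0))
  expect_true(all(rk$p < 0.05))
  expect_error(rankAgainst(cm, "nope"), "invalid argument")
})

test_that("networks contain significant edges only and honour top-k", {
  al <- sharedAligned()
  cm <- pearsonMatrix(al)
  net <- buildNetwork(cm)
  sp <- significantPairs(cm)
  expect_equal(igraph::ecount(net), sum(sp$significant))
  expect_true(all(igraph::E(net)$weight > 0))
  p <- corPValues(cm)
  el <- igraph::as_edgelist(net)
  expect_true(all(p[cbind(el[, 1], el[, 2])] < 0.05))
  net5 <- buildNetwork(cm, topK = 5)
  expect_equal(igraph::ecount(net5), 5)
  expect_equal(min(abs(igraph::E(net5)$r)),
               sort(abs(sp$r[sp$significant]), decreasing = TRUE)[5])
  expect_error(buildNetwork(cm, topK = 0), "topK")
  ed <- networkEdges(net5)
  expect_equal(nrow(ed), 5)
  expect_equal(ed$weight, abs(ed$r))
  expect_equal(ed$sign, sign(ed$r))
})

test_that("a strongly coupled marker pair tops every per-group network", {
  ## planted leukocyte coupling: GR-WBC share a factor with 0.95 loadings
  info <- markerPanelInfo()
  info <- info[info$marker %in% c("GR", "WBC", "CK", "urea", "RBC"), ]
  info$load_rho <- 0
  fac <- data.frame(marker = c("GR", "WBC"), factor = "leukocyte",
                    loading = 0.95)
  cfg <- effectConfig(markers = info, factors = fac)
  co <- simulateCohort(10, seed = 37)
  pan <- simulateBiomarkers(co, cfg, seed = 37)
  al <- suppressMessages(buildAlignedTable(
    pan, plannedDailyLoad(co, seed = 37),
    simulateSelfReports(co, seed = 37), simulateVO2max(co, seed = 37)))
  nets <- groupNetworks(al, topK = 10,
                        vars = c("GR", "WBC", "CK", "urea", "RBC"))
  expect_equal(sort(names(nets)), c("CG", "HSM", "HSM_LIT"))
  for (g in names(nets)) {
    expect_lte(igraph::ecount(nets[[g]]), 10)
    ed <- networkEdges(nets[[g]])
    hit <- (ed$var1 == "GR" & ed$var2 == "WBC") |
      (ed$var1 == "WBC" & ed$var2 == "GR")
    expect_true(any(hit))
    expect_gt(ed$r[hit], 0.8)
  }
})

test_that("shuffling a variable destroys its significant edges", {
  al <- sharedAligned()
  mk <- intersect(panelMarkers(), colnames(al))[1:12]
  set.seed(71)
  hits <- replicate(100, {
    perm <- al
    perm$soreness <- sample(perm$soreness)
    cm <- pearsonMatrix(perm, vars = c(mk, "soreness"))
    p <- corPValues(cm)[mk, "soreness"]
    mean(p < 0.05, na.rm = TRUE)
  })
  ## permutation null: false-edge rate stays near alpha
  expect_lt(mean(hits), 0.12)
})

test_that("per-participant collapse gives a repeated-measures sensitivity mode", {
  al <- sharedAligned()
  cm <- pearsonMatrix(al, vars = c("CK", "exp_trimp_7"),
                      collapse = "participant")
  expect_equal(unname(corCounts(cm)["CK", "exp_trimp_7"]), 30L)
})
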