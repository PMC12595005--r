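## Hand-crafted correlation matrix with controlled r/p entries.
mkMatrix <- function(rv, pv, markers, target = "exp_trimp_7") {
  vars <- c(markers, target)
  nv <- length(vars)
  r <- diag(nv); dimnames(r) <- list(vars, vars)
  p <- matrix(NA_real_, nv, nv, dimnames = list(vars, vars))
  n <- matrix(100L, nv, nv, dimnames = list(vars, vars))
  for (m in markers) {
    r[m, target] <- r[target, m] <- rv[[m]]
    p[m, target] <- p[target, m] <- pv[[m]]
  }
  new("CorrelationMatrix", r = r, p = p, n = n, alpha = 0.05,
      markers = markers)
}

test_that("ratio candidates are the extreme significant correlations", {
  cm <- mkMatrix(c(CK = 0.4, urea = 0.3, RBC = -0.15),
                 c(CK = 0.001, urea = 0.01, RBC = 0.03),
                 c("CK", "urea", "RBC"))
  sel <- selectRatioCandidates(cm)
  expect_equal(sel$positive, "CK")
  expect_equal(sel$negative, "RBC")
  expect_equal(sel$r_positive, 0.4)
  expect_equal(sel$r_negative, -0.15)
  ## single positive and single negative marker -> that pair
  cm2 <- mkMatrix(c(CK = 0.2, RBC = -0.1), c(CK = 0.04, RBC = 0.01),
                  c("CK", "RBC"))
  sel2 <- selectRatioCandidates(cm2)
  expect_equal(c(sel2$positive, sel2$negative), c("CK", "RBC"))
  ## all couplings positive -> selection fails rather than degenerating
  cm3 <- mkMatrix(c(CK = 0.4, urea = 0.3), c(CK = 0.001, urea = 0.01),
                  c("CK", "urea"))
  expect_error(selectRatioCandidates(cm3), "selection failed")
  ## a negative but non-significant marker does not qualify
  cm4 <- mkMatrix(c(CK = 0.4, RBC = -0.15), c(CK = 0.001, RBC = 0.5),
                  c("CK", "RBC"))
  expect_error(selectRatioCandidates(cm4), "selection failed")
  expect_error(selectRatioCandidates(cm, target = "nope"),
               "invalid argument")
})

test_that("the ratio series is the exact quotient of natural logs", {
  pan <- toyPanel(c("A", "B"), n = 3, value = function(i, tp, m)
    if (m == "A") exp(2) else exp(1))
  rs <- ratioSeries(pan, "A", "B")
  expect_equal(unique(rs$ratio), 2)
  ## identical markers give identically 1
  rs2 <- ratioSeries(pan, "A", "A")
  expect_equal(unique(rs2$ratio), 1)
  ## difference-of-logs variant
  rs3 <- ratioSeries(pan, "A", "B", form = "log-difference")
  expect_equal(unique(rs3$ratio), 1)
  ## direct recomputation oracle on simulated data
  st <- sharedStudy()
  rs4 <- ratioSeries(st$panel, "CK", "RBC")
  lf <- longForm(st$panel)
  key <- paste(lf$participant_id, lf$timepoint)
  num <- lf$value[lf$marker == "CK"][
    match(paste(rs4$participant_id, rs4$timepoint),
          key[lf$marker == "CK"])]
  den <- lf$value[lf$marker == "RBC"][
    match(paste(rs4$participant_id, rs4$timepoint),
          key[lf$marker == "RBC"])]
  expect_equal(rs4$ratio, log(num) / log(den), tolerance = 1e-12)
})

test_that("the unit guard refuses logs of values at or below 1", {
  pan <- toyPanel(c("A", "B"), n = 2, value = function(i, tp, m)
    if (m == "A") 100 else 0.8)
  expect_error(ratioSeries(pan, "A", "B"), "unit guard")
  ## the log-difference form has no such failure mode
  rs <- ratioSeries(pan, "A", "B", form = "log-difference")
  expect_true(all(is.finite(rs$ratio)))
  expect_error(ratioSeries(pan, "A", "nope"), "not in panel")
})

test_that("a constant denominator reduces the ratio to the log numerator", {
  st <- sharedStudy()
  lf <- longForm(st$panel[c("CK", "RBC"), ])
  lf$value[lf$marker == "RBC"] <- exp(2)
  pan <- BiomarkerPanel(lf)
  rs <- ratioSeries(pan, "CK", "RBC")
  attr(rs, "components") <- c("CK", "RBC")
  al <- sharedAligned()
  ev <- evaluateRatio(rs, al)
  lognum <- log(lf$value[lf$marker == "CK"])
  names(lognum) <- paste(lf$participant_id, lf$timepoint)[lf$marker == "CK"]
  keep <- paste(al$participant_id, al$timepoint)
  expect_equal(ev$r_load,
               unname(cor(lognum[keep], al$exp_trimp_7)),
               tolerance = 1e-12)
})

test_that("evaluateRatio reports component comparison and guards tiny inputs", {
  st <- sharedStudy()
  al <- sharedAligned()
  cm <- pearsonMatrix(al)
  cb <- combinedBiomarker(st$panel, cm, al)
  ev <- cb$evaluation
  expect_equal(nrow(ev$components), 2)
  expect_true(is.finite(ev$r_load) && is.finite(ev$r_soreness))
  expect_gt(ev$n, 200)
  expect_error(evaluateRatio(cb$series, al[1:2, ]), "insufficient")
})

test_that("the log-ratio beats its components more often than chance", {
  info <- markerPanelInfo()
  info <- info[info$marker %in% c("CK", "RBC"), ]
  info$load_rho <- ifelse(info$marker == "CK", 0.4, -0.15)
  cfg <- effectConfig(markers = info)
  wins <- vapply(1:100, function(i) {
    co <- simulateCohort(10, seed = 5000 + i)
    pan <- simulateBiomarkers(co, cfg, seed = 5000 + i)
    al <- suppressMessages(buildAlignedTable(
      pan, plannedDailyLoad(co, seed = 5000 + i),
      simulateSelfReports(co, seed = 5000 + i),
      simulateVO2max(co, seed = 5000 + i)))
    ratio <- log(al$CK) / log(al$RBC)
    abs(cor(ratio, al$exp_trimp_7)) >=
      max(abs(cor(al$CK, al$exp_trimp_7)), abs(cor(al$RBC, al$exp_trimp_7)))
  }, logical(1))
  ## one-sided binomial test against the 50% chance level
  bt <- binom.test(sum(wins), length(wins), p = 0.5,
                   alternative = "greater")
  expect_lt(bt$p.value, 0.05)
})

test_that("shuffled load decouples the ratio", {
  st <- sharedStudy()
  al <- sharedAligned()
  rs <- ratioSeries(st$panel, "CK", "RBC")
  key <- match(paste(al$participant_id, al$timepoint),
               paste(rs$participant_id, rs$timepoint))
  ratio <- rs$ratio[key]
  set.seed(19)
  sig <- replicate(100, {
    cor.test(ratio, sample(al$exp_trimp_7))$p.value < 0.05
  })
  expect_lte(mean(sig), 0.12)
})
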