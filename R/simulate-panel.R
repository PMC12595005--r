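#' Simulate VO2max measurements at the four exercise tests
#'
#' VO2max is measured at T1 (entry test) and the three post-intervention
#' tests T4, T5, T6.  Intervention groups gain a small training effect
#' (~+2% by T5/T6), controls stay flat; all values carry test-retest
#' noise and are clamped to a physiologically plausible 45-80 mL/min/kg.
#'
#' @param participants cohort table (supplies `vo2max_t1`).
#' @param seed integer seed.
#' @return `data.frame`: `participant_id`, `timepoint`, `vo2max`.
#' @export
simulateVO2max <- function(participants, seed = 1) {
  gain <- c(CG = 0, HSM = 0.02, HSM_LIT = 0.025)
  ramp <- c(T1 = 0, T4 = 0.6, T5 = 1, T6 = 1)  # fraction of full gain
  .withSeed(.subSeed(seed, 301L), {
    out <- do.call(rbind, lapply(.VO2_TESTS, function(tp) {
      g <- gain[as.character(participants$group)] * ramp[[tp]]
      noise <- if (tp == "T1") 0 else rnorm(nrow(participants), 0, 0.8)
      data.frame(participant_id = participants$participant_id,
                 timepoint = tp,
                 vo2max = pmin(80, pmax(45,
                   participants$vo2max_t1 * (1 + g) + noise)),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

## Latent load z-scores: the participant's previous-day 7-day expTRIMP
## from the individualized session plan, standardized over the pooled
## (participant, day) cells actually used.  Returns a matrix
## [participant_id, as.character(day)] of z values.
.latentLoadZ <- function(participants, seed, days) {
  pl <- plannedDailyLoad(participants, seed = seed,
                         days = (min(days) - 1L):max(days), N = 7)
  key <- paste(pl$participant_id, pl$study_day)
  z <- outer(participants$participant_id, days, function(p, d)
    pl$exp_trimp_7[match(paste(p, d - 1L), key)])
  dimnames(z) <- list(participants$participant_id, as.character(days))
  z
}

.standardize <- function(z, refCols) {
  ref <- z[, refCols, drop = FALSE]
  (z - mean(ref)) / sd(ref)
}

#' Simulate the longitudinal biomarker panel
#'
#' One observation per participant x 9 rest timepoints x marker.  Values
#' are log-normal around `baseline * (1 + shift(group, phase))` with the
#' total log-scale SD split into a stable between-subject intercept and
#' day-to-day noise; a marker's `load_rho` couples its log-concentration
#' to the standardized previous-day 7-day expTRIMP implied by the session
#' plan, so that the planted coupling is the population log-scale Pearson
#' r against training load.
#'
#' @param participants cohort table.
#' @param config an `EffectConfig` (see [effectConfig()]); must cover all
#'   requested markers.
#' @param seed integer seed (falls back to `config$seed`).
#' @param markers optional character subset of the configured markers.
#' @return A [BiomarkerPanel-class].
#' @export
#' @examples
#' p <- simulateCohort(2, seed = 1)
#' panel <- simulateBiomarkers(p, nullEffectConfig(c("CK", "RBC")), seed = 1)
#' dim(panel)  # 2 markers x 54 samples
simulateBiomarkers <- function(participants, config = defaultEffectConfig(),
                               seed = NULL, markers = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  info <- config$markers
  if (!is.null(markers)) {
    bad <- setdiff(markers, info$marker)
    if (length(bad))
      stop("configuration error: no config for marker(s): ",
           paste(bad, collapse = ", "))
    info <- info[match(markers, info$marker), , drop = FALSE]
  }
  shifts <- .shiftArray(config)[info$marker, , , drop = FALSE]
  grid <- timepointGrid()
  zmat <- .latentLoadZ(participants, seed, grid$study_day)
  ## standardize over the non-T0 cells (those entering load correlations)
  zmat <- .standardize(zmat, as.character(grid$study_day[-1]))
  nM <- nrow(info); nP <- nrow(participants); nT <- nrow(grid)
  ## cross-marker factor loading matrix (markers x factors); factors on
  ## markers outside the requested subset are simply not drawn
  fac <- config$factors[config$factors$marker %in% info$marker, ,
                        drop = FALSE]
  fnames <- unique(fac$factor)
  nF <- length(fnames)
  G <- matrix(0, nM, nF, dimnames = list(info$marker, fnames))
  if (nF)
    G[cbind(match(fac$marker, info$marker),
            match(fac$factor, fnames))] <- fac$loading
  sigTot <- sqrt(info$sigma_subject^2 + info$sigma_within^2)
  rho <- info$load_rho
  ## residual scale after latent-load and factor shares
  s <- sqrt(pmax(0, 1 - rho^2 - if (nF) rowSums(G^2) else 0))
  .withSeed(.subSeed(seed, 401L), {
    ## between-subject intercepts (per participant x marker, log scale)
    b <- matrix(rnorm(nP * nM), nrow = nP)
    long <- vector("list", nP)
    for (i in seq_len(nP)) {
      g <- as.character(participants$group[i])
      z <- zmat[i, ]
      z[is.na(z)] <- 0
      e <- matrix(rnorm(nT * nM), nrow = nT)
      ## shared factors: stable trait part + day-level part
      fterm <- 0
      if (nF) {
        B <- rnorm(nF)
        D <- matrix(rnorm(nT * nF), nrow = nT)
        Fm <- matrix(rep(0.7 * B, each = nT), nrow = nT) +
          sqrt(1 - 0.49) * D
        fterm <- sweep(Fm %*% t(G), 2, sigTot, `*`)
      }
      ## log-noise with marginal corr(log v, z) = rho
      noise <- outer(z, sigTot * rho) + fterm +
        sweep(e, 2, s * info$sigma_within, `*`) +
        matrix(rep(s * info$sigma_subject * b[i, ],
                   each = nT), nrow = nT)
      shiftFac <- 1 + t(shifts[, g, as.character(grid$phase), drop = TRUE])
      if (nM == 1L) shiftFac <- matrix(shiftFac, ncol = 1L)
      vals <- sweep(exp(noise), 2, info$baseline, `*`) * shiftFac
      long[[i]] <- data.frame(
        participant_id = participants$participant_id[i],
        group = g,
        timepoint = rep(as.character(grid$timepoint), times = nM),
        study_day = rep(grid$study_day, times = nM),
        marker = rep(info$marker, each = nT),
        value = as.vector(vals),
        stringsAsFactors = FALSE
      )
    }
    long <- do.call(rbind, long)
    if (config$dropout > 0) {
      samp <- unique(long[, c("participant_id", "timepoint")])
      drop <- samp[samp$timepoint != "T0" &
                     runif(nrow(samp)) < config$dropout, , drop = FALSE]
      if (nrow(drop))
        long <- long[!paste(long$participant_id, long$timepoint) %in%
                       paste(drop$participant_id, drop$timepoint), ,
                     drop = FALSE]
    }
    BiomarkerPanel(long)
  })
}

#' Simulate daily self-reports
#'
#' Daily sleep quality (1-7; higher = worse), VAS muscle soreness, muscle
#' pain and well-being (0-100), and fatigue (1-10), generated as monotone
#' functions of the standardized previous-day 7-day expTRIMP plus noise
#' and clipped to their scales - soreness tracks load with a population
#' correlation of about 0.6.
#'
#' @param participants cohort table.
#' @param seed integer seed.
#' @param days study days covered (default -9..21).
#' @return `data.frame`: `participant_id`, `study_day`, `soreness`,
#'   `pain`, `wellbeing`, `fatigue`, `sleep`.
#' @export
simulateSelfReports <- function(participants, seed = 1, days = -9:21) {
  zmat <- .standardize(.latentLoadZ(participants, seed, days),
                       as.character(days))
  nD <- length(days)
  .withSeed(.subSeed(seed, 501L), {
    out <- do.call(rbind, lapply(seq_len(nrow(participants)), function(i) {
      g <- as.character(participants$group[i])
      z <- zmat[i, ]
      clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
      data.frame(
        participant_id = participants$participant_id[i],
        study_day = days,
        soreness = clip(35 + 15 * z + rnorm(nD, 0, 20), 0, 100),
        pain = clip(30 + 12 * z + rnorm(nD, 0, 18), 0, 100),
        wellbeing = clip(60 - 12 * z + rnorm(nD, 0, 15), 0, 100),
        fatigue = clip(round(4 + 1.3 * z + rnorm(nD, 0, 1.5)), 1, 10),
        sleep = clip(round(3.5 + 0.6 * z + rnorm(nD, 0, 1.2)), 1, 7),
        stringsAsFactors = FALSE
      )
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete synthetic monitoring study
#'
#' Generates the full study in one call: cohort, session plan, optional
#' 1-Hz HR traces, incremental-test stages, the biomarker panel,
#' self-reports, VO2max, and the planned daily-load series.  All stages
#' derive their randomness from the one global seed, so identical calls
#' are bitwise-identical.
#'
#' @param nPerGroup participants per group (default 10, as in the study).
#' @param seed global integer seed.
#' @param config an `EffectConfig` (default [defaultEffectConfig()]).
#' @param traces logical, simulate HR traces (expensive; `FALSE` skips
#'   them and downstream load comes from [plannedDailyLoad()]).
#' @param markers optional marker subset for the panel.
#' @return named list: `participants`, `sessions`, `hrTraces` (or NULL),
#'   `petStages`, `panel`, `selfReports`, `vo2max`, `plannedDaily`.
#' @export
#' @examples
#' study <- simulateStudy(nPerGroup = 2, seed = 1, traces = FALSE,
#'                        markers = c("CK", "RBC"))
#' names(study)
simulateStudy <- function(nPerGroup = 10, seed = 1,
                          config = defaultEffectConfig(),
                          traces = TRUE, markers = NULL) {
  participants <- simulateCohort(nPerGroup, seed = seed)
  sessions <- cohortSessions(participants, seed = seed)
  hrTraces <- if (traces) simulateTraces(sessions, participants,
                                         seed = seed) else NULL
  petStages <- simulatePETStages(participants, seed = seed)
  panel <- simulateBiomarkers(participants, config, seed = seed,
                              markers = markers)
  selfReports <- simulateSelfReports(participants, seed = seed)
  vo2max <- simulateVO2max(participants, seed = seed)
  plannedDaily <- plannedDailyLoad(participants, seed = seed)
  list(participants = participants, sessions = sessions,
       hrTraces = hrTraces, petStages = petStages, panel = panel,
       selfReports = selfReports, vo2max = vo2max,
       plannedDaily = plannedDaily)
}
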