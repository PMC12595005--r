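## Planned (protocol-level) TRIMP per session kind, used for the latent
## daily-load signal that drives biomarker coupling and self-reports:
## HIIT = 10 min warm-up (z1) + 5x4 min z3 + 4x2.5 min recovery (z1)
##      = 10 + 60 + 10 = 80 AU;
## LIT = 30 min below the z1/z2 boundary = 30 AU;
## REGULAR = 45 min z1 + 15 min z2 = 75 AU.
.PLANNED_TRIMP <- c(HIIT = 80, LIT = 30, REGULAR = 75)

## Rest days: one per week outside the intervention, plus the mid-cycle
## resting day 4 for everyone.
.REST_DAYS <- c(-10L, -3L, 4L, 11L, 18L)

## Male fraction per group (9/1, 6/4, 8/2 at n = 10).
.MALE_FRAC <- c(CG = 0.8, HSM = 0.6, HSM_LIT = 0.9)

#' Generate a synthetic cohort
#'
#' Draws `3 * nPerGroup` trained endurance athletes allocated to the
#' control (CG), HIIT shock microcycle (HSM) and HSM plus low-intensity
#' training (HSM_LIT) groups.  VO2max at the entry test is drawn near the
#' group means of the study population (~60 mL/min/kg); each participant
#' carries an individual maximum HR, the treadmill speed and HR at the
#' 1.5 mmol/L lactate threshold, and an HR-vs-speed slope used by the
#' incremental-test generator.
#'
#' @param nPerGroup participants per group (>= 2; the study used 10).
#' @param seed integer seed; fixed seed gives identical cohorts.
#' @return `data.frame` with one row per participant: `participant_id`,
#'   `group`, `sex`, `age`, `hr_max`, `hr_at_1p5`, `hr_slope`,
#'   `speed_at_1p5`, `vo2max_t1`.
#' @export
#' @examples
#' cohort <- simulateCohort(10, seed = 1)
#' table(cohort$group)
simulateCohort <- function(nPerGroup = 10, seed = 1) {
  if (!is.numeric(nPerGroup) || nPerGroup < 2)
    stop("nPerGroup must be >= 2 (paired downstream tests need >= 2)")
  nPerGroup <- as.integer(nPerGroup)
  .withSeed(.subSeed(seed, 101L), {
    n <- 3L * nPerGroup
    group <- factor(rep(.GROUPS, each = nPerGroup), levels = .GROUPS)
    sex <- unlist(lapply(.GROUPS, function(g) {
      males <- round(.MALE_FRAC[[g]] * nPerGroup)
      c(rep("M", males), rep("F", nPerGroup - males))
    }))
    age <- pmin(45, pmax(18, round(rnorm(n, 29, 6))))
    hr_max <- pmin(210, pmax(165, round(208 - 0.7 * age + rnorm(n, 0, 5))))
    ## Lactate-threshold HR sits well below the 90% HRmax boundary.
    frac_lt <- runif(n, 0.76, 0.84)
    hr_at_1p5 <- frac_lt * hr_max
    speed_at_1p5 <- pmax(9, rnorm(n, 12.5, 1.2))
    hr_slope <- rnorm(n, 6.5, 0.5)
    vo2_mean <- c(CG = 59.5, HSM = 60.3, HSM_LIT = 60.3)
    vo2_sd <- c(CG = 2.6, HSM = 6.9, HSM_LIT = 5.2)
    vo2 <- pmin(80, pmax(45, rnorm(n, vo2_mean[as.character(group)],
                                   vo2_sd[as.character(group)])))
    data.frame(
      participant_id = sprintf("P%02d", seq_len(n)),
      group = group, sex = sex, age = age, hr_max = hr_max,
      hr_at_1p5 = hr_at_1p5, hr_slope = hr_slope,
      speed_at_1p5 = speed_at_1p5, vo2max_t1 = vo2,
      stringsAsFactors = FALSE
    )
  })
}

#' Training schedule for one group
#'
#' Deterministic session plan over study days -9..21 (day 1 = first
#' intervention day).  Both intervention groups complete exactly ten HIIT
#' sessions within intervention days 1-7: single sessions on days 1 and 5,
#' morning and afternoon sessions on days 2, 3, 6 and 7, and a resting
#' day 4.  HSM_LIT adds a 30-min low-intensity session after every HIIT
#' session (+300 min in total).  Outside the intervention all groups
#' (and CG throughout) keep a regular 60-min session per day with one
#' weekly rest day.
#'
#' @param group one of `"CG"`, `"HSM"`, `"HSM_LIT"`.
#' @param days integer study days covered (default -9..21).
#' @return `data.frame` with columns `study_day`, `slot` (AM/PM), `kind`
#'   (HIIT/LIT/REGULAR), `planned_minutes`.
#' @export
#' @examples
#' sum(simulateSchedule("HSM")$kind == "HIIT")  # 10
simulateSchedule <- function(group, days = -9:21) {
  group <- match.arg(group, .GROUPS)
  hiit <- group %in% c("HSM", "HSM_LIT")
  regDays <- setdiff(days, .REST_DAYS)
  if (hiit) regDays <- setdiff(regDays, 1:7)
  out <- data.frame(study_day = regDays, slot = "AM", kind = "REGULAR",
                    planned_minutes = 60, stringsAsFactors = FALSE)
  if (hiit) {
    d1 <- intersect(c(1L, 5L), days)                 # single sessions
    d2 <- intersect(c(2L, 3L, 6L, 7L), days)         # AM + PM doubles
    hd <- c(d1, rep(d2, each = 2L))
    hs <- c(rep("AM", length(d1)), rep(c("AM", "PM"), length(d2)))
    hiitRows <- data.frame(study_day = hd, slot = hs, kind = "HIIT",
                           planned_minutes = 40, stringsAsFactors = FALSE)
    out <- rbind(out, hiitRows)
    if (group == "HSM_LIT") {
      lit <- hiitRows
      lit$kind <- "LIT"
      lit$planned_minutes <- 30
      out <- rbind(out, lit)
    }
  }
  out <- out[order(out$study_day, out$slot, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Individual REGULAR-session volume: a stable habitual-volume offset per
## participant plus day-to-day variation, both log-normal (SD 0.2 each).
## Drawn once over a fixed canonical day range (-30..30) per participant,
## so any requested day window reproduces identically.
.regularMinutes <- function(i, seed) {
  .withSeed(.subSeed(seed, 600000L + i), {
    b <- rnorm(1, 0, 0.2)
    e <- rnorm(61, 0, 0.2)
    m <- pmin(100, pmax(35, round(60 * exp(b + e))))
    names(m) <- as.character(-30:30)
    m
  })
}

#' Sessions for a whole cohort
#'
#' Expands the per-group [simulateSchedule()] over all participants and
#' assigns stable session identifiers.  HIIT (40 min) and LIT (30 min)
#' sessions are protocolized; REGULAR sessions get individual durations
#' (a habitual-volume offset per athlete plus day-to-day variation around
#' 60 min) - "usual training" differs between and within athletes.
#'
#' @param participants cohort from [simulateCohort()].
#' @param seed integer seed for the individual session volumes.
#' @param days study days covered.
#' @return `data.frame`: `session_id`, `participant_id`, `study_day`,
#'   `slot`, `kind`, `planned_minutes`.
#' @export
cohortSessions <- function(participants, seed = 1, days = -9:21) {
  if (min(days) < -30 || max(days) > 30)
    stop("days must lie within -30..30")
  out <- do.call(rbind, lapply(seq_len(nrow(participants)), function(i) {
    sch <- simulateSchedule(as.character(participants$group[i]), days)
    reg <- which(sch$kind == "REGULAR")
    mins <- .regularMinutes(i, seed)
    sch$planned_minutes[reg] <- mins[as.character(sch$study_day[reg])]
    sch$participant_id <- participants$participant_id[i]
    sch
  }))
  out$session_id <- sprintf("%s_d%03d_%s_%s", out$participant_id,
                            out$study_day + 100L, out$slot, out$kind)
  rownames(out) <- NULL
  out[, c("session_id", "participant_id", "study_day", "slot", "kind",
          "planned_minutes")]
}

#' Simulate a 1-Hz heart-rate trace for one session
#'
#' HIIT sessions are a 10-min low-intensity warm-up (ramping below the
#' lactate-anchored HR), five 4-min interval bouts at a configurable
#' fraction of individual HRmax (default 0.925, i.e. within the prescribed
#' 90-95% band) interspersed with four 2.5-min low-intensity recoveries -
#' 40 min in total.  LIT sessions are 30 min strictly below the lactate
#' threshold; REGULAR sessions are 60 min of mostly low-intensity running
#' with a 15-min moderate block.  Additive Gaussian noise is bounded at
#' 3 SD and HR is clamped to (40, hr_max].
#'
#' @param spec one session row (`study_day`, `slot`, `kind`,
#'   `planned_minutes`), e.g. from [simulateSchedule()].
#' @param participant one row of the cohort table.
#' @param seed integer seed.
#' @param noiseSd HR noise SD in bpm (default 2; 0 gives the exact target
#'   profile).
#' @param hiitFraction interval-bout target as fraction of HRmax,
#'   in `[0.90, 0.95]`.
#' @return `data.frame` with `t_s` (0-based elapsed seconds at 1-s
#'   cadence) and `hr` (bpm); `planned_minutes * 60` rows.
#' @export
#' @examples
#' p <- simulateCohort(2, seed = 1)[1, ]
#' spec <- data.frame(study_day = 1, slot = "AM", kind = "HIIT",
#'                    planned_minutes = 40)
#' nrow(simulateHRTrace(spec, p, seed = 1))  # 2400
simulateHRTrace <- function(spec, participant, seed = 1, noiseSd = 2,
                            hiitFraction = 0.925) {
  if (is.null(participant$hr_max) || !is.finite(participant$hr_max))
    stop("invalid participant: hr_max is missing")
  if (hiitFraction < 0.90 || hiitFraction > 0.95)
    stop("hiitFraction must lie in [0.90, 0.95]")
  kind <- as.character(spec$kind)
  if (!kind %in% c("HIIT", "LIT", "REGULAR"))
    stop("unknown session kind: ", kind)
  hr_max <- participant$hr_max
  hr_lt <- participant$hr_at_1p5
  target <- switch(kind,
    HIIT = {
      warm <- seq(0.70 * hr_lt, 0.97 * hr_lt, length.out = 600)
      bout <- rep(hiitFraction * hr_max, 240)
      rec <- rep(0.90 * hr_lt, 150)
      c(warm, bout, rec, bout, rec, bout, rec, bout, rec, bout)
    },
    LIT = rep(0.90 * hr_lt, 1800),
    REGULAR = {
      n <- spec$planned_minutes * 60
      n1 <- round(0.75 * n)  # 3/4 easy, 1/4 moderate
      c(rep(0.88 * hr_lt, n1), rep((hr_lt + 0.90 * hr_max) / 2, n - n1))
    }
  )
  n <- length(target)
  stopifnot(n == spec$planned_minutes * 60)
  hr <- .withSeed(seed, {
    noise <- rnorm(n, 0, noiseSd)
    if (noiseSd > 0)
      noise <- pmin(3 * noiseSd, pmax(-3 * noiseSd, noise))
    target + noise
  })
  if (kind == "LIT") hr <- pmin(hr, hr_lt - 5)  # strictly sub-threshold
  hr <- pmin(hr_max, pmax(41, hr))
  data.frame(t_s = seq_len(n) - 1L, hr = hr)
}

#' Simulate HR traces for many sessions
#'
#' @param sessions table from [cohortSessions()].
#' @param participants cohort table.
#' @param seed global seed; each session gets a derived sub-stream.
#' @param ... passed to [simulateHRTrace()].
#' @return long `data.frame`: `session_id`, `t_s`, `hr`.
#' @export
simulateTraces <- function(sessions, participants, seed = 1, ...) {
  pidx <- match(sessions$participant_id, participants$participant_id)
  hr <- lapply(seq_len(nrow(sessions)), function(i)
    simulateHRTrace(sessions[i, ], participants[pidx[i], ],
                    seed = .subSeed(seed, 1000L + i), ...)$hr)
  len <- lengths(hr)
  data.frame(session_id = rep(sessions$session_id, times = len),
             t_s = unlist(lapply(len, function(n) seq_len(n) - 1L)),
             hr = unlist(hr), stringsAsFactors = FALSE)
}

#' Simulate an incremental treadmill test
#'
#' Eight 3-min stages with speed increasing in 1.5 km/h steps; blood
#' lactate follows an exponential speed-lactate curve crossing
#' 1.5 mmol/L at the participant's threshold speed (with multiplicative
#' noise, kept non-decreasing), and HR is affine in speed with bounded
#' noise.
#'
#' @param participant one cohort row.
#' @param seed integer seed.
#' @param noiseSd HR noise SD (bpm).
#' @param lactateNoise log-scale lactate noise SD.
#' @param nStages number of stages (default 8).
#' @return `data.frame`: `stage`, `speed` (km/h), `lactate` (mmol/L),
#'   `hr` (bpm).
#' @export
simulateIncrementalTest <- function(participant, seed = 1, noiseSd = 1.5,
                                    lactateNoise = 0.05, nStages = 8) {
  v15 <- participant$speed_at_1p5
  speed <- (v15 - 5.05) + 1.5 * (seq_len(nStages) - 1L)
  .withSeed(seed, {
    la <- 1.5 * exp(0.38 * (speed - v15)) *
      exp(rnorm(nStages, 0, lactateNoise))
    la <- cummax(la)  # lactate never falls between stages
    intercept <- participant$hr_at_1p5 - participant$hr_slope * v15
    hr <- intercept + participant$hr_slope * speed + rnorm(nStages, 0, noiseSd)
    hr <- pmin(participant$hr_max, hr)
    data.frame(stage = seq_len(nStages), speed = speed,
               lactate = la, hr = hr)
  })
}

#' Incremental tests for a whole cohort
#'
#' @param participants cohort table.
#' @param seed global seed.
#' @param ... passed to [simulateIncrementalTest()].
#' @return long `data.frame` with `participant_id` plus the stage columns.
#' @export
simulatePETStages <- function(participants, seed = 1, ...) {
  out <- do.call(rbind, lapply(seq_len(nrow(participants)), function(i) {
    st <- simulateIncrementalTest(participants[i, ],
                                  seed = .subSeed(seed, 2000L + i), ...)
    st$participant_id <- participants$participant_id[i]
    st
  }))
  rownames(out) <- NULL
  out[, c("participant_id", "stage", "speed", "lactate", "hr")]
}
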