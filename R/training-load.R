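#' Fit an individualized three-zone model from incremental-test stages
#'
#' The speed at the 1.5 mmol/L lactate threshold is found by linear
#' interpolation between the two stages bracketing the threshold (the
#' speed-lactate relation is convex, so a global regression would bias
#' the crossing).  The corresponding heart rate is obtained from a simple
#' least-squares regression of HR on speed over all stages, evaluated at
#' the interpolated speed; the zone 2/3 boundary is 90% of HRmax.
#'
#' @param stages `data.frame` with columns `speed`, `lactate`, `hr`
#'   (one row per stage).
#' @param hrMax individual maximum heart rate (bpm).
#' @param weights zone weights, default `c(1, 2, 3)`.
#' @param lactateThreshold anchor concentration (mmol/L), default 1.5.
#' @return A [ZoneModel-class] object.
#' @export
#' @examples
#' st <- data.frame(speed = c(9, 10.5, 12, 13.5),
#'                  lactate = c(0.8, 1.1, 1.5, 2.4),
#'                  hr = 100 + 5 * c(9, 10.5, 12, 13.5))
#' fitZoneModel(st, hrMax = 190)  # boundary at HR 160
fitZoneModel <- function(stages, hrMax, weights = c(1, 2, 3),
                         lactateThreshold = 1.5) {
  need <- c("speed", "lactate", "hr")
  miss <- setdiff(need, colnames(stages))
  if (length(miss))
    stop("stages missing columns: ", paste(miss, collapse = ", "))
  if (nrow(stages) < 3) stop("need at least 3 stages")
  stages <- stages[order(stages$speed), , drop = FALSE]
  la <- stages$lactate
  idx <- which(la >= lactateThreshold)[1]
  if (is.na(idx))
    stop(sprintf(
      "threshold not bracketed: lactate never reaches %.2f mmol/L (max %.2f)",
      lactateThreshold, max(la)))
  if (idx == 1L)
    stop(sprintf(
      "threshold not bracketed: first-stage lactate %.2f already >= %.2f",
      la[1], lactateThreshold))
  v0 <- stages$speed[idx - 1L]; v1 <- stages$speed[idx]
  l0 <- la[idx - 1L]; l1 <- la[idx]
  vThr <- v0 + (lactateThreshold - l0) * (v1 - v0) / (l1 - l0)
  fit <- lm(hr ~ speed, data = stages)
  hrZ1Z2 <- unname(predict(fit, data.frame(speed = vThr)))
  hrZ2Z3 <- 0.90 * hrMax
  if (hrZ1Z2 >= hrZ2Z3)
    stop(sprintf(
      paste0("inconsistent zone model: lactate-anchored HR %.1f is not ",
             "below 90%% HRmax %.1f (HRmax %.0f, threshold speed %.2f)"),
      hrZ1Z2, hrZ2Z3, hrMax, vThr))
  new("ZoneModel", hrZ1Z2 = hrZ1Z2, hrZ2Z3 = hrZ2Z3, hrMax = hrMax,
      weights = weights, speedAt1p5 = vThr)
}

#' Fit zone models for every participant
#'
#' @param petStages long stage table from [simulatePETStages()].
#' @param participants cohort table (supplies `hr_max`).
#' @return named list of [ZoneModel-class] objects by `participant_id`.
#' @export
fitZoneModels <- function(petStages, participants) {
  ids <- participants$participant_id
  out <- lapply(seq_along(ids), function(i) {
    fitZoneModel(petStages[petStages$participant_id == ids[i], ,
                           drop = FALSE],
                 hrMax = participants$hr_max[i])
  })
  names(out) <- ids
  out
}

#' Time in zone and session TRIMP for one HR trace
#'
#' Each 1-s sample is assigned to exactly one zone with lower-inclusive
#' boundaries: HR below the lactate-anchored boundary is zone 1, HR at or
#' above 90% HRmax is zone 3, everything between is zone 2.  Minutes over
#' the three zones sum exactly to the trace duration.
#'
#' @param trace `data.frame` with an `hr` column (1-s cadence) or a
#'   numeric HR vector.
#' @param zm a [ZoneModel-class].
#' @return `data.frame` with `minutes_z1`, `minutes_z2`, `minutes_z3`,
#'   `trimp` (arbitrary units).
#' @export
#' @examples
#' zm <- new("ZoneModel", hrZ1Z2 = 150, hrZ2Z3 = 171, hrMax = 190)
#' zoneTimes(rep(140, 2400), zm)$trimp  # 40 min of zone 1 -> 40 AU
zoneTimes <- function(trace, zm) {
  hr <- if (is.data.frame(trace)) trace$hr else trace
  if (length(hr) == 0) stop("invalid input: empty HR trace")
  if (any(!is.finite(hr))) stop("invalid input: non-finite HR samples")
  z1 <- sum(hr < zm@hrZ1Z2) / 60
  z3 <- sum(hr >= zm@hrZ2Z3) / 60
  z2 <- length(hr) / 60 - z1 - z3
  mins <- c(z1, z2, z3)
  data.frame(minutes_z1 = z1, minutes_z2 = z2, minutes_z3 = z3,
             trimp = sessionTRIMP(mins, zm@weights))
}

#' Session TRIMP from zone minutes
#'
#' TRIMP = minutes in zone 1 x 1 + minutes in zone 2 x 2 + minutes in
#' zone 3 x 3 (weights configurable).
#'
#' @param minutes numeric length-3 vector of zone minutes.
#' @param weights zone weights, default `c(1, 2, 3)`.
#' @return TRIMP in arbitrary units.
#' @export
#' @examples
#' sessionTRIMP(c(20, 0, 20))  # 80
sessionTRIMP <- function(minutes, weights = c(1, 2, 3)) {
  if (length(minutes) != 3) stop("minutes must have length 3")
  if (any(minutes < 0)) stop("invalid input: negative zone minutes")
  sum(minutes * weights)
}

#' Exponentially weighted TRIMP series
#'
#' Standard exponentially weighted moving average over a contiguous daily
#' load series with decay `lambda = 2 / (N + 1)`:
#' `e_t = lambda * load_t + (1 - lambda) * e_{t-1}`, initialized with the
#' first recorded load (`init = "first-load"`, default) or with zero.
#' Days without training must already be present as zero loads.  The
#' non-convex variant printed as
#' `load_today * lambda + ((1 - lambda) + EWMA_yesterday)` is available
#' for audit via `variant = "as-printed"`; it grows without bound and is
#' not used anywhere else in the package.
#'
#' @param loads numeric vector of daily TRIMP values (contiguous days).
#' @param N time-decay constant in days (3, 5 or 7 in this protocol; any
#'   positive value is accepted).
#' @param init `"first-load"` or `"zero"`.
#' @param variant `"standard"` or `"as-printed"`.
#' @return numeric vector of expTRIMP values, same length as `loads`.
#' @export
#' @examples
#' expTRIMP(c(80, 0, 80), N = 7)  # 80, 60, 65
expTRIMP <- function(loads, N, init = c("first-load", "zero"),
                     variant = c("standard", "as-printed")) {
  if (length(loads) == 0) stop("invalid input: empty load series")
  if (any(!is.finite(loads))) stop("invalid input: non-finite loads")
  if (N <= 0) stop("N must be positive")
  init <- match.arg(init)
  variant <- match.arg(variant)
  lambda <- 2 / (N + 1)
  e <- numeric(length(loads))
  e[1] <- if (init == "first-load") loads[1] else lambda * loads[1]
  if (variant == "standard") {
    for (t in seq_along(loads)[-1])
      e[t] <- lambda * loads[t] + (1 - lambda) * e[t - 1]
  } else {
    for (t in seq_along(loads)[-1])
      e[t] <- lambda * loads[t] + (1 - lambda) + e[t - 1]
  }
  e
}

#' Zone times and TRIMP for every recorded session
#'
#' @param hrTraces long trace table (`session_id`, `t_s`, `hr`).
#' @param zoneModels named list from [fitZoneModels()].
#' @param sessions session table mapping `session_id` to
#'   `participant_id`, `study_day`, `kind`.
#' @return `data.frame`: one row per session with zone minutes and TRIMP.
#' @export
computeSessionLoads <- function(hrTraces, zoneModels, sessions) {
  hrBySession <- split(hrTraces$hr, hrTraces$session_id)
  sidx <- match(names(hrBySession), sessions$session_id)
  if (anyNA(sidx)) stop("traces contain unknown session ids")
  out <- do.call(rbind, lapply(seq_along(hrBySession), function(i) {
    pid <- sessions$participant_id[sidx[i]]
    zm <- zoneModels[[pid]]
    if (is.null(zm)) stop("no zone model for participant ", pid)
    zt <- zoneTimes(hrBySession[[i]], zm)
    cbind(data.frame(session_id = names(hrBySession)[i],
                     participant_id = pid,
                     study_day = sessions$study_day[sidx[i]],
                     kind = sessions$kind[sidx[i]],
                     stringsAsFactors = FALSE),
          zt)
  }))
  rownames(out) <- NULL
  out[order(out$participant_id, out$study_day, out$session_id), ]
}

#' Daily TRIMP totals and 3/5/7-day expTRIMP per participant
#'
#' Sessions are summed per calendar day; days without training enter the
#' series as zero load (they still decay the moving average), and the
#' EWMA runs over the full contiguous day range.
#'
#' @param sessionLoads table from [computeSessionLoads()], or any
#'   `data.frame` with `participant_id`, `study_day`, `trimp`.
#' @param days contiguous integer day range to cover (default -9..21).
#' @param N decay constants, default `c(3, 5, 7)`.
#' @param init,variant passed to [expTRIMP()].
#' @return `data.frame`: `participant_id`, `study_day`, `trimp`, and one
#'   `exp_trimp_<N>` column per horizon.
#' @export
dailyLoad <- function(sessionLoads, days = -9:21, N = c(3, 5, 7),
                      init = "first-load", variant = "standard") {
  if (!all(diff(days) == 1L)) stop("days must be contiguous")
  ids <- unique(sessionLoads$participant_id)
  out <- do.call(rbind, lapply(ids, function(pid) {
    s <- sessionLoads[sessionLoads$participant_id == pid, , drop = FALSE]
    daily <- vapply(days, function(d)
      sum(s$trimp[s$study_day == d]), numeric(1))
    res <- data.frame(participant_id = pid, study_day = days,
                      trimp = daily, stringsAsFactors = FALSE)
    for (n in N)
      res[[paste0("exp_trimp_", n)]] <-
        expTRIMP(daily, n, init = init, variant = variant)
    res
  }))
  rownames(out) <- NULL
  out
}

#' Planned (protocol-level) daily load per participant
#'
#' Daily TRIMP and expTRIMP implied by the session plan alone, without
#' simulating HR traces: HIIT sessions count 80 AU (10 warm-up + 20 zone-3
#' + 10 recovery minutes), LIT 30 AU, and REGULAR sessions 1.25 AU per
#' planned minute (3/4 zone 1, 1/4 zone 2).  A warm-up week of regular
#' training before the first requested day brings the EWMA to steady
#' state.  This is the latent load signal the biomarker and self-report
#' generators couple to, and a fast substitute for the trace pipeline.
#'
#' @param participants cohort table.
#' @param seed integer seed for the individual session volumes (must
#'   match the seed used for [cohortSessions()] to stay consistent with
#'   the trace pipeline).
#' @param days contiguous day range (default -9..21).
#' @param N decay constants, default `c(3, 5, 7)`.
#' @return `data.frame` like [dailyLoad()] output.
#' @export
plannedDailyLoad <- function(participants, seed = 1, days = -9:21,
                             N = c(3, 5, 7)) {
  if (!all(diff(days) == 1L)) stop("days must be contiguous")
  full <- (min(days) - 7L):max(days)
  ses <- cohortSessions(participants, seed = seed, days = full)
  ses$trimp <- ifelse(ses$kind == "REGULAR", 1.25 * ses$planned_minutes,
                      .PLANNED_TRIMP[ses$kind])
  out <- do.call(rbind, lapply(participants$participant_id, function(pid) {
    s <- ses[ses$participant_id == pid, , drop = FALSE]
    daily <- vapply(full, function(d)
      sum(s$trimp[s$study_day == d]), numeric(1))
    res <- data.frame(participant_id = pid, study_day = full,
                      trimp = daily, stringsAsFactors = FALSE)
    for (n in N)
      res[[paste0("exp_trimp_", n)]] <- expTRIMP(daily, n)
    res[res$study_day %in% days, , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}
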