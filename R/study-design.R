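#' @importFrom methods new validObject is callNextMethod slot
#' @importFrom stats rnorm runif lm predict coef sd median cor cor.test
#'   wilcox.test t.test anova aggregate quantile setNames
#' @importFrom utils write.csv read.csv head
NULL

## Canonical rest/blood-draw timepoints in study order.  "D4" is the resting
## day in the middle of the intervention week, "P1" the day after it ends.
.TP_LEVELS <- c("T0", "T1", "T2", "D4", "T3", "P1", "T4", "T5", "T6")

## Study-day grid for the timepoints.  Day 1 is the first intervention day;
## negative days are pre-intervention, days 8..21 post-intervention.
.TP_DAYS <- c(T0 = -9L, T1 = -1L, T2 = 2L, D4 = 4L, T3 = 7L, P1 = 8L,
              T4 = 10L, T5 = 14L, T6 = 21L)

.GROUPS <- c("CG", "HSM", "HSM_LIT")

.PHASES <- c("pre", "intervention", "post")

## Exercise-test timepoints at which VO2max is measured.
.VO2_TESTS <- c("T1", "T4", "T5", "T6")

## Carry-forward map: which measured VO2max value is attached to each
## blood-draw timepoint when correlating against the panel.
.VO2_CARRY <- c(T0 = "T1", T1 = "T1", T2 = "T1", D4 = "T1",
                T3 = "T4", P1 = "T4", T4 = "T4", T5 = "T5", T6 = "T6")

.SELF_REPORTS <- c("soreness", "pain", "wellbeing", "fatigue", "sleep")

#' Timepoint grid of the monitoring protocol
#'
#' Returns the rest/blood-draw timepoints of the four-week protocol together
#' with their study-day positions (day 1 = first day of the 7-day
#' intervention) and the phase each timepoint is summarized into for the
#' mixed-effects analysis.
#'
#' @return A `data.frame` with columns `timepoint`, `study_day`, `phase`.
#' @export
#' @examples
#' timepointGrid()
timepointGrid <- function() {
  data.frame(
    timepoint = factor(.TP_LEVELS, levels = .TP_LEVELS),
    study_day = unname(.TP_DAYS),
    phase = unname(phaseMap()[.TP_LEVELS]),
    stringsAsFactors = FALSE
  )
}

#' Phase map: timepoint to study phase
#'
#' Timepoints are summarized into pre-intervention (T0, T1), intervention
#' (T2, D4, T3, +1) and post-intervention (T4, T5, T6) phases for the
#' longitudinal mixed model.
#'
#' @return Named character vector mapping timepoint to phase.
#' @export
phaseMap <- function() {
  c(T0 = "pre", T1 = "pre",
    T2 = "intervention", D4 = "intervention", T3 = "intervention",
    P1 = "intervention",
    T4 = "post", T5 = "post", T6 = "post")
}

#' The 32-marker monitoring panel
#'
#' Reference description of the blood panel: 12 cytokines, creatine kinase
#' (muscle damage), urea (protein metabolism), ferritin and transferrin
#' (iron homeostasis), and 16 differential blood-count parameters.
#' Baselines are clinical reference mid-range values; the log-scale SDs
#' split total biological variability into a stable between-subject
#' component (`sigma_subject`) and day-to-day within-subject noise
#' (`sigma_within`), both on the natural-log scale.  `load_rho` is the
#' default coupling of the marker to the latent previous-day training load
#' used by the synthetic generator (marginal log-scale Pearson r).
#'
#' @return A `data.frame` with one row per marker: `marker`, `class`,
#'   `unit`, `baseline`, `sigma_subject`, `sigma_within`, `load_rho`.
#' @export
#' @examples
#' nrow(markerPanelInfo())  # 32
markerPanelInfo <- function() {
  cyt <- function(m, base) {
    data.frame(marker = m, class = "cytokine", unit = "pg/mL",
               baseline = base, sigma_subject = 0.45, sigma_within = 0.30,
               load_rho = 0, stringsAsFactors = FALSE)
  }
  cnt <- function(m, unit, base, sb, sw) {
    data.frame(marker = m, class = "blood_count", unit = unit,
               baseline = base, sigma_subject = sb, sigma_within = sw,
               load_rho = 0, stringsAsFactors = FALSE)
  }
  info <- rbind(
    cyt("IL-2", 2.5), cyt("IL-4", 2.0), cyt("IL-5", 2.2), cyt("IL-6", 3.0),
    cyt("IL-9", 2.8), cyt("IL-10", 2.4), cyt("IL-13", 2.6),
    cyt("IL-17A", 3.2), cyt("IL-17F", 4.0), cyt("IL-22", 5.0),
    cyt("IFN-g", 6.0), cyt("TNF-a", 8.0),
    data.frame(marker = "CK", class = "muscle_damage", unit = "U/L",
               baseline = 150, sigma_subject = 0.60, sigma_within = 0.30,
               load_rho = 0, stringsAsFactors = FALSE),
    data.frame(marker = "urea", class = "metabolism", unit = "mg/dL",
               baseline = 32, sigma_subject = 0.15, sigma_within = 0.12,
               load_rho = 0, stringsAsFactors = FALSE),
    data.frame(marker = "ferritin", class = "iron", unit = "ng/mL",
               baseline = 85, sigma_subject = 0.50, sigma_within = 0.15,
               load_rho = 0, stringsAsFactors = FALSE),
    data.frame(marker = "transferrin", class = "iron", unit = "mg/dL",
               baseline = 260, sigma_subject = 0.10, sigma_within = 0.06,
               load_rho = 0, stringsAsFactors = FALSE),
    cnt("LYM",   "10^3/uL", 2.1,  0.15, 0.10),
    cnt("GR",    "10^3/uL", 4.0,  0.15, 0.12),
    cnt("GR%",   "%",       60,   0.05, 0.05),
    cnt("WBC",   "10^3/uL", 6.5,  0.12, 0.10),
    cnt("MO%",   "%",       7.0,  0.12, 0.10),
    cnt("LYM%",  "%",       32,   0.07, 0.06),
    cnt("PLT",   "10^3/uL", 250,  0.10, 0.06),
    cnt("RBC",   "10^6/uL", 4.9,  0.06, 0.03),
    cnt("HGB",   "g/dL",    14.8, 0.05, 0.03),
    cnt("HCT",   "%",       44,   0.05, 0.03),
    cnt("RDWCV", "%",       13.2, 0.03, 0.015),
    cnt("PDW%",  "%",       13.0, 0.06, 0.04),
    cnt("MPV",   "fL",      10.5, 0.04, 0.02),
    cnt("MCH",   "pg",      30,   0.02, 0.01),
    cnt("MCHC",  "g/dL",    34,   0.015, 0.008),
    cnt("MCV",   "fL",      88,   0.02, 0.01)
  )
  rownames(info) <- NULL
  info
}

#' Names of the 32 panel markers
#' @return Character vector of the marker names in panel order.
#' @export
panelMarkers <- function() markerPanelInfo()$marker

## Derive a reproducible sub-stream seed from a global seed.  Kept below
## 2^31 - 1 so it is always a valid integer seed.
.subSeed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483629) * 48271 + as.double(k)
  as.integer(s %% 2147483629)
}

## Evaluate `expr` with a locally derived RNG seed, restoring the caller's
## RNG state afterwards so generators compose deterministically.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
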