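#' Percent change from baseline T0
#'
#' `100 * (value - value_T0) / value_T0` per participant and marker;
#' identically 0 at T0 by construction.
#'
#' @param panel a [BiomarkerPanel-class] with T0 present for every
#'   participant.
#' @return tidy `data.frame`: `participant_id`, `group`, `timepoint`,
#'   `study_day`, `phase`, `marker`, `pct`.
#' @export
percentChange <- function(panel) {
  a <- SummarizedExperiment::assay(panel, "concentration")
  cd <- SummarizedExperiment::colData(panel)
  t0 <- which(cd$timepoint == "T0")
  names(t0) <- cd$participant_id[t0]
  miss <- setdiff(unique(cd$participant_id), names(t0))
  if (length(miss))
    stop("undefined baseline: no T0 sample for ",
         paste(miss, collapse = ", "))
  base <- a[, t0[as.character(cd$participant_id)], drop = FALSE]
  pct <- 100 * (a - base) / base
  out <- data.frame(
    participant_id = rep(cd$participant_id, each = nrow(a)),
    group = rep(as.character(cd$group), each = nrow(a)),
    timepoint = rep(as.character(cd$timepoint), each = nrow(a)),
    study_day = rep(cd$study_day, each = nrow(a)),
    phase = rep(as.character(cd$phase), each = nrow(a)),
    marker = rep(rownames(a), times = ncol(a)),
    pct = as.vector(pct),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' SD noise threshold per marker
#'
#' The sample standard deviation of each marker over the pooled T0 and T1
#' values of all participants - the yardstick separating meaningful
#' change from measurement noise.
#'
#' @param panel a [BiomarkerPanel-class] with T0 and T1 present.
#' @return `data.frame`: `marker`, `sd_threshold`, `n`.
#' @export
sdThreshold <- function(panel) {
  cd <- SummarizedExperiment::colData(panel)
  keep <- cd$timepoint %in% c("T0", "T1")
  if (!any(cd$timepoint == "T0") || !any(cd$timepoint == "T1"))
    stop("both T0 and T1 must be present")
  a <- SummarizedExperiment::assay(panel, "concentration")[, keep,
                                                           drop = FALSE]
  thr <- apply(a, 1, function(v) {
    if (length(unique(v)) < 2) {
      warning("degenerate threshold: fewer than 2 distinct values; using 0")
      0
    } else sd(v)
  })
  data.frame(marker = rownames(a), sd_threshold = unname(thr),
             n = ncol(a), stringsAsFactors = FALSE)
}

#' Significance stars
#'
#' Star coding used throughout: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `****` p < 0.0001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings (empty when p >= 0.05 or NA).
#' @export
significanceStars <- function(p) {
  out <- rep("", length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[!is.na(p) & p < 0.0001] <- "****"
  out
}

## Fit the phase mixed model for a single marker's tidy slice.  The
## interaction contrasts are the treatment-coded group:phase coefficients
## (reference CG and pre), i.e. the difference-in-differences of each
## intervention group against CG relative to the pre phase, with
## Satterthwaite degrees of freedom.
.fitPhaseModel <- function(d) {
  if (sd(d$logv) < 1e-10)
    stop("degenerate variance: all log-concentrations identical")
  fit <- lmerTest::lmer(
    logv ~ group * phase + (1 | participant_id), data = d, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore"))
  an <- suppressMessages(stats::anova(fit))
  cf <- stats::coef(summary(fit))
  ia <- grep("^group.+:phase", rownames(cf))
  nm <- rownames(cf)[ia]
  ct <- data.frame(
    contrast = paste(sub("^group(.+):phase.+$", "\\1", nm), "- CG"),
    phase = sub("^group.+:phase(.+)$", "\\1", nm),
    estimate = cf[ia, "Estimate"], SE = cf[ia, "Std. Error"],
    df = cf[ia, "df"], p.value = cf[ia, "Pr(>|t|)"],
    stringsAsFactors = FALSE)
  list(anova = an, contrasts = ct)
}

#' Phase mixed-effects model on log concentrations
#'
#' Per marker, a restricted-maximum-likelihood linear mixed model of the
#' log concentration with fixed effects group, phase
#' (pre / intervention / post) and their interaction, and a random
#' intercept per participant.  The reported contrasts are the group-by-
#' phase interaction effects of each intervention group against CG,
#' relative to the pre phase (difference-in-differences, Satterthwaite
#' df, no multiplicity adjustment), star-coded at
#' 0.05 / 0.01 / 0.001 / 0.0001.  Markers whose fit fails are flagged
#' (`converged = FALSE`) with NA p-values and excluded from stars, never
#' dropped silently.
#'
#' @param panel a [BiomarkerPanel-class]; needs >= 2 participants per
#'   group.
#' @return list with `tests` (marker, effect, p_value - the group, phase
#'   and interaction F-tests) and `contrasts` (marker, contrast, phase,
#'   estimate, se, df, p_value, stars, converged).
#' @export
phaseMixedModel <- function(panel) {
  cd <- SummarizedExperiment::colData(panel)
  if (min(table(unique(data.frame(p = cd$participant_id,
                                  g = cd$group))$g)) < 2)
    stop("need at least 2 participants per group")
  a <- SummarizedExperiment::assay(panel, "concentration")
  tests <- list(); contrasts <- list(); failed <- character()
  for (m in rownames(a)) {
    d <- data.frame(logv = log(a[m, ]),
                    group = cd$group, phase = cd$phase,
                    participant_id = cd$participant_id)
    res <- tryCatch(.fitPhaseModel(d), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, m)
      warning("mixed model failed for ", m, ": ", conditionMessage(res))
      contrasts[[m]] <- data.frame(
        marker = m, contrast = NA_character_, phase = NA_character_,
        estimate = NA_real_, se = NA_real_, df = NA_real_,
        p_value = NA_real_, stars = "", converged = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    an <- res$anova
    tests[[m]] <- data.frame(
      marker = m, effect = rownames(an), p_value = an[["Pr(>F)"]],
      stringsAsFactors = FALSE)
    ct <- res$contrasts
    contrasts[[m]] <- data.frame(
      marker = m, contrast = as.character(ct$contrast),
      phase = as.character(ct$phase), estimate = ct$estimate,
      se = ct$SE, df = ct$df, p_value = ct$p.value,
      stars = significanceStars(ct$p.value), converged = TRUE,
      stringsAsFactors = FALSE)
  }
  if (length(failed) == nrow(a))
    stop("degenerate variance: no marker could be fit")
  out <- list(tests = do.call(rbind, tests),
              contrasts = do.call(rbind, contrasts))
  rownames(out$tests) <- rownames(out$contrasts) <- NULL
  out
}

## Per-day-normalized trapezoid of the difference-to-baseline series over
## one window of timepoints (study-day x axis).
.windowAUC <- function(value, day, normalize) {
  o <- order(day)
  value <- value[o]; day <- day[o]
  auc <- sum(diff(day) * (head(value, -1) + value[-1]) / 2)
  if (normalize) auc / (max(day) - min(day)) else auc
}

#' Chronic-change analysis: pre vs post AUC of difference to baseline
#'
#' For every participant and marker the series
#' `d(t) = value(t) - value(T0)` (or its percent form) is integrated by
#' the trapezoid rule over the study-day axis within the pre-intervention
#' window (T0-T1) and the post-intervention window (T5-T6), normalized
#' per day so windows of unequal length compare.  A paired test (Wilcoxon
#' signed-rank by default, robust at n = 10) compares pre vs post AUC per
#' group, and - because both intervention groups respond alike - for the
#' pooled HSM and HSM_LIT participants.  The percent chronic change is
#' `100 * (mean AUC_post - mean AUC_pre) / mean baseline`.
#'
#' @param panel a [BiomarkerPanel-class].
#' @param windowPre,windowPost character timepoint windows.
#' @param integrand `"difference"` (raw difference to baseline, default)
#'   or `"percent"` (percent difference).
#' @param normalize divide each window AUC by its length in days
#'   (default TRUE; FALSE gives the plain trapezoid).
#' @param pairedTest `"wilcoxon"` or `"t"`.
#' @param pool also analyze pooled HSM + HSM_LIT (as group
#'   `"HSM_POOLED"`).
#' @return list with `byGroup` (marker, group, n, auc_pre, auc_post,
#'   delta_auc, p_value, stars, pct_change), `byParticipant` (per
#'   participant AUCs), and `excluded` (participants dropped for missing
#'   timepoints).
#' @export
chronicAUC <- function(panel, windowPre = c("T0", "T1"),
                       windowPost = c("T5", "T6"),
                       integrand = c("difference", "percent"),
                       normalize = TRUE,
                       pairedTest = c("wilcoxon", "t"),
                       pool = TRUE) {
  integrand <- match.arg(integrand)
  pairedTest <- match.arg(pairedTest)
  a <- SummarizedExperiment::assay(panel, "concentration")
  cd <- SummarizedExperiment::colData(panel)
  needTp <- unique(c("T0", windowPre, windowPost))
  ids <- unique(cd$participant_id)
  have <- vapply(ids, function(p)
    all(needTp %in% cd$timepoint[cd$participant_id == p]), logical(1))
  excluded <- ids[!have]
  if (length(excluded))
    message(length(excluded),
            " participant(s) excluded for missing timepoints: ",
            paste(excluded, collapse = ", "))
  ids <- ids[have]
  days <- .TP_DAYS
  byP <- do.call(rbind, lapply(ids, function(p) {
    sel <- cd$participant_id == p
    tp <- as.character(cd$timepoint[sel])
    v <- a[, sel, drop = FALSE]
    v0 <- v[, tp == "T0"]
    d <- if (integrand == "difference") v - v0 else 100 * (v - v0) / v0
    pre <- apply(d[, match(windowPre, tp), drop = FALSE], 1, .windowAUC,
                 day = days[windowPre], normalize = normalize)
    post <- apply(d[, match(windowPost, tp), drop = FALSE], 1, .windowAUC,
                  day = days[windowPost], normalize = normalize)
    data.frame(participant_id = p,
               group = as.character(cd$group[sel][1]),
               marker = rownames(a), auc_pre = pre, auc_post = post,
               delta_auc = pre - post, baseline = v0,
               stringsAsFactors = FALSE)
  }))
  rownames(byP) <- NULL
  groups <- lapply(.GROUPS, function(g) byP[byP$group == g, , drop = FALSE])
  names(groups) <- .GROUPS
  if (pool)
    groups$HSM_POOLED <- byP[byP$group %in% c("HSM", "HSM_LIT"), ,
                             drop = FALSE]
  byG <- do.call(rbind, lapply(names(groups), function(g) {
    gd <- groups[[g]]
    do.call(rbind, lapply(unique(gd$marker), function(m) {
      s <- gd[gd$marker == m, , drop = FALSE]
      p <- if (nrow(s) >= 2 && sd(s$auc_pre - s$auc_post) > 0) {
        if (pairedTest == "wilcoxon")
          suppressWarnings(wilcox.test(s$auc_pre, s$auc_post,
                                       paired = TRUE))$p.value
        else t.test(s$auc_pre, s$auc_post, paired = TRUE)$p.value
      } else NA_real_
      data.frame(marker = m, group = g, n = nrow(s),
                 auc_pre = mean(s$auc_pre), auc_post = mean(s$auc_post),
                 delta_auc = mean(s$delta_auc), p_value = p,
                 stars = significanceStars(p),
                 pct_change = 100 * (mean(s$auc_post) - mean(s$auc_pre)) /
                   mean(s$baseline),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(byG) <- NULL
  list(byGroup = byG, byParticipant = byP, excluded = excluded)
}

#' Pool groups and recompute the chronic-change test
#'
#' Recomputes the paired pre/post AUC analysis on the concatenated
#' participants of disjoint groups (never by averaging per-group
#' p-values).
#'
#' @param byParticipant the `byParticipant` table from [chronicAUC()].
#' @param groups character vector (length >= 2) of disjoint groups.
#' @param pairedTest `"wilcoxon"` or `"t"`.
#' @return `data.frame` like the `byGroup` table, one row per marker.
#' @export
poolGroups <- function(byParticipant, groups = c("HSM", "HSM_LIT"),
                       pairedTest = c("wilcoxon", "t")) {
  pairedTest <- match.arg(pairedTest)
  if (anyDuplicated(groups))
    stop("invalid argument: groups to pool must be disjoint")
  if (!all(groups %in% byParticipant$group))
    stop("unknown group(s): ",
         paste(setdiff(groups, byParticipant$group), collapse = ", "))
  gd <- byParticipant[byParticipant$group %in% groups, , drop = FALSE]
  out <- do.call(rbind, lapply(unique(gd$marker), function(m) {
    s <- gd[gd$marker == m, , drop = FALSE]
    p <- if (pairedTest == "wilcoxon")
      suppressWarnings(wilcox.test(s$auc_pre, s$auc_post,
                                   paired = TRUE))$p.value
    else t.test(s$auc_pre, s$auc_post, paired = TRUE)$p.value
    data.frame(marker = m, group = paste(groups, collapse = "+"),
               n = nrow(s), auc_pre = mean(s$auc_pre),
               auc_post = mean(s$auc_post), delta_auc = mean(s$delta_auc),
               p_value = p, stars = significanceStars(p),
               pct_change = 100 * (mean(s$auc_post) - mean(s$auc_pre)) /
                 mean(s$baseline),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Between-group test on the per-participant delta AUC
#'
#' Mann-Whitney (default) comparison of `delta_auc = AUC_pre - AUC_post`
#' between two groups for one marker.
#'
#' @param chronic result of [chronicAUC()].
#' @param marker marker name.
#' @param groups character length-2.
#' @param test `"wilcoxon"` or `"t"`.
#' @return list with `statistic`, `p_value`, group medians.
#' @export
deltaAucTest <- function(chronic, marker, groups = c("HSM_LIT", "CG"),
                         test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (length(groups) != 2 || groups[1] == groups[2])
    stop("need two distinct groups")
  byP <- chronic$byParticipant
  x <- byP$delta_auc[byP$marker == marker & byP$group == groups[1]]
  y <- byP$delta_auc[byP$marker == marker & byP$group == groups[2]]
  if (!length(x) || !length(y)) stop("no data for marker ", marker)
  ht <- if (test == "wilcoxon") suppressWarnings(wilcox.test(x, y))
        else t.test(x, y)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       median_1 = median(x), median_2 = median(y))
}
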