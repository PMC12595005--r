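#' Select the ratio candidates from the correlation matrix
#'
#' Picks the marker with the highest positive and the marker with the
#' most negative significant Pearson r against the target (7-day expTRIMP
#' by default) - the two components of the combined log-ratio biomarker.
#' Ties are broken by marker name for determinism.
#'
#' @param object a [CorrelationMatrix-class].
#' @param target target variable (default `"exp_trimp_7"`).
#' @return list: `positive`, `negative` (marker names), `r_positive`,
#'   `r_negative`.
#' @export
selectRatioCandidates <- function(object, target = "exp_trimp_7") {
  stopifnot(is(object, "CorrelationMatrix"))
  if (!target %in% rownames(object@r))
    stop("invalid argument: target '", target, "' not in matrix")
  mk <- setdiff(object@markers, target)
  r <- object@r[mk, target]
  p <- object@p[mk, target]
  sig <- !is.na(p) & p < object@alpha
  posOk <- sig & r > 0
  negOk <- sig & r < 0
  if (!any(posOk))
    stop("selection failed: no significant positive marker correlation ",
         "with ", target)
  if (!any(negOk))
    stop("selection failed: no significant negative marker correlation ",
         "with ", target)
  ord <- order(-r, mk)
  pos <- mk[ord][posOk[ord]][1]
  ordNeg <- order(r, mk)
  neg <- mk[ordNeg][negOk[ordNeg]][1]
  list(positive = pos, negative = neg,
       r_positive = unname(r[pos]), r_negative = unname(r[neg]))
}

#' Per-observation combined log-ratio series
#'
#' The combined biomarker is the quotient of natural logs,
#' `log(numerator) / log(denominator)` (the "log-X-to-log-Y" reading);
#' the difference-of-logs variant `log(numerator / denominator)` is
#' available via `form = "log-difference"`.  Marker values must be in
#' their native units, well above 1, so both logs are safely positive -
#' otherwise a unit-guard error asks for unit normalization rather than
#' silently shifting values.
#'
#' @param panel a [BiomarkerPanel-class].
#' @param numerator,denominator marker names.
#' @param form `"log-quotient"` (default) or `"log-difference"`.
#' @return `data.frame`: `participant_id`, `group`, `timepoint`,
#'   `study_day`, `ratio`.
#' @export
ratioSeries <- function(panel, numerator, denominator,
                        form = c("log-quotient", "log-difference")) {
  form <- match.arg(form)
  a <- SummarizedExperiment::assay(panel, "concentration")
  for (m in c(numerator, denominator))
    if (!m %in% rownames(a)) stop("marker not in panel: ", m)
  num <- a[numerator, ]
  den <- a[denominator, ]
  if (form == "log-quotient" && any(c(num, den) <= 1))
    stop("unit guard: marker values <= 1 in native units make log(value) ",
         "<= 0; normalize units so concentrations are well above 1 ",
         "before forming the log-quotient")
  ratio <- if (form == "log-quotient") log(num) / log(den)
           else log(num / den)
  if (any(!is.finite(ratio))) stop("non-finite ratio values")
  cd <- SummarizedExperiment::colData(panel)
  out <- data.frame(participant_id = cd$participant_id,
                    group = as.character(cd$group),
                    timepoint = as.character(cd$timepoint),
                    study_day = cd$study_day,
                    ratio = unname(ratio),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate the combined biomarker against load and soreness
#'
#' Pearson correlation of the ratio series with the previous-day 7-day
#' expTRIMP and the muscle-soreness score over the aligned table, with an
#' improvement report comparing `|r|` of the ratio against each
#' component's `|r|` (components taken as absolute values, as in the
#' correlation matrix).
#'
#' @param series ratio table from [ratioSeries()].
#' @param aligned table from [buildAlignedTable()]; must contain the
#'   component markers, `exp_trimp_7` and `soreness`.
#' @param components character length-2, the numerator and denominator
#'   markers.
#' @return list: `r_load`, `p_load`, `r_soreness`, `p_soreness`, `n`,
#'   `components` (per-component r against both targets),
#'   `improved_load`, `improved_soreness`.
#' @export
evaluateRatio <- function(series, aligned,
                          components = attr(series, "components")) {
  key <- paste(aligned$participant_id, aligned$timepoint)
  si <- match(key, paste(series$participant_id, series$timepoint))
  d <- aligned
  d$ratio <- series$ratio[si]
  d <- d[is.finite(d$ratio) & is.finite(d$exp_trimp_7) &
           is.finite(d$soreness), , drop = FALSE]
  if (nrow(d) < 3)
    stop("insufficient data: need at least 3 paired observations")
  ctL <- cor.test(d$ratio, d$exp_trimp_7)
  ctS <- cor.test(d$ratio, d$soreness)
  comp <- NULL
  if (!is.null(components)) {
    miss <- setdiff(components, colnames(d))
    if (length(miss))
      stop("aligned table lacks component(s): ",
           paste(miss, collapse = ", "))
    comp <- do.call(rbind, lapply(components, function(m)
      data.frame(marker = m,
                 r_load = unname(cor(d[[m]], d$exp_trimp_7)),
                 r_soreness = unname(cor(d[[m]], d$soreness)),
                 stringsAsFactors = FALSE)))
  }
  out <- list(r_load = unname(ctL$estimate), p_load = ctL$p.value,
              r_soreness = unname(ctS$estimate), p_soreness = ctS$p.value,
              n = nrow(d), components = comp)
  if (!is.null(comp)) {
    out$improved_load <- abs(out$r_load) >= max(abs(comp$r_load))
    out$improved_soreness <- abs(out$r_soreness) >=
      max(abs(comp$r_soreness))
  }
  out
}

#' One-call combined-biomarker analysis
#'
#' Selects the extreme positively and negatively load-correlated markers
#' from the matrix, forms the log-ratio series and evaluates it -
#' the complete exploratory combined-biomarker procedure.
#'
#' @param panel a [BiomarkerPanel-class].
#' @param object a [CorrelationMatrix-class] over the aligned table.
#' @param aligned the aligned table the matrix was computed from.
#' @param target selection target (default `"exp_trimp_7"`).
#' @param form passed to [ratioSeries()].
#' @param normalizeUnits if a selected marker has observations at or
#'   below 1 (so its log would change sign), rescale that marker by the
#'   smallest power of 10 making all values exceed 1 - the unit
#'   normalization the guard in [ratioSeries()] asks for.  The applied
#'   factors are reported in the result.  Pearson correlations are
#'   unaffected for the components but the quotient-of-logs does depend
#'   on the unit choice, which is why the factors are surfaced rather
#'   than applied silently.
#' @return list: `spec` (selection, including any `unit_factor_num` /
#'   `unit_factor_den`), `series`, `evaluation`.
#' @export
combinedBiomarker <- function(panel, object, aligned,
                              target = "exp_trimp_7",
                              form = "log-quotient",
                              normalizeUnits = TRUE) {
  spec <- selectRatioCandidates(object, target = target)
  spec$unit_factor_num <- 1
  spec$unit_factor_den <- 1
  if (normalizeUnits && form == "log-quotient") {
    a <- SummarizedExperiment::assay(panel, "concentration")
    lf <- longForm(panel)
    rescale <- function(m) {
      v <- a[m, ]
      if (all(v > 1)) return(1)
      fac <- 10^ceiling(-log10(min(v)) + 1e-9)
      if (min(v) * fac <= 1) fac <- fac * 10
      fac
    }
    fn <- rescale(spec$positive)
    fd <- rescale(spec$negative)
    if (fn > 1 || fd > 1) {
      lf$value[lf$marker == spec$positive] <-
        lf$value[lf$marker == spec$positive] * fn
      lf$value[lf$marker == spec$negative] <-
        lf$value[lf$marker == spec$negative] * fd
      panel <- BiomarkerPanel(lf)
      spec$unit_factor_num <- fn
      spec$unit_factor_den <- fd
      message("unit normalization applied: ", spec$positive, " x", fn,
              ", ", spec$negative, " x", fd)
    }
  }
  series <- ratioSeries(panel, spec$positive, spec$negative, form = form)
  attr(series, "components") <- c(spec$positive, spec$negative)
  evaluation <- evaluateRatio(series, aligned)
  list(spec = spec, series = series, evaluation = evaluation)
}
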