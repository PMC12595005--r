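#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ZoneModel: individualized three-zone heart-rate model
#'
#' Zone 1/2 boundary is the heart rate at the 1.5 mmol/L blood-lactate
#' threshold (from the incremental test, via linear regression of HR on
#' speed); the zone 2/3 boundary is 90% of the individual maximum heart
#' rate.  Zone weights default to (1, 2, 3).
#'
#' @slot hrZ1Z2 numeric, HR (bpm) separating zone 1 from zone 2.
#' @slot hrZ2Z3 numeric, HR (bpm) separating zone 2 from zone 3.
#' @slot hrMax numeric, individual maximum HR (bpm).
#' @slot weights numeric length-3 zone weights.
#' @slot speedAt1p5 numeric, treadmill speed (km/h) at 1.5 mmol/L lactate.
#' @export
setClass("ZoneModel",
  representation(hrZ1Z2 = "numeric", hrZ2Z3 = "numeric", hrMax = "numeric",
                 weights = "numeric", speedAt1p5 = "numeric"),
  prototype(weights = c(1, 2, 3), speedAt1p5 = NA_real_)
)

setValidity("ZoneModel", function(object) {
  msg <- character()
  if (length(object@weights) != 3L)
    msg <- c(msg, "weights must have length 3")
  if (!is.finite(object@hrZ1Z2) || !is.finite(object@hrZ2Z3))
    msg <- c(msg, "zone boundaries must be finite")
  else {
    if (object@hrZ1Z2 >= object@hrZ2Z3)
      msg <- c(msg, sprintf(
        "inconsistent zone model: hrZ1Z2 (%.1f) must be below hrZ2Z3 (%.1f)",
        object@hrZ1Z2, object@hrZ2Z3))
    if (is.finite(object@hrMax) && object@hrZ2Z3 > object@hrMax + 1e-8)
      msg <- c(msg, "hrZ2Z3 must not exceed hrMax")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ZoneModel-class show method
#' @param object a `ZoneModel`
#' @export
setMethod("show", "ZoneModel", function(object) {
  cat("ZoneModel\n")
  cat(sprintf("  zone 1: HR < %.1f bpm (1.5 mmol/L lactate anchor)\n",
              object@hrZ1Z2))
  cat(sprintf("  zone 2: %.1f <= HR < %.1f bpm (90%% HRmax)\n",
              object@hrZ1Z2, object@hrZ2Z3))
  cat(sprintf("  zone 3: HR >= %.1f bpm  (HRmax %.0f)\n",
              object@hrZ2Z3, object@hrMax))
  cat(sprintf("  weights: (%s)\n", paste(object@weights, collapse = ", ")))
})

#' BiomarkerPanel: longitudinal 32-marker panel container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with markers as rows and
#' participant-by-timepoint samples as columns.  The single assay
#' `"concentration"` holds strictly positive marker values in native units;
#' `colData` carries `participant_id`, `group`, `timepoint`, `study_day`
#' and `phase`; `rowData` carries the marker class and unit.
#'
#' @export
setClass("BiomarkerPanel", contains = "SummarizedExperiment")

setValidity("BiomarkerPanel", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("participant_id", "group", "timepoint", "study_day", "phase")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData missing:", paste(miss, collapse = ", ")))
  if (!"concentration" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'concentration' is required")
  else {
    a <- SummarizedExperiment::assay(object, "concentration")
    if (any(!is.finite(a)) || any(a <= 0))
      msg <- c(msg, "all concentrations must be finite and > 0")
  }
  if (!length(miss)) {
    key <- paste(cd$participant_id, cd$timepoint)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate participant x timepoint samples")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BiomarkerPanel-class show method
#' @param object a `BiomarkerPanel`
#' @export
setMethod("show", "BiomarkerPanel", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("BiomarkerPanel: %d markers x %d samples (%d participants, %d timepoints)\n",
              nrow(object), ncol(object),
              length(unique(cd$participant_id)),
              length(unique(cd$timepoint))))
  callNextMethod()
})

#' CorrelationMatrix: pairwise Pearson correlations with significance mask
#'
#' Symmetric matrices of pairwise-complete Pearson r, two-sided p-values
#' and pair counts over the aligned monitoring table, with the significance
#' threshold used to gate rankings and networks.
#'
#' @slot r numeric matrix of correlations (unit diagonal).
#' @slot p numeric matrix of two-sided p-values (NA on the diagonal).
#' @slot n integer matrix of complete-pair counts.
#' @slot alpha numeric significance threshold (default 0.05).
#' @slot markers character, which variables are panel markers.
#' @export
setClass("CorrelationMatrix",
  representation(r = "matrix", p = "matrix", n = "matrix",
                 alpha = "numeric", markers = "character"))

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  d <- dim(object@r)
  if (!identical(d, dim(object@p)) || !identical(d, dim(object@n)))
    msg <- c(msg, "r, p, n must have identical dimensions")
  if (d[1] != d[2]) msg <- c(msg, "matrices must be square")
  else {
    if (max(abs(object@r - t(object@r)), na.rm = TRUE) > 1e-12)
      msg <- c(msg, "r must be symmetric")
    if (max(abs(diag(object@r) - 1), na.rm = TRUE) > 1e-12)
      msg <- c(msg, "diagonal of r must be 1")
    rr <- object@r[is.finite(object@r)]
    if (length(rr) && (min(rr) < -1 - 1e-12 || max(rr) > 1 + 1e-12))
      msg <- c(msg, "r must lie in [-1, 1]")
  }
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn CorrelationMatrix-class show method
#' @param object a `CorrelationMatrix`
#' @export
setMethod("show", "CorrelationMatrix", function(object) {
  ns <- sum(significantPairs(object)$significant)
  cat(sprintf("CorrelationMatrix: %d variables, %d significant pairs (p < %g)\n",
              nrow(object@r), ns, object@alpha))
})

#' Accessors for CorrelationMatrix
#'
#' `corValues()`, `corPValues()` and `corCounts()` return the r, p and n
#' matrices; `significantPairs()` returns the tidy upper-triangle table.
#'
#' @param object a `CorrelationMatrix`
#' @return matrices, or a `data.frame` for `significantPairs()`.
#' @export
setGeneric("corValues", function(object) standardGeneric("corValues"))
#' @rdname corValues
#' @export
setMethod("corValues", "CorrelationMatrix", function(object) object@r)

#' @rdname corValues
#' @export
setGeneric("corPValues", function(object) standardGeneric("corPValues"))
#' @rdname corValues
#' @export
setMethod("corPValues", "CorrelationMatrix", function(object) object@p)

#' @rdname corValues
#' @export
setGeneric("corCounts", function(object) standardGeneric("corCounts"))
#' @rdname corValues
#' @export
setMethod("corCounts", "CorrelationMatrix", function(object) object@n)

#' Marker names of a panel
#'
#' @param object a `BiomarkerPanel`
#' @return character vector of marker names (row names of the panel).
#' @export
setGeneric("markerNames", function(object) standardGeneric("markerNames"))
#' @rdname markerNames
#' @export
setMethod("markerNames", "BiomarkerPanel", function(object) rownames(object))

#' Tidy long form of a panel
#'
#' One row per (participant, timepoint, marker) with the concentration in
#' native units - the exchange format written to `biomarkers.csv`.
#'
#' @param object a `BiomarkerPanel`
#' @return `data.frame` with columns `participant_id`, `group`,
#'   `timepoint`, `study_day`, `phase`, `marker`, `unit`, `value`.
#' @export
setGeneric("longForm", function(object) standardGeneric("longForm"))
#' @rdname longForm
#' @export
setMethod("longForm", "BiomarkerPanel", function(object) {
  a <- SummarizedExperiment::assay(object, "concentration")
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  rd <- as.data.frame(SummarizedExperiment::rowData(object))
  out <- data.frame(
    participant_id = rep(cd$participant_id, each = nrow(a)),
    group = rep(as.character(cd$group), each = nrow(a)),
    timepoint = rep(as.character(cd$timepoint), each = nrow(a)),
    study_day = rep(cd$study_day, each = nrow(a)),
    phase = rep(as.character(cd$phase), each = nrow(a)),
    marker = rep(rownames(a), times = ncol(a)),
    unit = rep(rd$unit, times = ncol(a)),
    value = as.vector(a),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
})

#' Construct a BiomarkerPanel from a tidy long table
#'
#' @param long `data.frame` with columns `participant_id`, `group`,
#'   `timepoint`, `study_day`, `marker`, `value` and optionally `unit`.
#' @return a validated [BiomarkerPanel-class] object.
#' @export
#' @examples
#' study <- simulateStudy(nPerGroup = 2, seed = 1, traces = FALSE)
#' panel <- BiomarkerPanel(longForm(study$panel))
BiomarkerPanel <- function(long) {
  need <- c("participant_id", "group", "timepoint", "study_day",
            "marker", "value")
  miss <- setdiff(need, colnames(long))
  if (length(miss))
    stop("long table missing columns: ", paste(miss, collapse = ", "))
  long$timepoint <- as.character(long$timepoint)
  markers <- unique(long$marker)
  samp <- unique(long[, c("participant_id", "group", "timepoint",
                          "study_day")])
  samp <- samp[order(samp$participant_id,
                     match(samp$timepoint, .TP_LEVELS)), , drop = FALSE]
  sid <- paste(samp$participant_id, samp$timepoint, sep = ".")
  a <- matrix(NA_real_, nrow = length(markers), ncol = nrow(samp),
              dimnames = list(markers, sid))
  idx <- cbind(match(long$marker, markers),
               match(paste(long$participant_id, long$timepoint, sep = "."),
                     sid))
  a[idx] <- long$value
  if (anyNA(a))
    stop("long table does not cover every participant x timepoint x marker")
  info <- markerPanelInfo()
  unit <- if ("unit" %in% colnames(long))
    long$unit[match(markers, long$marker)]
  else info$unit[match(markers, info$marker)]
  cls <- info$class[match(markers, info$marker)]
  cd <- S4Vectors::DataFrame(
    participant_id = samp$participant_id,
    group = factor(samp$group, levels = .GROUPS),
    timepoint = factor(samp$timepoint, levels = .TP_LEVELS),
    study_day = samp$study_day,
    phase = factor(unname(phaseMap()[samp$timepoint]), levels = .PHASES),
    row.names = sid
  )
  rd <- S4Vectors::DataFrame(marker = markers, class = cls, unit = unit,
                             row.names = markers)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(concentration = a), colData = cd, rowData = rd)
  new("BiomarkerPanel", se)
}
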