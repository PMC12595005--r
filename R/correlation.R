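#' Build the aligned monitoring table
#'
#' One row per participant and blood-draw timepoint (T0 excluded: no
#' previous-day load is defined before the observation window), holding
#' the absolute marker values, the 3/5/7-day expTRIMP of the day *before*
#' the draw, the same-day self-report scores, and VO2max carried forward
#' from the most recent exercise test (T1 covers T1, T2 and day 4; T4
#' covers T3, +1 and T4; T5 and T6 cover themselves).
#'
#' @param panel a [BiomarkerPanel-class].
#' @param dailyLoad per-participant daily-load table from [dailyLoad()]
#'   or [plannedDailyLoad()] (needs `exp_trimp_3/5/7`).
#' @param selfReports table from [simulateSelfReports()].
#' @param vo2max table from [simulateVO2max()].
#' @return `data.frame` with id columns (`participant_id`, `group`,
#'   `timepoint`, `study_day`), one column per marker, `exp_trimp_3/5/7`,
#'   the five self-report scores and `vo2max`.  Rows lacking the
#'   previous-day load are dropped with a message.
#' @export
buildAlignedTable <- function(panel, dailyLoad, selfReports, vo2max) {
  cd <- SummarizedExperiment::colData(panel)
  a <- SummarizedExperiment::assay(panel, "concentration")
  keep <- cd$timepoint != "T0"
  cd <- cd[keep, , drop = FALSE]
  a <- a[, keep, drop = FALSE]
  out <- data.frame(participant_id = cd$participant_id,
                    group = as.character(cd$group),
                    timepoint = as.character(cd$timepoint),
                    study_day = cd$study_day,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (m in rownames(a)) out[[m]] <- a[m, ]
  ## previous-day expTRIMP
  loadKey <- paste(dailyLoad$participant_id, dailyLoad$study_day)
  li <- match(paste(out$participant_id, out$study_day - 1L), loadKey)
  for (col in c("exp_trimp_3", "exp_trimp_5", "exp_trimp_7")) {
    if (!col %in% colnames(dailyLoad))
      stop("dailyLoad lacks column ", col)
    out[[col]] <- dailyLoad[[col]][li]
  }
  dropped <- is.na(li)
  if (any(dropped))
    message(sum(dropped), " row(s) dropped: no previous-day load")
  out <- out[!dropped, , drop = FALSE]
  ## same-day self-reports
  srKey <- paste(selfReports$participant_id, selfReports$study_day)
  si <- match(paste(out$participant_id, out$study_day), srKey)
  for (col in .SELF_REPORTS) out[[col]] <- selfReports[[col]][si]
  ## VO2max carry-forward (total and deterministic over the 8 timepoints)
  vKey <- paste(vo2max$participant_id, vo2max$timepoint)
  vi <- match(paste(out$participant_id, .VO2_CARRY[out$timepoint]), vKey)
  out$vo2max <- vo2max$vo2max[vi]
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation matrix with significance mask
#'
#' Pairwise-complete Pearson correlations with two-sided p-values over
#' the aligned table, pooling all timepoints and participants (repeated
#' measures enter as independent rows, as in the aggregate analysis; a
#' per-participant-mean sensitivity mode is available).  Variables with
#' zero variance get NA correlations and a warning - they are flagged,
#' not dropped.
#'
#' @param aligned table from [buildAlignedTable()].
#' @param vars variables to correlate; default: every non-id column.
#' @param alpha significance threshold for the mask (default 0.05).
#' @param scale `"raw"` (absolute values, default) or `"log"`
#'   (log-transform the marker columns first).
#' @param collapse `"none"` (default) or `"participant"` (correlate
#'   per-participant means - repeated-measures sensitivity mode).
#' @param minPairs minimum complete pairs required per correlation.
#' @return a [CorrelationMatrix-class].
#' @export
pearsonMatrix <- function(aligned, vars = NULL, alpha = 0.05,
                          scale = c("raw", "log"),
                          collapse = c("none", "participant"),
                          minPairs = 3) {
  scale <- match.arg(scale)
  collapse <- match.arg(collapse)
  idCols <- c("participant_id", "group", "timepoint", "study_day")
  if (is.null(vars)) vars <- setdiff(colnames(aligned), idCols)
  miss <- setdiff(vars, colnames(aligned))
  if (length(miss))
    stop("unknown variable(s): ", paste(miss, collapse = ", "))
  x <- aligned[, vars, drop = FALSE]
  markers <- intersect(vars, panelMarkers())
  if (scale == "log") {
    if (any(x[, markers] <= 0, na.rm = TRUE))
      stop("log scale requires positive marker values")
    x[, markers] <- log(x[, markers])
  }
  if (collapse == "participant") {
    x <- aggregate(x, by = list(pid = aligned$participant_id), mean,
                   na.rm = TRUE)
    x$pid <- NULL
  }
  x <- as.matrix(x)
  nv <- length(vars)
  r <- matrix(NA_real_, nv, nv, dimnames = list(vars, vars))
  p <- matrix(NA_real_, nv, nv, dimnames = list(vars, vars))
  n <- matrix(0L, nv, nv, dimnames = list(vars, vars))
  degen <- character()
  diag(r) <- 1
  diag(n) <- as.integer(colSums(is.finite(x)))
  for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
    ok <- is.finite(x[, i]) & is.finite(x[, j])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < minPairs) next
    if (sd(x[ok, i]) == 0 || sd(x[ok, j]) == 0) {
      degen <- union(degen, vars[c(i, j)][c(sd(x[ok, i]) == 0,
                                            sd(x[ok, j]) == 0)])
      next
    }
    ct <- cor.test(x[ok, i], x[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  if (length(degen))
    warning("zero variance, correlations undefined for: ",
            paste(degen, collapse = ", "))
  new("CorrelationMatrix", r = r, p = p, n = n, alpha = alpha,
      markers = markers)
}

#' Strength class of a correlation coefficient
#'
#' Band classification of significant correlations: `|r| <= 0.295` low,
#' `0.295 < |r| <= 0.495` moderate, above that strong (the conventional
#' 0.29 / 0.49 cut points, with the printed band gaps 0.29-0.30 and
#' 0.49-0.50 closed at 0.295 / 0.495).
#'
#' @param r numeric vector of correlations.
#' @return character vector: `"low"`, `"moderate"` or `"strong"`.
#' @export
strengthClass <- function(r) {
  cls <- ifelse(abs(r) <= 0.295, "low",
                ifelse(abs(r) <= 0.495, "moderate", "strong"))
  cls[!is.finite(r)] <- NA_character_
  cls
}

#' @rdname corValues
#' @export
setGeneric("significantPairs",
           function(object) standardGeneric("significantPairs"))

#' @rdname corValues
#' @export
setMethod("significantPairs", "CorrelationMatrix", function(object) {
  vars <- rownames(object@r)
  ut <- which(upper.tri(object@r), arr.ind = TRUE)
  out <- data.frame(
    var1 = vars[ut[, 1]], var2 = vars[ut[, 2]],
    r = object@r[ut], p = object@p[ut], n = object@n[ut],
    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p) & out$p < object@alpha
  out$class <- strengthClass(out$r)
  out[order(out$var1, out$var2), ]
})

#' Rank markers by correlation with a monitoring target
#'
#' Markers significantly correlated with the target (7-day expTRIMP,
#' muscle soreness or VO2max), sorted by r from highest to lowest; ties
#' broken by marker name for determinism.  Non-significant markers are
#' excluded.
#'
#' @param object a [CorrelationMatrix-class].
#' @param target a variable present in the matrix, e.g. `"exp_trimp_7"`,
#'   `"soreness"`, `"vo2max"`.
#' @return `data.frame`: `marker`, `r`, `p`, `class`, ranked.
#' @export
rankAgainst <- function(object, target = "exp_trimp_7") {
  stopifnot(is(object, "CorrelationMatrix"))
  if (!target %in% rownames(object@r))
    stop("invalid argument: target '", target, "' not in matrix")
  mk <- setdiff(object@markers, target)
  r <- object@r[mk, target]
  p <- object@p[mk, target]
  sig <- !is.na(p) & p < object@alpha
  out <- data.frame(marker = mk[sig], r = r[sig], p = p[sig],
                    class = strengthClass(r[sig]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$marker), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation network of significant associations
#'
#' Nodes are the matrix variables; edges exist only where the pairwise
#' correlation is significant.  Edge weight is `|r|` (a monotone
#' transform of the coefficient; the sign is carried as a separate
#' attribute, negative edges conventionally drawn blue, positive red).
#'
#' @param object a [CorrelationMatrix-class].
#' @param topK optional: keep only the `topK` edges with largest `|r|`
#'   (ties broken deterministically by node names).
#' @return an [igraph::graph] with edge attributes `r`, `weight`, `sign`
#'   and graph attribute `alpha`.
#' @export
buildNetwork <- function(object, topK = NULL) {
  stopifnot(is(object, "CorrelationMatrix"))
  if (!is.null(topK) && topK < 1)
    stop("invalid argument: topK must be >= 1")
  sp <- significantPairs(object)
  ed <- sp[sp$significant, , drop = FALSE]
  ed <- ed[order(-abs(ed$r), ed$var1, ed$var2), , drop = FALSE]
  if (!is.null(topK) && nrow(ed) > topK) ed <- ed[seq_len(topK), ]
  g <- igraph::graph_from_data_frame(
    ed[, c("var1", "var2")], directed = FALSE,
    vertices = data.frame(name = rownames(object@r)))
  igraph::E(g)$r <- ed$r
  igraph::E(g)$weight <- abs(ed$r)
  igraph::E(g)$sign <- sign(ed$r)
  igraph::E(g)$class <- ed$class
  g <- igraph::set_graph_attr(g, "alpha", object@alpha)
  g
}

#' Per-group top-k correlation subnetworks
#'
#' Recomputes the correlation matrix within each group and keeps the
#' `topK` significant edges by `|r|` - the per-group "top ten correlating
#' biomarkers" view.
#'
#' @param aligned table from [buildAlignedTable()].
#' @param topK edges kept per group (default 10).
#' @param vars,alpha,scale passed to [pearsonMatrix()].
#' @return named list of igraph networks, one per group.
#' @export
groupNetworks <- function(aligned, topK = 10, vars = NULL, alpha = 0.05,
                          scale = "raw") {
  if (topK < 1) stop("invalid argument: topK must be >= 1")
  groups <- sort(unique(aligned$group))
  out <- lapply(groups, function(g) {
    cm <- pearsonMatrix(aligned[aligned$group == g, , drop = FALSE],
                        vars = vars, alpha = alpha, scale = scale)
    buildNetwork(cm, topK = topK)
  })
  names(out) <- groups
  out
}

#' Edge table of a correlation network
#'
#' @param network an igraph network from [buildNetwork()].
#' @return `data.frame`: `var1`, `var2`, `r`, `weight`, `sign`, `class`.
#' @export
networkEdges <- function(network) {
  el <- igraph::as_edgelist(network)
  data.frame(var1 = el[, 1], var2 = el[, 2],
             r = igraph::E(network)$r,
             weight = igraph::E(network)$weight,
             sign = igraph::E(network)$sign,
             class = igraph::E(network)$class,
             stringsAsFactors = FALSE)
}
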