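## Shared fixtures, all built in code at test time.

## A hand-crafted panel: `value(i, tp, m)` gives the concentration for
## participant index i (P01..P{n}, groups recycled CG/HSM/HSM_LIT),
## timepoint tp and marker m.
toyPanel <- function(markers, n = 6, value) {
  grid <- timepointGrid()
  groups <- rep(c("CG", "HSM", "HSM_LIT"), length.out = n)
  long <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(seq_len(nrow(grid)), function(t) {
      data.frame(
        participant_id = sprintf("P%02d", i),
        group = groups[i],
        timepoint = as.character(grid$timepoint[t]),
        study_day = grid$study_day[t],
        marker = markers,
        value = vapply(markers, function(m)
          value(i, as.character(grid$timepoint[t]), m), numeric(1)),
        stringsAsFactors = FALSE
      )
    }))
  }))
  BiomarkerPanel(long)
}

## Independent closed-form expansion of the first-load-initialized EWMA.
ewmaOracle <- function(loads, N) {
  lam <- 2 / (N + 1)
  vapply(seq_along(loads), function(t) {
    k <- 0:(t - 2)
    tail <- if (t >= 2) sum(lam * (1 - lam)^k * loads[t - k]) else 0
    tail + (1 - lam)^(t - 1) * loads[1]
  }, numeric(1))
}

## Independent ordinary-least-squares fit (normal equations).
lsOracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

## A moderately sized default-config study without traces, shared across
## test files (generated once per test run).
sharedStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(
        simulateStudy(nPerGroup = 10, seed = 42, traces = FALSE))
    cache
  }
})

sharedAligned <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- sharedStudy()
      cache <<- suppressMessages(buildAlignedTable(
        st$panel, st$plannedDaily, st$selfReports, st$vo2max))
    }
    cache
  }
})
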