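#' Bin spikes around events
#'
#' Counts spikes of one unit in equal-width half-open bins relative to each
#' event and converts to rates (sp/s). The bin grid is anchored at the event
#' (an edge at 0), so `values[t, b]` is the count in
#' `[event_t + edge_b, event_t + edge_{b+1})` divided by the bin width.
#'
#' @param spike_times Sorted numeric vector, seconds.
#' @param events Numeric vector of alignment times, seconds.
#' @param window Length-2 interval relative to each event, seconds.
#' @param bin Bin width, seconds; must divide the window length to within one
#'   part in 1e6.
#' @return Matrix `length(events)` x `n_bins` of rates, with bin edges in
#'   `attr(, "bin_edges")`. Empty `events` give a zero-row matrix with a
#'   warning.
#' @export
bin_spikes <- function(spike_times, events, window, bin) {
  span <- window[2] - window[1]
  n_bins <- round(span / bin)
  if (abs(n_bins * bin - span) > 1e-6 * span) {
    abort("bin width must divide the window length")
  }
  edges <- window[1] + bin * (0:n_bins)
  if (!length(events)) {
    warn("no events supplied; returning an empty tensor slice")
    out <- matrix(numeric(0), nrow = 0, ncol = n_bins)
    attr(out, "bin_edges") <- edges
    return(out)
  }
  spike_times <- as.numeric(spike_times)
  counts <- matrix(0, nrow = length(events), ncol = n_bins)
  for (i in seq_along(events)) {
    cum <- findInterval(events[i] + edges, spike_times)
    counts[i, ] <- diff(cum)
  }
  out <- counts / bin
  attr(out, "bin_edges") <- edges
  out
}

#' Build a unit x trial x bin rate tensor
#'
#' Aligns every unit's spikes to a per-trial event (default the first touch)
#' and bins them over `window` at width `bin`.
#'
#' @param session A [wb_session()].
#' @param window Interval relative to the alignment event, seconds; the
#'   default spans the 1.5 s baseline and the 300 ms response period.
#' @param bin Bin width, seconds (default the 10 ms bias cadence).
#' @param alignment `"first_touch"` or `"first_lick"` (trials without the
#'   event are filled with `NA`).
#' @return Object of class `wb_rate_tensor`: a list with `values`
#'   (3-d array unit x trial x bin, sp/s), `bin_edges`, `unit_ids`,
#'   `trial_ids`, `alignment`, `zscored` flag and (after [zscore_tensor()])
#'   `baseline_stats`.
#' @export
rate_tensor <- function(session, window = c(-1.5, 0.3), bin = 0.010,
                        alignment = c("first_touch", "first_lick")) {
  alignment <- match.arg(alignment)
  tr <- session$trials
  events <- switch(alignment,
    first_touch = tr$first_touch,
    first_lick = vapply(seq_len(nrow(tr)), function(i) {
      lk <- tr$lick_times[[i]]
      lk <- lk[lk >= tr$first_touch[i]]
      if (length(lk)) lk[1] else NA_real_
    }, numeric(1)))
  u <- session$units
  n_bins <- round((window[2] - window[1]) / bin)
  vals <- array(NA_real_, dim = c(nrow(u), nrow(tr), n_bins))
  ok <- !is.na(events)
  for (i in seq_len(nrow(u))) {
    m <- bin_spikes(u$spike_times[[i]], events[ok], window, bin)
    vals[i, ok, ] <- m
  }
  structure(list(values = vals,
                 bin_edges = window[1] + bin * (0:n_bins),
                 unit_ids = u$unit_id, trial_ids = tr$trial_id,
                 alignment = alignment, zscored = FALSE,
                 baseline_stats = NULL),
            class = "wb_rate_tensor")
}

#' @export
print.wb_rate_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<wb_rate_tensor> %d units x %d trials x %d bins of %.0f ms, aligned to %s%s\n",
              d[1], d[2], d[3], diff(x$bin_edges[1:2]) * 1000, x$alignment,
              if (x$zscored) " (z-scored)" else ""))
  invisible(x)
}

bin_centers <- function(tensor) {
  e <- tensor$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Trials the animal was engaged in
#'
#' Engaged trials are Hits and Correct Rejections: the animal either responded
#' to the positive stimulus or actively withheld a response to the negative
#' one. Used as the default reference for z-scoring.
#'
#' @param trials Session trial tibble.
#' @return Logical vector over trials.
#' @export
engaged_trials <- function(trials) {
  trials$outcome %in% c("Hit", "CR") & trials$context == "Home"
}

#' Z-score a rate tensor against its baseline
#'
#' Per unit, subtracts the mean and divides by the SD of the baseline-window
#' bin rates pooled over the reference trials (default: all engaged trials),
#' so rates in every condition are expressed on the engaged baseline scale.
#' The SD is floored at 0.1 sp/s; floored (near-silent) units are flagged in
#' `baseline_stats$floored` rather than excluded.
#'
#' @param tensor A non-z-scored [rate_tensor()].
#' @param session The session the tensor came from.
#' @param windows [analysis_windows()] defining the baseline interval.
#' @param reference_trials Logical or integer index of trials; default
#'   [engaged_trials()].
#' @param sd_floor Floor on the baseline SD, sp/s.
#' @return The tensor with z-scored `values`, `zscored = TRUE` and per-unit
#'   `baseline_stats` (mean, sd, floored flag).
#' @export
zscore_tensor <- function(tensor, session, windows = analysis_windows(),
                          reference_trials = engaged_trials(session$trials),
                          sd_floor = 0.1) {
  if (tensor$zscored) abort("tensor is already z-scored")
  if (is.logical(reference_trials)) reference_trials <- which(reference_trials)
  if (!length(reference_trials)) abort("no reference trials for z-scoring")
  centers <- bin_centers(tensor)
  base_bins <- which(in_interval(centers, windows$baseline))
  if (!length(base_bins)) abort("tensor does not cover the baseline window")
  nu <- dim(tensor$values)[1]
  mu <- numeric(nu); sdev <- numeric(nu)
  for (i in seq_len(nu)) {
    b <- tensor$values[i, reference_trials, base_bins]
    b <- b[!is.na(b)]
    mu[i] <- mean(b)
    sdev[i] <- sd(b)
  }
  floored <- is.na(sdev) | sdev < sd_floor
  sdev[floored] <- sd_floor
  tensor$values <- (tensor$values - rep(mu, times = prod(dim(tensor$values)[2:3]))) /
    rep(sdev, times = prod(dim(tensor$values)[2:3]))
  tensor$zscored <- TRUE
  tensor$baseline_stats <- tibble::tibble(
    unit_id = tensor$unit_ids, mean = mu, sd = sdev, floored = floored)
  tensor
}

#' Mean rate in a time window
#'
#' Mean over the bins lying fully inside the half-open `window`, per unit and
#' trial.
#'
#' @param tensor A [rate_tensor()].
#' @param window Length-2 interval, seconds relative to the alignment event.
#' @return Matrix unit x trial (sp/s, or z-units for a z-scored tensor).
#' @export
window_rate <- function(tensor, window) {
  e <- tensor$bin_edges
  sel <- which(e[-length(e)] >= window[1] - 1e-9 & e[-1] <= window[2] + 1e-9)
  if (!length(sel)) abort("window overlaps no complete bin")
  m <- apply(tensor$values[, , sel, drop = FALSE], c(1, 2), mean)
  dimnames(m) <- list(tensor$unit_ids, NULL)
  m
}

#' @describeIn rate_tensor Long-format tibble (`unit_id`, `trial_id`, `time`
#'   at bin centers, `rate`).
#' @param x A `wb_rate_tensor`.
#' @param ... Unused.
#' @export
tidy.wb_rate_tensor <- function(x, ...) {
  d <- dim(x$values)
  centers <- bin_centers(x)
  tibble::tibble(
    unit_id = rep(x$unit_ids, times = d[2] * d[3]),
    trial_id = rep(rep(x$trial_ids, each = d[1]), times = d[3]),
    time = rep(centers, each = d[1] * d[2]),
    rate = as.vector(x$values))
}

#' Trial-averaged PSTH table
#'
#' Mean rate per unit and time bin over a trial subset, suitable for CSV
#' export or plotting.
#'
#' @param tensor A [rate_tensor()].
#' @param trials Logical or integer trial index (default all trials).
#' @return Tibble `unit_id`, `time`, `rate`.
#' @export
psth <- function(tensor, trials = NULL) {
  idx <- if (is.null(trials)) seq_along(tensor$trial_ids)
         else if (is.logical(trials)) which(trials) else trials
  m <- apply(tensor$values[, idx, , drop = FALSE], c(1, 3),
             function(v) mean(v, na.rm = TRUE))
  tibble::tibble(
    unit_id = rep(tensor$unit_ids, times = ncol(m)),
    time = rep(bin_centers(tensor), each = nrow(m)),
    rate = as.vector(m))
}
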