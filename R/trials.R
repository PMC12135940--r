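#' Remove disengaged correct rejections
#'
#' Satiated or disengaged animals stop licking altogether, which would
#' inflate the CR count. A disengagement window is a maximal run of
#' consecutive no-lick trials (Miss or CR) containing at least `min_misses`
#' Miss trials; CR trials inside such a window are removed. Licked trials are
#' never removed and trial order is preserved.
#'
#' @param trials Trial tibble in session order.
#' @param min_misses Miss count that marks a no-lick run as disengaged.
#' @return The retained trials, same columns and order.
#' @export
filter_disengaged_cr <- function(trials, min_misses = 5L) {
  no_lick <- trials$outcome %in% c("Miss", "CR")
  drop <- logical(nrow(trials))
  r <- rle(no_lick)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    run <- starts[k]:ends[k]
    if (sum(trials$outcome[run] == "Miss") >= min_misses) {
      drop[run] <- trials$outcome[run] == "CR"
    }
  }
  trials[!drop, , drop = FALSE]
}

#' Lick latency of each trial
#'
#' Time from first touch to the first subsequent lick; `NA` for trials with
#' no lick at or after the first touch.
#'
#' @param trials Trial tibble.
#' @return Tibble `trial_id`, `latency` (seconds).
#' @export
lick_latency <- function(trials) {
  lat <- vapply(seq_len(nrow(trials)), function(i) {
    lk <- trials$lick_times[[i]]
    lk <- lk[lk >= trials$first_touch[i]]
    if (length(lk)) lk[1] - trials$first_touch[i] else NA_real_
  }, numeric(1))
  tibble::tibble(trial_id = trials$trial_id, latency = lat)
}
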