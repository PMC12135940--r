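#' Analysis windows relative to first touch
#'
#' Bundles the time windows used throughout the pipeline, all in seconds
#' relative to the first touch of a trial and all half-open `[start, end)`.
#' Defaults follow the task design: a 1.5 s pre-touch baseline, a 300 ms
#' stimulus (response) period, an early feed-forward window (first 50 ms) and
#' a late window (70-300 ms) where suppression dominates, with the
#' time-resolved bias computed in 10 ms bins.
#'
#' @param baseline,response,early,late Length-2 numeric intervals, seconds
#'   relative to first touch.
#' @param bias_bin Bin width for the time-resolved bias, seconds.
#'
#' @return A list of class `wb_windows`.
#' @examples
#' analysis_windows()
#' @export
analysis_windows <- function(baseline = c(-1.5, 0),
                             response = c(0, 0.3),
                             early = c(0, 0.05),
                             late = c(0.07, 0.3),
                             bias_bin = 0.010) {
  w <- list(baseline = as.numeric(baseline), response = as.numeric(response),
            early = as.numeric(early), late = as.numeric(late),
            bias_bin = as.numeric(bias_bin))
  for (nm in c("baseline", "response", "early", "late")) {
    iv <- w[[nm]]
    if (length(iv) != 2L || !all(is.finite(iv)) || iv[1] >= iv[2]) {
      abort(paste0("`", nm, "` must be a finite interval [start, end) with start < end"))
    }
  }
  if (w$baseline[2] > w$response[1]) {
    abort("baseline window must precede the response window")
  }
  if (w$early[1] < w$response[1] || w$early[2] > w$response[2]) {
    abort("early window must lie inside the response window")
  }
  if (w$late[1] < w$response[1] || w$late[2] > w$response[2]) {
    abort("late window must lie inside the response window")
  }
  if (!is.finite(w$bias_bin) || w$bias_bin <= 0) abort("bias_bin must be > 0")
  structure(w, class = "wb_windows")
}

# interval membership helper for half-open [a, b)
in_interval <- function(x, interval) x >= interval[1] & x < interval[2]
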