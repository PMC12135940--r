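#' Normalized cross-correlation of two traces
#'
#' Coefficient-normalized cross-correlation with zero-padding outside the
#' trace: `r(l) = sum_t f(t + l) s(t) / sqrt(sum f^2 sum s^2)`, so the
#' zero-lag autocorrelation of a trace with itself is 1. Traces are taken as
#' given (z-scored traces are already expressed relative to the baseline
#' mean); no additional mean removal is applied, since demeaning a short
#' all-response window would turn the late part of a facilitated trace
#' negative and distort the minimum. The lag convention follows the
#' facilitation/suppression analysis: if `s` is a delayed (negated) copy of
#' `f` the minimum falls at a negative lag — negative lag means the
#' suppressed trace follows the facilitated one.
#'
#' @param f,s Numeric traces on a shared bin grid.
#' @param max_lag_bins Maximum |lag| in bins.
#' @return Tibble `lag_bins`, `r`.
#' @export
xcorr_coeff <- function(f, s, max_lag_bins = length(f) - 1L) {
  n <- length(f)
  if (length(s) != n) abort("traces must share the bin grid")
  f0 <- f; s0 <- s
  denom <- sqrt(sum(f0^2) * sum(s0^2))
  if (denom == 0 || var(f) == 0 || var(s) == 0) {
    abort("constant trace", class = "wb_constant_trace")
  }
  lags <- (-max_lag_bins):max_lag_bins
  r <- vapply(lags, function(l) {
    t_s <- seq_len(n)
    t_f <- t_s + l
    ok <- t_f >= 1L & t_f <= n
    sum(f0[t_f[ok]] * s0[t_s[ok]])
  }, numeric(1)) / denom
  tibble::tibble(lag_bins = lags, r = r)
}

#' Lag of the minimum cross-correlation between facilitated and suppressed
#' populations
#'
#' Every facilitated trace is cross-correlated with every suppressed trace;
#' per pair, the lag at the minimum correlation estimates the temporal offset
#' between touch facilitation and touch suppression (negative lag:
#' suppression follows facilitation). Ties in the minimum resolve to the lag
#' of smallest magnitude. Pairs with a constant trace are skipped and
#' counted.
#'
#' @param facilitated,suppressed Matrices (trace per row) of trial-averaged
#'   z-scored touch responses on a shared grid, e.g. rows of
#'   [psth()] values over the response window.
#' @param bin Trace bin width, seconds.
#' @param max_lag Maximum |lag|, seconds.
#' @return Object of class `wb_lag`: list with `pairs` (tibble `fac`, `sup`,
#'   `lag` seconds), `correlogram` (mean r per lag), `summary_lag` (mean pair
#'   lag, seconds, stored unrounded), `n_skipped`.
#' @export
xcorr_min_lag <- function(facilitated, suppressed, bin = 0.010,
                          max_lag = 0.3) {
  facilitated <- rbind(facilitated)
  suppressed <- rbind(suppressed)
  if (!nrow(facilitated) || !nrow(suppressed)) {
    abort("both populations must be nonempty")
  }
  max_bins <- min(round(max_lag / bin), ncol(facilitated) - 1L)
  lags <- ((-max_bins):max_bins) * bin
  acc <- numeric(length(lags)); n_acc <- 0L; n_skip <- 0L
  rows <- list()
  for (i in seq_len(nrow(facilitated))) {
    for (j in seq_len(nrow(suppressed))) {
      cc <- tryCatch(
        xcorr_coeff(facilitated[i, ], suppressed[j, ], max_bins),
        wb_constant_trace = function(e) NULL)
      if (is.null(cc)) { n_skip <- n_skip + 1L; next }
      mn <- min(cc$r)
      cand <- which(cc$r == mn)
      pick <- cand[which.min(abs(cc$lag_bins[cand]))]
      rows[[length(rows) + 1L]] <- c(i, j, cc$lag_bins[pick] * bin)
      acc <- acc + cc$r; n_acc <- n_acc + 1L
    }
  }
  if (!length(rows)) abort("no valid facilitated x suppressed pair")
  m <- do.call(rbind, rows)
  pairs <- tibble::tibble(fac = as.integer(m[, 1]), sup = as.integer(m[, 2]),
                          lag = m[, 3])
  structure(list(pairs = pairs,
                 correlogram = tibble::tibble(lag = lags, r = acc / n_acc),
                 summary_lag = mean(pairs$lag),
                 n_skipped = n_skip, bin = bin),
            class = "wb_lag")
}

#' @export
print.wb_lag <- function(x, ...) {
  cat(sprintf("<wb_lag> %d pairs, mean minimum-correlation lag %.1f ms (%d skipped)\n",
              nrow(x$pairs), 1000 * x$summary_lag, x$n_skipped))
  invisible(x)
}

#' @describeIn xcorr_min_lag Per-pair lags as a tibble.
#' @param x A `wb_lag`.
#' @param ... Unused.
#' @export
tidy.wb_lag <- function(x, ...) x$pairs

#' @describeIn xcorr_min_lag One-row summary (`summary_lag`, `n_pairs`,
#'   `n_skipped`).
#' @export
glance.wb_lag <- function(x, ...) {
  tibble::tibble(summary_lag = x$summary_lag, n_pairs = nrow(x$pairs),
                 n_skipped = x$n_skipped)
}

#' Facilitation-suppression lag of one session
#'
#' End-to-end per-mouse lag analysis: classifies units facilitated or
#' suppressed by the negative stimulus (paired t-test vs baseline on CR
#' trials), builds their trial-averaged z-scored CR responses over the
#' response window at the bias-bin width, and runs [xcorr_min_lag()] on all
#' facilitated x suppressed pairs.
#'
#' @param session A [wb_session()].
#' @param windows [analysis_windows()].
#' @param max_lag Maximum |lag|, seconds.
#' @param classes Optional precomputed [classify_units()] table.
#' @return A `wb_lag`, or `NULL` (with a warning) when either population is
#'   empty.
#' @export
session_lag <- function(session, windows = analysis_windows(), max_lag = 0.3,
                        classes = NULL) {
  tensor <- rate_tensor(session, window = c(windows$baseline[1],
                                            windows$response[2]),
                        bin = windows$bias_bin)
  if (is.null(classes)) {
    classes <- classify_units(session, tensor, windows = windows)
  }
  z <- zscore_tensor(tensor, session, windows = windows)
  kept <- filter_disengaged_cr(session$trials)
  cr <- session$trials$trial_id %in% kept$trial_id &
    session$trials$outcome == "CR"
  traces <- psth(z, trials = cr)
  centers <- sort(unique(traces$time))
  resp <- centers[in_interval(centers, windows$response)]
  wide <- tidyr::pivot_wider(traces[traces$time %in% resp, ],
                             names_from = "time", values_from = "rate")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$unit_id
  fac <- mat[wide$unit_id %in% classes$unit_id[classes$touch_effect == "facilitated"], ,
             drop = FALSE]
  sup <- mat[wide$unit_id %in% classes$unit_id[classes$touch_effect == "suppressed"], ,
             drop = FALSE]
  if (!nrow(fac) || !nrow(sup)) {
    warn("no facilitated or no suppressed units in this session")
    return(NULL)
  }
  xcorr_min_lag(fac, sup, bin = windows$bias_bin, max_lag = max_lag)
}
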