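#' Neurometric d-prime (stimulus bias)
#'
#' The selectivity of a response between two conditions A and B:
#' \deqn{d' = (\mu_A - \mu_B) / \sqrt{(\sigma^2_A + \sigma^2_B)/2}}
#' the difference of mean spike rates divided by the root-mean-square of the
#' across-trial standard deviations. Positive values indicate preference for
#' condition A. When both variances are zero the value is 0 if the means are
#' equal, otherwise `sign(mu_a - mu_b) * cap` and the bin is flagged.
#'
#' @param mu_a,var_a,mu_b,var_b Mean and across-trial variance of the spike
#'   rate in each condition (vectorized).
#' @param cap Magnitude assigned to degenerate (both-variance-zero, unequal
#'   mean) bins.
#' @return Numeric vector of d-prime values with attribute `flagged` marking
#'   degenerate entries.
#' @examples
#' dprime(10, 4, 6, 4)  # 2
#' @export
dprime <- function(mu_a, var_a, mu_b, var_b, cap = 10) {
  rms <- sqrt((var_a + var_b) / 2)
  d <- (mu_a - mu_b) / rms
  degen <- rms == 0
  flagged <- degen & (mu_a != mu_b)
  d[degen] <- 0
  d[flagged] <- sign(mu_a - mu_b)[flagged] * cap
  attr(d, "flagged") <- flagged
  d
}

# per-unit, per-bin condition moments over a trial subset
condition_moments <- function(tensor, trials, bins) {
  v <- tensor$values[, trials, bins, drop = FALSE]
  mu <- apply(v, c(1, 3), function(x) mean(x, na.rm = TRUE))
  va <- apply(v, c(1, 3), function(x) var(x[!is.na(x)]))
  list(mu = mu, var = va, n = length(trials))
}

resolve_trials <- function(tensor, trials, what) {
  idx <- if (is.logical(trials)) which(trials) else as.integer(trials)
  if (length(idx) < 2L) {
    abort(paste0("condition ", what, " has fewer than 2 trials"))
  }
  idx
}

#' Time-resolved stimulus bias between two trial sets
#'
#' Computes [dprime()] per unit in every bias bin of the response span,
#' comparing trial set A against trial set B (e.g., Hit vs CR trials). The
#' calculation is performed every `windows$bias_bin` (10 ms by default),
#' giving a continuous estimate of bias through the response window.
#'
#' @param tensor A [rate_tensor()] whose bin width equals `windows$bias_bin`.
#' @param trials_a,trials_b Logical or integer trial indices for conditions A
#'   and B; each needs at least 2 trials.
#' @param span Interval covered by the series (default the response window).
#' @param windows [analysis_windows()].
#' @param cap Degenerate-bin cap, see [dprime()].
#' @return A tibble of class `wb_bias` with columns `unit_id`, `time` (bin
#'   center, s), `dprime`, `flagged`.
#' @seealso [bias_from_baseline()], [summarize_bias()]
#' @export
stimulus_bias <- function(tensor, trials_a, trials_b,
                          span = NULL, windows = analysis_windows(),
                          cap = 10) {
  if (is.null(span)) span <- windows$response
  bw <- diff(tensor$bin_edges[1:2])
  if (abs(bw - windows$bias_bin) > 1e-9) {
    abort("tensor bin width must equal windows$bias_bin")
  }
  ia <- resolve_trials(tensor, trials_a, "A")
  ib <- resolve_trials(tensor, trials_b, "B")
  centers <- bin_centers(tensor)
  bins <- which(in_interval(centers, span))
  a <- condition_moments(tensor, ia, bins)
  b <- condition_moments(tensor, ib, bins)
  d <- dprime(a$mu, a$var, b$mu, b$var, cap = cap)
  new_bias(tensor$unit_ids, centers[bins], d, attr(d, "flagged"), windows)
}

#' Time-resolved bias of a condition relative to its baseline
#'
#' Same statistic as [stimulus_bias()] but condition B is the pre-touch
#' baseline of the same trials, measured on the same 10 ms-bin scale as the
#' response: `mu_B` is the mean baseline bin rate and `sigma2_B` the mean
#' across-trial variance of the baseline bins, so both conditions carry
#' comparable counting noise (a baseline summarized by its 1.5 s mean would
#' have near-zero variance and make empty response bins explode). Negative
#' values mean the response fell below the pre-touch baseline (touch
#' suppression).
#'
#' @inheritParams stimulus_bias
#' @param trials Trial subset supplying both the response and the baseline
#'   sample.
#' @return A `wb_bias` tibble.
#' @export
bias_from_baseline <- function(tensor, trials, span = NULL,
                               windows = analysis_windows(), cap = 10) {
  if (is.null(span)) span <- windows$response
  bw <- diff(tensor$bin_edges[1:2])
  if (abs(bw - windows$bias_bin) > 1e-9) {
    abort("tensor bin width must equal windows$bias_bin")
  }
  idx <- resolve_trials(tensor, trials, "condition")
  centers <- bin_centers(tensor)
  bins <- which(in_interval(centers, span))
  a <- condition_moments(tensor, idx, bins)
  base_bins <- which(in_interval(centers, windows$baseline))
  b <- condition_moments(tensor, idx, base_bins)
  mu_b <- rowMeans(b$mu, na.rm = TRUE)
  var_b <- rowMeans(b$var, na.rm = TRUE)
  d <- dprime(a$mu, a$var,
              matrix(mu_b, nrow = nrow(a$mu), ncol = ncol(a$mu)),
              matrix(var_b, nrow = nrow(a$mu), ncol = ncol(a$mu)), cap = cap)
  new_bias(tensor$unit_ids, centers[bins], d, attr(d, "flagged"), windows)
}

new_bias <- function(unit_ids, times, d, flagged, windows) {
  out <- tibble::tibble(
    unit_id = rep(unit_ids, times = length(times)),
    time = rep(times, each = length(unit_ids)),
    dprime = as.vector(d),
    flagged = as.vector(flagged))
  class(out) <- c("wb_bias", class(out))
  attr(out, "windows") <- windows
  out
}

#' Per-unit window summaries of a bias series
#'
#' Mean bias over the response, early (0-50 ms) and late (70-300 ms) windows.
#' The response-window mean is the quantity whose sign defines a unit's
#' stimulus preference.
#'
#' @param bias A `wb_bias` tibble.
#' @param windows [analysis_windows()] (defaults to those stored on `bias`).
#' @return Tibble `unit_id`, `mean_response`, `mean_early`, `mean_late`.
#' @export
summarize_bias <- function(bias, windows = NULL) {
  windows <- windows %||% attr(bias, "windows") %||% analysis_windows()
  bias |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      mean_response = mean(.data$dprime[in_interval(.data$time, windows$response)]),
      mean_early = mean(.data$dprime[in_interval(.data$time, windows$early)]),
      mean_late = mean(.data$dprime[in_interval(.data$time, windows$late)]),
      .groups = "drop")
}

#' Behavioral d-prime from hit and false-alarm rates
#'
#' Standard signal-detection sensitivity `qnorm(H') - qnorm(F')`. With trial
#' counts supplied, rates get the log-linear correction
#' `H' = (hits + 0.5) / (n + 1)`; otherwise extreme rates are clipped to
#' `[1/(2n), 1 - 1/(2n)]` with `n = 1e6` standing in for an unknown count
#' (i.e., essentially unclipped away from 0 and 1).
#'
#' @param hit_rate,fa_rate Fractions in `[0, 1]`.
#' @param n_go,n_nogo Optional trial counts behind each rate.
#' @return Unitless d-prime (vectorized).
#' @examples
#' behavioral_dprime(0.9, 0.1)  # 2.563
#' @export
behavioral_dprime <- function(hit_rate, fa_rate, n_go = NULL, n_nogo = NULL) {
  if (any(hit_rate < 0 | hit_rate > 1 | fa_rate < 0 | fa_rate > 1)) {
    abort("rates must lie in [0, 1]")
  }
  adj <- function(rate, n) {
    if (!is.null(n)) (rate * n + 0.5) / (n + 1)
    else pmin(pmax(rate, 1 / (2 * 1e6)), 1 - 1 / (2 * 1e6))
  }
  qnorm(adj(hit_rate, n_go)) - qnorm(adj(fa_rate, n_nogo))
}
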