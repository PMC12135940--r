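#' Correlation between baseline firing rate and lick latency
#'
#' If a unit's spontaneous rate tracks readiness to respond, trials with a
#' higher pre-touch baseline rate should show shorter reaction times. Per
#' unit, correlates the per-trial baseline-window rate with the lick latency
#' over Hit trials (pairwise-complete; trials without a qualifying lick are
#' excluded, not imputed), and tests the population of per-unit coefficients
#' against zero with a one-sample t-test.
#'
#' @param tensor A [rate_tensor()] covering the baseline window (raw or
#'   z-scored; both correlation methods are invariant to the per-unit affine
#'   rescaling).
#' @param session The session.
#' @param method `"pearson"` (population default) or `"spearman"`.
#' @param windows [analysis_windows()].
#' @param min_trials Minimum Hit trials with defined latency (default 10).
#' @param alpha Per-unit significance level.
#' @return Tibble of class `wb_latency_cor`: `unit_id`, `r`, `p`,
#'   `significant`, `flagged` (zero-variance units, `r = NA`); attributes
#'   `population_p`, `n_trials`, `method`.
#' @export
baseline_latency_correlation <- function(tensor, session,
                                         method = c("pearson", "spearman"),
                                         windows = analysis_windows(),
                                         min_trials = 10L, alpha = 0.05) {
  method <- match.arg(method)
  tr <- session$trials
  lat <- lick_latency(tr)$latency
  hit <- which(tr$outcome == "Hit" & tr$context == "Home" & !is.na(lat))
  if (length(hit) < min_trials) {
    abort(sprintf("fewer than %d Hit trials with defined latency", min_trials))
  }
  base <- window_rate(tensor, windows$baseline)[, hit, drop = FALSE]
  y <- lat[hit]
  res <- lapply(seq_len(nrow(base)), function(u) {
    x <- base[u, ]
    ok <- !is.na(x)
    if (sum(ok) < min_trials || var(x[ok]) == 0 || var(y[ok]) == 0) {
      return(list(r = NA_real_, p = NA_real_, flagged = TRUE))
    }
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method))
    list(r = unname(ct$estimate), p = ct$p.value, flagged = FALSE)
  })
  out <- tibble::tibble(
    unit_id = tensor$unit_ids,
    r = vapply(res, `[[`, numeric(1), "r"),
    p = vapply(res, `[[`, numeric(1), "p"),
    flagged = vapply(res, `[[`, logical(1), "flagged"))
  out$significant <- !is.na(out$p) & out$p < alpha
  class(out) <- c("wb_latency_cor", class(out))
  rr <- out$r[!is.na(out$r)]
  attr(out, "population_p") <- if (length(rr) >= 2) t.test(rr)$p.value else NA_real_
  attr(out, "n_trials") <- length(hit)
  attr(out, "method") <- method
  out
}

#' @describeIn baseline_latency_correlation One-row population summary.
#' @param x A `wb_latency_cor`.
#' @param ... Unused.
#' @export
glance.wb_latency_cor <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method"),
    n_units = sum(!is.na(x$r)),
    mean_r = mean(x$r, na.rm = TRUE),
    n_significant = sum(x$significant, na.rm = TRUE),
    population_p = attr(x, "population_p"))
}
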