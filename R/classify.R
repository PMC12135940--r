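#' Is a unit touch responsive?
#'
#' One-way ANOVA over three groups of per-trial rates — baseline, response to
#' stimulus A, response to stimulus B — followed by Tukey post-hoc
#' comparisons. A unit is responsive iff the Tukey-adjusted comparison of
#' baseline against either stimulus has `p < alpha` (the A-vs-B contrast is
#' not used: responsiveness means a tactile response to one or both whiskers,
#' not selectivity).
#'
#' @param baseline,stim_a,stim_b Numeric vectors of per-trial window rates
#'   (each needs at least 5 trials).
#' @param alpha Significance level.
#' @return Logical; `NA`-safe (a group with undefined variance returns
#'   `FALSE` with attribute `flagged = TRUE`).
#' @export
classify_responsive <- function(baseline, stim_a, stim_b, alpha = 0.05) {
  groups <- list(baseline = baseline, stim_a = stim_a, stim_b = stim_b)
  groups <- lapply(groups, function(x) x[!is.na(x)])
  if (any(lengths(groups) < 5L)) {
    abort("each group needs at least 5 trials")
  }
  if (all(vapply(groups, function(x) var(x) == 0, logical(1))) ||
      anyNA(vapply(groups, var, numeric(1)))) {
    return(structure(FALSE, flagged = TRUE))
  }
  df <- data.frame(rate = unlist(groups, use.names = FALSE),
                   grp = factor(rep(names(groups), lengths(groups)),
                                levels = names(groups)))
  fit <- aov(rate ~ grp, data = df)
  tk <- TukeyHSD(fit)$grp
  p <- tk[c("stim_a-baseline", "stim_b-baseline"), "p adj"]
  structure(any(p < alpha, na.rm = TRUE), flagged = FALSE)
}

#' Stimulus preference from the mean response-window bias
#'
#' The mean stimulus bias within the 300 ms window following touch onset
#' determines the preference: `"positive"` if > 0, `"negative"` if < 0, and
#' `"none"` (flagged tie) if exactly 0.
#'
#' @param mean_response_bias Numeric vector of per-unit mean response-window
#'   bias values (see [summarize_bias()]).
#' @return Character vector in `{"positive", "negative", "none"}`.
#' @export
classify_preference <- function(mean_response_bias) {
  out <- ifelse(mean_response_bias > 0, "positive",
                ifelse(mean_response_bias < 0, "negative", "none"))
  out[is.na(mean_response_bias)] <- "none"
  out
}

#' Touch facilitation or suppression
#'
#' Paired two-sided t-test of per-trial response-window rates against the
#' matched baseline-window rates at level `alpha`; the sign of the mean
#' difference labels the unit `"facilitated"` or `"suppressed"`, otherwise
#' `"neither"`. Zero-variance differences return `"neither"` flagged.
#'
#' @param response,baseline Numeric vectors of per-trial rates on the same
#'   trials (at least 5).
#' @param alpha Significance level.
#' @return Character scalar with attribute `flagged`.
#' @export
classify_touch_effect <- function(response, baseline, alpha = 0.05) {
  ok <- !is.na(response) & !is.na(baseline)
  response <- response[ok]; baseline <- baseline[ok]
  if (length(response) < 5L) abort("at least 5 trials required")
  diffs <- response - baseline
  if (var(diffs) == 0) {
    return(structure("neither", flagged = TRUE))
  }
  p <- t.test(diffs)$p.value
  out <- if (p < alpha) {
    if (mean(diffs) > 0) "facilitated" else "suppressed"
  } else "neither"
  structure(out, flagged = FALSE)
}

#' Classify every unit of a session
#'
#' Runs the full per-unit classification used by the population analyses:
#' responsiveness (ANOVA + Tukey of baseline vs either stimulus),
#' stimulus preference (sign of the mean response-window bias between
#' positive- and negative-stimulus engaged trials), touch effect on
#' negative-stimulus trials (facilitated/suppressed vs baseline, paired
#' t-test) and the baseline firing rate (mean rate in the 1.5 s preceding
#' first touch over engaged trials).
#'
#' @param session A [wb_session()].
#' @param tensor Optional precomputed non-z-scored [rate_tensor()] at the
#'   bias-bin width covering baseline and response windows.
#' @param windows [analysis_windows()].
#' @param alpha Significance level for responsiveness and touch effect.
#' @param engaged Logical trial mask used for preference/baseline estimates
#'   (default [engaged_trials()] after [filter_disengaged_cr()]).
#' @return Tibble of class `wb_unit_classes`: `unit_id`, `region`,
#'   `mouse_id`, `responsive`, `preference`, `touch_effect`, `baseline_rate`,
#'   `mean_response_bias`.
#' @export
classify_units <- function(session, tensor = NULL,
                           windows = analysis_windows(), alpha = 0.05,
                           engaged = NULL) {
  if (is.null(tensor)) {
    tensor <- rate_tensor(session, window = c(windows$baseline[1],
                                              windows$response[2]),
                          bin = windows$bias_bin)
  }
  tr <- session$trials
  if (is.null(engaged)) {
    kept <- filter_disengaged_cr(tr)
    engaged <- tr$trial_id %in% kept$trial_id & engaged_trials(tr)
  }
  pos <- engaged & tr$stimulus == "positive"
  neg <- engaged & tr$stimulus == "negative"
  # touch effect is assessed on all retained CR trials (both contexts): the
  # negative-stimulus response is what is being tested against baseline
  kept_ids <- filter_disengaged_cr(tr)$trial_id
  cr_all <- tr$trial_id %in% kept_ids & tr$outcome == "CR"
  base <- window_rate(tensor, windows$baseline)
  resp <- window_rate(tensor, windows$response)
  bias <- stimulus_bias(tensor, pos, neg, windows = windows)
  bsum <- summarize_bias(bias, windows)
  bsum <- bsum[match(tensor$unit_ids, bsum$unit_id), ]

  nu <- length(tensor$unit_ids)
  responsive <- logical(nu); eff <- character(nu)
  have_cr <- sum(cr_all) >= 5L  # detection sessions have no CR trials
  for (i in seq_len(nu)) {
    responsive[i] <- as.logical(classify_responsive(
      base[i, engaged], resp[i, pos], resp[i, neg], alpha = alpha))
    eff[i] <- if (have_cr) {
      as.character(classify_touch_effect(resp[i, cr_all], base[i, cr_all],
                                         alpha = alpha))
    } else "neither"
  }
  preference <- classify_preference(bsum$mean_response)
  preference[!responsive] <- "none"
  out <- tibble::tibble(
    unit_id = tensor$unit_ids,
    region = session$units$region,
    mouse_id = session$units$mouse_id,
    responsive = responsive,
    preference = preference,
    touch_effect = eff,
    baseline_rate = rowMeans(base[, engaged, drop = FALSE], na.rm = TRUE),
    mean_response_bias = bsum$mean_response)
  class(out) <- c("wb_unit_classes", class(out))
  out
}

#' Group units by baseline firing rate
#'
#' Partitions units into half-open rate intervals defined by strictly
#' decreasing `edges`: with `edges = c(10, 5, 1)` the groups are
#' `bfr >= 10`, `10 > bfr >= 5`, `5 > bfr >= 1` and `bfr < 1`. A unit sitting
#' exactly on an edge falls in the group whose lower bound it equals.
#'
#' @param classes A [classify_units()] tibble (or any tibble with
#'   `baseline_rate`).
#' @param edges Strictly decreasing positive thresholds, sp/s.
#' @return `classes` with an ordered factor column `baseline_group`.
#' @export
group_by_baseline_rate <- function(classes, edges = c(10, 5, 1)) {
  if (is.unsorted(rev(edges), strictly = TRUE)) {
    abort("edges must be strictly decreasing")
  }
  brk <- c(-Inf, rev(edges), Inf)
  labs <- character(length(edges) + 1L)
  labs[1] <- paste0("bfr<", rev(edges)[1])
  if (length(edges) > 1L) {
    for (k in seq_len(length(edges) - 1L)) {
      lo <- rev(edges)[k]; hi <- rev(edges)[k + 1L]
      labs[k + 1L] <- paste0(hi, ">bfr>=", lo)
    }
  }
  labs[length(labs)] <- paste0("bfr>=", edges[1])
  g <- cut(classes$baseline_rate, breaks = brk, labels = labs,
           right = FALSE, ordered_result = TRUE)
  classes$baseline_group <- g
  classes
}

#' Per-group mean and SEM of a unit-level value
#'
#' Summarises a per-unit quantity (evoked rate, bias, ...) within baseline
#' firing-rate groups. Empty groups are reported with `n = 0`, not dropped.
#'
#' @param classes Output of [group_by_baseline_rate()].
#' @param values Tibble with `unit_id` and a `value` column to summarise.
#' @return Tibble `baseline_group`, `n`, `mean`, `sem`.
#' @export
baseline_group_summary <- function(classes, values) {
  joined <- dplyr::left_join(classes, values, by = "unit_id")
  joined |>
    dplyr::group_by(.data$baseline_group, .drop = FALSE) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sem = sd(.data$value, na.rm = TRUE) / sqrt(max(sum(!is.na(.data$value)), 1)),
      .groups = "drop")
}

#' Population preference statistics
#'
#' The fraction of preference-labeled units preferring the positive stimulus,
#' a goodness-of-fit chi-squared against an equal split, and (when at least
#' two mice contribute) a homogeneity chi-squared over the mouse-by-preference
#' contingency table.
#'
#' @param classes A [classify_units()] tibble restricted to the units of
#'   interest (units with `preference == "none"` are dropped).
#' @return One-row tibble: `n_positive`, `n_total`, `fraction_positive`,
#'   `p_equal_split`, `p_mouse_homogeneity` (`NA` and flagged for a single
#'   mouse).
#' @export
population_preference_stats <- function(classes) {
  cl <- classes[classes$preference %in% c("positive", "negative"), ]
  if (nrow(cl) < 2L) abort("need at least 2 preference-labeled units")
  n_pos <- sum(cl$preference == "positive")
  n_tot <- nrow(cl)
  gof <- suppressWarnings(chisq.test(c(n_pos, n_tot - n_pos), p = c(0.5, 0.5)))
  mice <- unique(cl$mouse_id)
  if (length(mice) >= 2L) {
    tab <- table(cl$mouse_id, cl$preference)
    hom <- suppressWarnings(chisq.test(tab))$p.value
    single <- FALSE
  } else {
    hom <- NA_real_
    single <- TRUE
  }
  tibble::tibble(n_positive = n_pos, n_total = n_tot,
                 fraction_positive = n_pos / n_tot,
                 p_equal_split = gof$p.value,
                 p_mouse_homogeneity = hom,
                 single_mouse = single)
}
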