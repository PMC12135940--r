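#' Occupancy-matched resampling plan
#'
#' Behavioral covariates (run speed, curvature, touch rate) can differ
#' between conditions and confound rate comparisons. This control bins the
#' pooled joint feature space, then within every jointly occupied cell
#' subsamples each condition without replacement down to the smaller count,
#' so the retained trials of both conditions share the same joint feature
#' histogram. `n_perm` independent plans are drawn; downstream statistics are
#' computed per plan and averaged.
#'
#' @param trials_a,trials_b Trial tibbles for the two conditions.
#' @param features Feature column names present in both tibbles.
#' @param n_bins Bins per feature over the pooled range.
#' @param n_perm Number of resampling permutations.
#' @return Object of class `wb_occupancy`: list with `plans` (list of
#'   `n_perm` lists, each holding integer row indices `a` and `b` into the
#'   input tibbles), `features`, `n_bins`.
#' @export
occupancy_match <- function(trials_a, trials_b,
                            features = c("run_speed", "curvature"),
                            n_bins = 8, n_perm = 20) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  fa <- as.matrix(trials_a[, features, drop = FALSE])
  fb <- as.matrix(trials_b[, features, drop = FALSE])
  if (!all(is.finite(fa)) || !all(is.finite(fb))) {
    abort("feature values must be finite")
  }
  cell_a <- rep(0, nrow(fa)); cell_b <- rep(0, nrow(fb))
  for (k in seq_along(features)) {
    rng <- range(c(fa[, k], fb[, k]))
    brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    brk[length(brk)] <- brk[length(brk)] + 1e-9  # right-open top bin
    ia <- findInterval(fa[, k], brk, rightmost.closed = TRUE)
    ib <- findInterval(fb[, k], brk, rightmost.closed = TRUE)
    cell_a <- cell_a * n_bins + (ia - 1L)
    cell_b <- cell_b * n_bins + (ib - 1L)
  }
  common <- intersect(unique(cell_a), unique(cell_b))
  if (!length(common)) abort("disjoint feature supports")
  plans <- lapply(seq_len(n_perm), function(p) {
    keep_a <- integer(0); keep_b <- integer(0)
    for (cell in common) {
      ia <- which(cell_a == cell); ib <- which(cell_b == cell)
      m <- min(length(ia), length(ib))
      keep_a <- c(keep_a, if (length(ia) == m) ia else sample(ia, m))
      keep_b <- c(keep_b, if (length(ib) == m) ib else sample(ib, m))
    }
    list(a = sort(keep_a), b = sort(keep_b))
  })
  structure(list(plans = plans, features = features, n_bins = n_bins),
            class = "wb_occupancy")
}

# per-unit Mann-Whitney comparison of two per-trial rate vectors
mw_modulation <- function(cond, ref) {
  cond <- cond[!is.na(cond)]; ref <- ref[!is.na(ref)]
  p <- suppressWarnings(wilcox.test(cond, ref, exact = FALSE)$p.value)
  c(delta = mean(cond) - mean(ref), p = p)
}

#' Behavioral-context modulation of unit rates
#'
#' Compares per-trial window rates between a condition and its reference —
#' `Hit_vs_Miss` (Miss trials at Home vs Hit trials) or `Home_vs_Away`
#' (positive-stimulus Away trials vs Hit trials) — per unit with a two-sided
#' Mann-Whitney U test, in either the evoked (0-300 ms) or the baseline
#' (-1.5-0 s) window. `delta_z` is the change in mean z-scored rate
#' (condition minus reference) on the shared engaged-trial baseline scale.
#' With an [occupancy_match()] plan, statistics are computed per permutation
#' on the retained trials and averaged. A one-sample t-test of `delta_z`
#' over units gives the population p-value.
#'
#' @param ztensor A z-scored [rate_tensor()] of the session.
#' @param session The session.
#' @param contrast `"Hit_vs_Miss"` or `"Home_vs_Away"`.
#' @param window `"evoked"` or `"baseline"`.
#' @param plan Optional `wb_occupancy` built on the same condition/reference
#'   trial tables (in the order condition = a, reference = b).
#' @param windows [analysis_windows()].
#' @param alpha Per-unit significance level.
#' @param min_trials Minimum trials per side; units below are excluded and
#'   counted.
#' @return Tibble of class `wb_modulation`: `unit_id`, `window`, `contrast`,
#'   `delta_z`, `p_unit`, `significant`; attributes `population_p`,
#'   `n_excluded`, `condition_trials`, `reference_trials`.
#' @export
condition_modulation <- function(ztensor, session,
                                 contrast = c("Hit_vs_Miss", "Home_vs_Away"),
                                 window = c("evoked", "baseline"),
                                 plan = NULL, windows = analysis_windows(),
                                 alpha = 0.05, min_trials = 5L) {
  contrast <- match.arg(contrast)
  window <- match.arg(window)
  if (!ztensor$zscored) abort("tensor must be z-scored")
  tr <- session$trials
  ref_idx <- which(tr$outcome == "Hit" & tr$context == "Home")
  cond_idx <- switch(contrast,
    Hit_vs_Miss = which(tr$outcome == "Miss" & tr$context == "Home"),
    Home_vs_Away = which(tr$stimulus == "positive" & tr$context == "Away"))
  iv <- if (window == "evoked") windows$response else windows$baseline
  rates <- window_rate(ztensor, iv)
  run_one <- function(ci, ri) {
    t(vapply(seq_len(nrow(rates)),
             function(u) mw_modulation(rates[u, ci], rates[u, ri]),
             numeric(2)))
  }
  if (is.null(plan)) {
    if (length(cond_idx) < min_trials || length(ref_idx) < min_trials) {
      abort(sprintf("fewer than %d trials on one side of %s", min_trials, contrast))
    }
    res <- run_one(cond_idx, ref_idx)
  } else {
    per <- lapply(plan$plans, function(p) {
      if (length(p$a) < min_trials || length(p$b) < min_trials) return(NULL)
      run_one(cond_idx[p$a], ref_idx[p$b])
    })
    per <- per[!vapply(per, is.null, logical(1))]
    if (!length(per)) abort("all matched plans fall below min_trials")
    res <- Reduce(`+`, per) / length(per)
  }
  out <- tibble::tibble(
    unit_id = ztensor$unit_ids, window = window, contrast = contrast,
    delta_z = res[, 1], p_unit = res[, 2],
    significant = res[, 2] < alpha)
  class(out) <- c("wb_modulation", class(out))
  pop <- t.test(out$delta_z)
  attr(out, "population_p") <- pop$p.value
  attr(out, "n_excluded") <- 0L
  attr(out, "condition_trials") <- length(cond_idx)
  attr(out, "reference_trials") <- length(ref_idx)
  out
}

#' @describeIn condition_modulation One-row population summary: fraction and
#'   count of significantly modulated units split by sign, and the
#'   population t-test p-value.
#' @param x A `wb_modulation`.
#' @param ... Unused.
#' @export
glance.wb_modulation <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast[1], window = x$window[1],
    n_units = nrow(x),
    n_significant = sum(x$significant),
    fraction_significant = mean(x$significant),
    n_decreased = sum(x$significant & x$delta_z < 0),
    n_increased = sum(x$significant & x$delta_z > 0),
    population_p = attr(x, "population_p"))
}

#' Fractions of modulated units
#'
#' Counts and fractions of significantly modulated units, split by sign of
#' the change, across one or more [condition_modulation()] results bound
#' together (grouping by region/contrast/window columns present).
#'
#' @param results A `wb_modulation` tibble or a row-bound combination,
#'   optionally with extra grouping columns (e.g. `region`).
#' @return Tibble with one row per contrast/window (/region) group:
#'   `n_units`, `n_significant`, `fraction_significant`, `n_decreased`,
#'   `n_increased`.
#' @export
modulation_fraction_report <- function(results) {
  if (!nrow(results)) abort("results must be nonempty")
  grp <- intersect(c("region", "contrast", "window"), names(results))
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      n_significant = sum(.data$significant),
      fraction_significant = mean(.data$significant),
      n_decreased = sum(.data$significant & .data$delta_z < 0),
      n_increased = sum(.data$significant & .data$delta_z > 0),
      .groups = "drop")
}
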