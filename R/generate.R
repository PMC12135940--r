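#' Configuration for the synthetic-session generator
#'
#' Builds the parameter set for [generate_session()]. Defaults emulate the
#' study conditions of a head-fixed Go/No-Go whisker task: two adjacent
#' single-whisker stimuli, touch-locked facilitation with delayed suppression
#' of the non-rewarded response in collicular-like populations, log-normal
#' baseline-rate heterogeneity, reduced evoked/baseline rates on Miss trials
#' and in the Away (water port displaced) condition alternated in blocks of
#' seven positive-stimulus trials, and lick latencies negatively coupled to a
#' per-trial engagement latent that also scales baseline rates.
#'
#' @param region_profile `"SC_like"` (deep superior colliculus: 70%
#'   positive-preferring, 60 ms facilitation-to-suppression delay, strong
#'   context modulation) or `"S1_like"` (barrel cortex: near-symmetric
#'   preference, 10 ms delay, weak Away modulation).
#' @param task `"discrimination"` (Go/No-Go; suppression of the negative
#'   stimulus active) or `"detection"` (Go/Go; suppression disabled, symmetric
#'   preference).
#' @param n_units,n_trials Session size.
#' @param frac_positive_preferring Fraction of units preferring the positive
#'   stimulus; `NULL` takes the profile default (SC_like discrimination 0.70,
#'   S1_like 0.42, detection 0.5).
#' @param baseline_median,baseline_sdlog Log-normal baseline firing-rate law
#'   (median sp/s and log-SD dispersion).
#' @param facil_onset,facil_rise,facil_decay Facilitation kernel timing,
#'   seconds: onset latency, exponential rise and decay of the alpha-like bump
#'   `(1 - exp(-x/rise)) * exp(-x/decay)`, peak-normalized.
#' @param facil_gain,facil_floor Preferred-stimulus kernel amplitude =
#'   `facil_gain * baseline + facil_floor` sp/s.
#' @param nonpref_gain Amplitude fraction for the non-preferred stimulus;
#'   `NULL` takes the profile default (SC_like 0.25, S1_like 0.15).
#' @param nonpref_decay Decay of the non-preferred response, seconds:
#'   non-preferred responses are both weaker and more transient than
#'   preferred ones, so the negative-stimulus response of a
#'   positive-preferring unit is a brief bump that the delayed, sustained
#'   suppression then pulls below baseline.
#' @param supp_delay Facilitation-to-suppression onset offset, seconds;
#'   `NULL` takes the profile default (SC_like 0.060, S1_like 0.010).
#' @param supp_depth Suppression amplitude as a fraction of baseline rate
#'   (depth scales with baseline; rates clip at zero).
#' @param supp_rise,supp_decay Suppression kernel timing, seconds; `NULL`
#'   takes the profile default (SC_like 0.012/0.250: sustained, slow-rising;
#'   S1_like 0.008/0.150: mirroring the facilitation dynamics).
#' @param miss_gain,away_evoked_gain,away_baseline_gain Multiplicative factors
#'   in (0, 1] applied to positive-preferring units on Miss / Away trials.
#' @param away_block Positive-stimulus trials per Home/Away block.
#' @param touch_rate_hz Whisk-contact rate during the stimulus window.
#' @param latency_intercept,latency_slope,latency_noise,latency_floor Lick
#'   latency model: `intercept - slope * engagement + Normal(0, noise)`
#'   seconds, clamped into the response window; under the defaults well over
#'   `latency_floor` = 0.3 s of latency is exceeded on at least 92% of trials.
#' @param p_miss,miss_coupling Baseline Miss probability on the logit scale
#'   and its (negative) coupling to the engagement latent.
#' @param p_fa False-alarm probability on Home negative-stimulus trials.
#' @param baseline_coupling Log-scale gain of per-trial baseline rate per unit
#'   of the engagement latent.
#' @param cov_rho,cov_sd AR(1) parameters for the run-speed and curvature
#'   trial covariates.
#' @param trial_duration,touch_offset Trial window length and first-touch time
#'   within the trial, seconds.
#' @param touch_adaptation Fraction of the evoked kernel applied to touches
#'   after the first (default 0: fully adapted after first touch).
#' @param dt Simulation grid resolution, seconds (at most 1 ms).
#' @param seed Default RNG seed for [generate_session()].
#'
#' @return A list of class `wb_generator_config`.
#' @export
generator_config <- function(region_profile = c("SC_like", "S1_like"),
                             task = c("discrimination", "detection"),
                             n_units = 60, n_trials = 200,
                             frac_positive_preferring = NULL,
                             baseline_median = 4, baseline_sdlog = 1,
                             facil_onset = 0.005, facil_rise = 0.008,
                             facil_decay = 0.250,
                             facil_gain = 1.5, facil_floor = 5,
                             nonpref_gain = NULL, nonpref_decay = 0.060,
                             supp_delay = NULL, supp_depth = 0.9,
                             supp_rise = NULL, supp_decay = NULL,
                             miss_gain = NULL, away_evoked_gain = NULL,
                             away_baseline_gain = NULL,
                             away_block = 7, touch_rate_hz = 10,
                             latency_intercept = 0.55, latency_slope = 0.06,
                             latency_noise = 0.12, latency_floor = 0.3,
                             p_miss = 0.15, miss_coupling = 1.5, p_fa = 0.10,
                             baseline_coupling = 0.2,
                             cov_rho = 0.7, cov_sd = 1,
                             trial_duration = 6, touch_offset = 2,
                             touch_adaptation = 0, dt = 0.001, seed = 1L) {
  region_profile <- match.arg(region_profile)
  task <- match.arg(task)
  sc <- region_profile == "SC_like"
  if (is.null(supp_delay)) supp_delay <- if (sc) 0.060 else 0.010
  # region-specific response shapes: collicular suppression is sustained and
  # slower-rising; cortical suppression mirrors the faster facilitation
  # dynamics, and the non-preferred transient is weaker
  if (is.null(nonpref_gain)) nonpref_gain <- if (sc) 0.25 else 0.15
  if (is.null(supp_rise)) supp_rise <- if (sc) 0.012 else 0.008
  if (is.null(supp_decay)) supp_decay <- if (sc) 0.250 else 0.150
  if (is.null(frac_positive_preferring)) {
    frac_positive_preferring <-
      if (task == "detection") 0.5 else if (sc) 0.70 else 0.42
  }
  if (is.null(miss_gain)) miss_gain <- if (sc) 0.5 else 0.7
  if (is.null(away_evoked_gain)) away_evoked_gain <- if (sc) 0.6 else 1.0
  if (is.null(away_baseline_gain)) away_baseline_gain <- if (sc) 0.7 else 1.0
  cfg <- mget(setdiff(names(formals()), c()), envir = environment())
  if (cfg$n_units < 1 || cfg$n_trials < 1) {
    abort("n_units and n_trials must be >= 1", class = "wb_config_error")
  }
  rates_ok <- c(cfg$baseline_median, cfg$facil_floor, cfg$touch_rate_hz) >= 0
  if (!all(rates_ok)) abort("rates must be >= 0", class = "wb_config_error")
  if (cfg$supp_delay < 0) abort("supp_delay must be >= 0", class = "wb_config_error")
  fr <- c(cfg$frac_positive_preferring, cfg$supp_depth, cfg$nonpref_gain,
          cfg$p_miss, cfg$p_fa)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]",
                                  class = "wb_config_error")
  gn <- c(cfg$miss_gain, cfg$away_evoked_gain, cfg$away_baseline_gain)
  if (any(gn <= 0 | gn > 1)) abort("context gains must lie in (0, 1]",
                                   class = "wb_config_error")
  if (cfg$away_block < 1) abort("away_block must be >= 1", class = "wb_config_error")
  if (cfg$dt > 0.001 + 1e-12) abort("dt must be <= 1 ms", class = "wb_config_error")
  structure(cfg, class = "wb_generator_config")
}

# peak-normalized alpha-like bump on a time grid (x relative to kernel onset)
evoked_kernel <- function(x, rise, decay) {
  k <- ifelse(x > 0, (1 - exp(-x / rise)) * exp(-x / decay), 0)
  xpk <- rise * log1p(decay / rise)
  kpk <- (1 - exp(-xpk / rise)) * exp(-xpk / decay)
  k / kpk
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' The rate function is discretized to a piecewise-constant intensity on a
#' grid of width `dt`; candidate events are drawn homogeneously at the grid
#' maximum and accepted with probability `rate(t) / rate_max` (exact for the
#' discretized intensity).
#'
#' @param rate_fn Function of time returning intensity in sp/s (vectorized).
#' @param t_span Length-2 interval, seconds.
#' @param dt Grid resolution, seconds (at most 1 ms).
#' @return Sorted numeric vector of spike times.
#' @examples
#' set.seed(1)
#' poisson_thinning(function(t) 10 + 5 * sin(2 * pi * t), c(0, 10))
#' @export
poisson_thinning <- function(rate_fn, t_span, dt = 0.001) {
  if (dt > 0.001 + 1e-12) abort("dt must be <= 1 ms", class = "wb_config_error")
  grid <- seq(t_span[1], t_span[2], by = dt)
  mids <- grid[-length(grid)] + dt / 2
  rate <- rate_fn(mids)
  if (any(rate < 0)) abort("negative rate encountered", class = "wb_generation_error")
  thin_spikes(rate, dt, t0 = t_span[1])
}

# core thinning on a piecewise-constant rate vector (rate[i] on bin i of width dt)
thin_spikes <- function(rate, dt, t0 = 0) {
  rmax <- max(rate)
  if (!is.finite(rmax) || rmax <= 0) return(numeric(0))
  span <- length(rate) * dt
  n_cand <- rpois(1L, rmax * span)
  if (n_cand == 0L) return(numeric(0))
  cand <- sort(runif(n_cand, 0, span))
  idx <- pmin.int(floor(cand / dt) + 1L, length(rate))
  keep <- runif(n_cand) < rate[idx] / rmax
  t0 + cand[keep]
}

#' Generate a synthetic session with ground truth
#'
#' Simulates one recording: unit baseline rates are drawn log-normally; each
#' unit is assigned a stimulus preference; trials get stimuli, Home/Away
#' contexts (alternating after every `away_block` positive-stimulus trials),
#' outcomes, lick latencies, covariates, and touch times; spike trains are
#' drawn from an inhomogeneous Poisson process (thinning on a 1 ms grid) whose
#' intensity is baseline + a touch-locked facilitation kernel and, for
#' positive-preferring units on negative-stimulus trials of the discrimination
#' task, a suppression kernel starting `supp_delay` after facilitation onset,
#' clipped at zero. All stochastic draws consume one RNG stream seeded from
#' `seed`, in a fixed documented order (baselines, preferences, stimuli,
#' engagement, outcomes, latencies, covariates, touches, then spikes
#' unit-by-unit), so identical `(config, seed)` yield identical sessions.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed (defaults to `config$seed`).
#' @return A list with elements `session` ([wb_session()]) and `truth`
#'   (class `wb_ground_truth`: per-unit labels/parameters and per-trial
#'   latents for recovery tests).
#' @export
generate_session <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "wb_generator_config"))
  set.seed(as.integer(seed))
  cf <- config
  nu <- cf$n_units; nt <- cf$n_trials
  mouse <- paste0("m", seed)

  # 1) baselines, 2) preferences
  baseline <- cf$baseline_median * exp(cf$baseline_sdlog * rnorm(nu))
  n_pos <- round(cf$frac_positive_preferring * nu)
  pref <- sample(rep(c("positive", "negative"), c(n_pos, nu - n_pos)))

  # 3) stimuli, contexts (blocks of away_block positive-stimulus trials)
  stimulus <- ifelse(runif(nt) < 0.5, "positive", "negative")
  context <- character(nt); cur <- "Home"; pos_seen <- 0L
  for (t in seq_len(nt)) {
    context[t] <- cur
    if (stimulus[t] == "positive") {
      pos_seen <- pos_seen + 1L
      if (pos_seen == cf$away_block) {
        cur <- if (cur == "Home") "Away" else "Home"
        pos_seen <- 0L
      }
    }
  }

  # 4) engagement latent, 5) outcomes
  engagement <- rnorm(nt)
  u_out <- runif(nt)
  outcome <- character(nt)
  for (t in seq_len(nt)) {
    rewarded <- stimulus[t] == "positive" || cf$task == "detection"
    if (rewarded) {
      if (context[t] == "Away") {
        outcome[t] <- "Miss"  # port removed: no lick possible
      } else {
        pm <- plogis(stats::qlogis(cf$p_miss) - cf$miss_coupling * engagement[t])
        outcome[t] <- if (u_out[t] < pm) "Miss" else "Hit"
      }
    } else {
      outcome[t] <- if (context[t] == "Home" && u_out[t] < cf$p_fa) "FA" else "CR"
    }
  }

  # 6) latencies (consumed for every trial to keep the stream order fixed)
  lat_noise <- rnorm(nt, 0, cf$latency_noise)
  rw <- 1.5
  latency <- cf$latency_intercept - cf$latency_slope * engagement + lat_noise
  latency <- pmin(pmax(latency, 0.05), rw - 0.02)
  latency[!outcome %in% c("Hit", "FA")] <- NA_real_

  # 7) covariates (AR(1) across trials; run speed shares the engagement latent)
  ar1 <- function(n, rho, sd_innov) {
    x <- numeric(n); x[1] <- rnorm(1, 0, sd_innov / sqrt(1 - rho^2))
    for (i in seq_len(n - 1L)) x[i + 1L] <- rho * x[i] + rnorm(1, 0, sd_innov)
    x
  }
  run_speed <- 2 + 0.5 * ar1(nt, cf$cov_rho, cf$cov_sd) + 0.3 * engagement
  curvature <- 0.005 + 0.002 * ar1(nt, cf$cov_rho, cf$cov_sd)

  # 8) touch times: first touch at a fixed offset, later contacts at the whisk
  #    rate through the 1.5 s stimulus window
  trial_start <- (seq_len(nt) - 1L) * cf$trial_duration
  first_touch <- trial_start + cf$touch_offset
  touch_times <- vector("list", nt)
  for (t in seq_len(nt)) {
    tt <- first_touch[t]
    if (cf$touch_rate_hz > 0) {
      gaps <- cumsum(stats::rexp(ceiling(2 * cf$touch_rate_hz * rw) + 2,
                                 cf$touch_rate_hz))
      tt <- c(tt, first_touch[t] + gaps[gaps < rw])
    }
    touch_times[[t]] <- tt
  }
  lick_times <- vector("list", nt)
  for (t in seq_len(nt)) {
    lick_times[[t]] <- if (outcome[t] %in% c("Hit", "FA")) {
      first_touch[t] + latency[t] + c(0, 0.12, 0.26)
    } else numeric(0)
  }

  # 9) spike trains (unit-by-unit, thinning over the whole session grid)
  ticks <- round(cf$trial_duration / cf$dt)
  kern_len <- ticks - round(cf$touch_offset / cf$dt)
  xg <- (seq_len(kern_len) - 0.5) * cf$dt
  k_fac <- evoked_kernel(xg - cf$facil_onset, cf$facil_rise, cf$facil_decay)
  k_non <- evoked_kernel(xg - cf$facil_onset, cf$facil_rise, cf$nonpref_decay)
  k_sup <- evoked_kernel(xg - cf$facil_onset - cf$supp_delay,
                         cf$supp_rise, cf$supp_decay)
  touch_idx <- round(cf$touch_offset / cf$dt)
  base_gain <- exp(cf$baseline_coupling * engagement -
                   cf$baseline_coupling^2 / 2)
  suppression_on <- cf$task == "discrimination"

  spikes <- vector("list", nu)
  amp_ev <- cf$facil_gain * baseline + cf$facil_floor
  amp_sup_unit <- cf$supp_depth * baseline
  for (i in seq_len(nu)) {
    rate <- numeric(nt * ticks)
    for (t in seq_len(nt)) {
      b <- baseline[i] * base_gain[t]
      if (context[t] == "Away" && pref[i] == "positive") {
        b <- b * cf$away_baseline_gain
      }
      preferred <- stimulus[t] == pref[i]
      amp <- amp_ev[i] * if (preferred) 1 else cf$nonpref_gain
      k_ev <- if (preferred) k_fac else k_non
      if (pref[i] == "positive" && stimulus[t] == "positive") {
        if (context[t] == "Away") amp <- amp * cf$away_evoked_gain
        else if (outcome[t] == "Miss") amp <- amp * cf$miss_gain
      }
      sup <- if (suppression_on && pref[i] == "positive" &&
                 stimulus[t] == "negative") amp_sup_unit[i] else 0
      seg <- rep(b, ticks)
      ev <- amp * k_ev - sup * k_sup
      if (cf$touch_adaptation > 0 && length(touch_times[[t]]) > 1L) {
        for (tt in touch_times[[t]][-1L]) {
          off <- round((tt - trial_start[t]) / cf$dt)
          len <- ticks - off
          if (len > 0) {
            pad <- c(rep(0, off - touch_idx),
                     cf$touch_adaptation * (amp * k_ev - sup * k_sup))
            ev <- ev + pad[seq_len(kern_len)]
          }
        }
      }
      seg[(touch_idx + 1L):ticks] <- seg[(touch_idx + 1L):ticks] + ev
      rate[((t - 1L) * ticks + 1L):(t * ticks)] <- seg
    }
    spikes[[i]] <- thin_spikes(pmax(rate, 0), cf$dt)
  }

  units <- tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(nu)),
    region = if (cf$region_profile == "SC_like") "SC" else "S1",
    mouse_id = mouse, depth_um = NA_real_, shank = NA_integer_,
    spike_times = spikes)
  trials <- tibble::tibble(
    trial_id = seq_len(nt), stimulus = stimulus, outcome = outcome,
    context = context, first_touch = first_touch,
    touch_times = touch_times, lick_times = lick_times,
    run_speed = run_speed, curvature = curvature, response_window = rw)
  session <- wb_session(units, trials, task = cf$task)

  truth <- structure(list(
    units = tibble::tibble(
      unit_id = units$unit_id, preference = pref, baseline_rate = baseline,
      evoked_amp = amp_ev, supp_amp = ifelse(pref == "positive" & suppression_on,
                                             amp_sup_unit, 0),
      context_modulated = pref == "positive"),
    trials = tibble::tibble(
      trial_id = seq_len(nt), engagement = engagement, latency = latency,
      stimulus = stimulus, outcome = outcome, context = context),
    config = unclass(cf), seed = as.integer(seed)),
    class = "wb_ground_truth")
  list(session = session, truth = truth)
}

#' Write a ground-truth record as JSON
#'
#' @param truth A `wb_ground_truth` from [generate_session()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(units = truth$units, trials = truth$trials,
         config = truth$config, seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
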