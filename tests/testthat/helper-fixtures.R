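# shared fixtures, built in code at test time

# hand-made 2-unit, 3-trial discrimination session
tiny_session <- function() {
  units <- tibble::tibble(
    unit_id = c("uA", "uB"),
    region = "SC",
    mouse_id = "m0",
    depth_um = c(1200, 1350),
    shank = c(1L, 2L),
    spike_times = list(c(0.5, 1.25, 2.0, 7.3), c(0.1, 6.05, 6.051)))
  trials <- tibble::tibble(
    trial_id = 1:3,
    stimulus = c("positive", "negative", "positive"),
    outcome = c("Hit", "CR", "Miss"),
    context = c("Home", "Home", "Home"),
    first_touch = c(2.0, 6.0, 10.0),
    touch_times = list(c(2.0, 2.2), c(6.0, 6.1, 6.3), 10.0),
    lick_times = list(c(2.6, 2.8), numeric(0), numeric(0)),
    run_speed = c(1.5, 2.0, 0.5),
    curvature = c(0.004, 0.006, 0.005),
    response_window = 1.5)
  wb_session(units, trials)
}

# fabricate a rate tensor directly from an array (values in sp/s or z-units)
make_tensor <- function(values, window = c(-1.5, 0.3), bin = 0.01,
                        zscored = FALSE) {
  n_bins <- dim(values)[3]
  stopifnot(abs(n_bins * bin - diff(window)) < 1e-9)
  structure(list(values = values,
                 bin_edges = window[1] + bin * (0:n_bins),
                 unit_ids = sprintf("u%03d", seq_len(dim(values)[1])),
                 trial_ids = seq_len(dim(values)[2]),
                 alignment = "first_touch", zscored = zscored,
                 baseline_stats = NULL),
            class = "wb_rate_tensor")
}

# minimal trial table for functions that only need a few fields
make_trials <- function(outcome,
                        stimulus = ifelse(outcome %in% c("Hit", "Miss"),
                                          "positive", "negative"),
                        context = "Home") {
  n <- length(outcome)
  first_touch <- 2 + 6 * (seq_len(n) - 1)
  tibble::tibble(
    trial_id = seq_len(n), stimulus = stimulus, outcome = outcome,
    context = context, first_touch = first_touch,
    touch_times = as.list(first_touch),
    lick_times = lapply(seq_len(n), function(i) {
      if (outcome[i] %in% c("Hit", "FA")) first_touch[i] + 0.5 else numeric(0)
    }),
    run_speed = 1, curvature = 0.005, response_window = 1.5)
}

# sessions reused across acceptance checks (generated once per test run)
.wb_cache <- new.env(parent = emptyenv())

cached_sessions <- function(profile, seeds = 11:15) {
  key <- paste0(profile, "_", paste(seeds, collapse = "-"))
  if (is.null(.wb_cache[[key]])) {
    .wb_cache[[key]] <- lapply(seeds, function(sd) {
      generate_session(generator_config(region_profile = profile), seed = sd)
    })
  }
  .wb_cache[[key]]
}
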