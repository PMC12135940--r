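#' Construct a recording session
#'
#' A session bundles the sorted units and the behavioral trial table of one
#' recording. Times are in seconds, zero-referenced to session start; per-trial
#' alignment (e.g., to first touch) is computed on demand and never stored.
#'
#' @param units Tibble with columns `unit_id`, `region` (`"SC"` or `"S1"`),
#'   `mouse_id`, `spike_times` (list-column of nondecreasing numeric vectors,
#'   seconds), and optionally `depth_um`, `shank`.
#' @param trials Tibble with columns `trial_id`, `stimulus`
#'   (`"positive"`/`"negative"`; aliases `"whisker1"`/`"whisker2"` are accepted
#'   for the detection task and mapped to positive/negative slot order),
#'   `outcome` (`"Hit"`, `"Miss"`, `"CR"`, `"FA"`), `context`
#'   (`"Home"`/`"Away"`), `first_touch`, list-columns `touch_times` and
#'   `lick_times`, covariates `run_speed` and `curvature`, and
#'   `response_window` (seconds, default 1.5).
#' @param task `"discrimination"` (Go/No-Go) or `"detection"` (Go/Go).
#' @param sampling_dt Spike-time resolution in seconds (20 kHz acquisition
#'   gives 5e-5).
#' @param validate Check invariants (default `TRUE`).
#'
#' @return An object of class `wb_session`.
#' @seealso [read_session()], [generate_session()]
#' @export
wb_session <- function(units, trials, task = c("discrimination", "detection"),
                       sampling_dt = 5e-5, validate = TRUE) {
  task <- match.arg(task)
  units <- tibble::as_tibble(units)
  trials <- tibble::as_tibble(trials)
  if (!"response_window" %in% names(trials)) trials$response_window <- 1.5
  alias <- c(whisker1 = "positive", whisker2 = "negative")
  hit <- trials$stimulus %in% names(alias)
  trials$stimulus[hit] <- alias[trials$stimulus[hit]]
  s <- structure(list(units = units, trials = trials, task = task,
                      sampling_dt = sampling_dt),
                 class = "wb_session")
  if (validate) validate_session(s)
  s
}

#' @export
print.wb_session <- function(x, ...) {
  cat(sprintf("<wb_session> %s task: %d units (%s), %d trials, %d mouse/mice\n",
              x$task, nrow(x$units),
              paste(unique(x$units$region), collapse = "/"),
              nrow(x$trials), length(unique(x$units$mouse_id))))
  invisible(x)
}

#' Validate session invariants
#'
#' Checks the structural invariants of a [wb_session()]: required columns,
#' sorted nonnegative spike times, outcome/stimulus consistency (in the
#' discrimination task Hit/Miss pair with the positive stimulus, CR/FA with the
#' negative one), lick presence/absence consistent with the outcome, and
#' `first_touch == min(touch_times)`. Violations raise an error naming the
#' offending unit or trial; nothing is silently repaired.
#'
#' @param session A `wb_session`.
#' @return `session`, invisibly, if valid.
#' @export
validate_session <- function(session) {
  u <- session$units
  tr <- session$trials
  need_u <- c("unit_id", "region", "mouse_id", "spike_times")
  miss <- setdiff(need_u, names(u))
  if (length(miss)) abort(paste0("units table missing column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "wb_schema_error")
  need_t <- c("trial_id", "stimulus", "outcome", "context", "first_touch",
              "touch_times", "lick_times", "run_speed", "curvature",
              "response_window")
  miss <- setdiff(need_t, names(tr))
  if (length(miss)) abort(paste0("trials table missing column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "wb_schema_error")
  if (anyDuplicated(u$unit_id)) abort("duplicate unit_id in units table",
                                      class = "wb_validation_error")
  bad <- !u$region %in% c("SC", "S1")
  if (any(bad)) abort(paste0("unit ", u$unit_id[which(bad)[1]],
                             ": region must be 'SC' or 'S1'"),
                      class = "wb_validation_error")
  for (i in seq_len(nrow(u))) {
    st <- u$spike_times[[i]]
    if (length(st)) {
      if (is.unsorted(st)) {
        abort(paste0("unit ", u$unit_id[i], ": spike times are not nondecreasing"),
              class = "wb_validation_error")
      }
      if (st[1] < 0) abort(paste0("unit ", u$unit_id[i], ": negative spike time"),
                           class = "wb_validation_error")
    }
  }
  if (!all(tr$stimulus %in% c("positive", "negative"))) {
    abort("stimulus must be 'positive'/'negative' (or whisker1/whisker2 alias)",
          class = "wb_validation_error")
  }
  if (!all(tr$outcome %in% c("Hit", "Miss", "CR", "FA"))) {
    abort("outcome must be one of Hit, Miss, CR, FA", class = "wb_validation_error")
  }
  if (!all(tr$context %in% c("Home", "Away"))) {
    abort("context must be 'Home' or 'Away'", class = "wb_validation_error")
  }
  for (i in seq_len(nrow(tr))) {
    id <- tr$trial_id[i]
    tt <- tr$touch_times[[i]]
    if (length(tt) && abs(tr$first_touch[i] - min(tt)) > 1e-9) {
      abort(paste0("trial ", id, ": first_touch does not equal min(touch_times)"),
            class = "wb_validation_error")
    }
    if (session$task == "discrimination") {
      pos_out <- tr$outcome[i] %in% c("Hit", "Miss")
      pos_stim <- tr$stimulus[i] == "positive"
      if (pos_out != pos_stim) {
        abort(paste0("trial ", id, ": outcome ", tr$outcome[i],
                     " inconsistent with stimulus ", tr$stimulus[i]),
              class = "wb_validation_error")
      }
    }
    lk <- tr$lick_times[[i]]
    rw <- c(tr$first_touch[i], tr$first_touch[i] + tr$response_window[i])
    lick_in <- length(lk) && any(lk >= rw[1] & lk < rw[2])
    if (tr$outcome[i] %in% c("Hit", "FA") && !lick_in) {
      abort(paste0("trial ", id, ": outcome ", tr$outcome[i],
                   " requires a lick inside the response window"),
            class = "wb_validation_error")
    }
    if (tr$outcome[i] %in% c("Miss", "CR") && lick_in) {
      abort(paste0("trial ", id, ": outcome ", tr$outcome[i],
                   " forbids licks inside the response window"),
            class = "wb_validation_error")
    }
  }
  if (length(unique(u$mouse_id)) > 1L) {
    abort("all units in a session must share one mouse_id",
          class = "wb_validation_error")
  }
  invisible(session)
}

# encode/decode semicolon-delimited event lists inside single CSV cells
encode_times <- function(x) {
  vapply(x, function(v) paste(sprintf("%.17g", v), collapse = ";"), character(1))
}

decode_times <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0) else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Read a session from disk
#'
#' `spike_path` may be either (a) a delimited text file with columns
#' `unit_id`, `spike_time_s`, `region`, `mouse_id` (optional `depth_um`,
#' `shank`), one row per spike, or (b) a Kilosort/Phy-style sorted-output
#' directory containing `spike_times.npy` (sample indices),
#' `spike_clusters.npy` and a `params.py` sidecar stating `sample_rate`;
#' for a directory, `region` and `mouse_id` must be supplied. `trial_path` is
#' a CSV with one row per trial; event-time lists (`touch_times`,
#' `lick_times`) are semicolon-delimited within their cell.
#'
#' @param spike_path Spike file or Phy directory.
#' @param trial_path Trial CSV.
#' @param task,sampling_dt See [wb_session()].
#' @param region,mouse_id Required when `spike_path` is a Phy directory.
#' @return A validated [wb_session()].
#' @export
read_session <- function(spike_path, trial_path,
                         task = c("discrimination", "detection"),
                         sampling_dt = 5e-5, region = NULL, mouse_id = NULL) {
  task <- match.arg(task)
  if (dir.exists(spike_path)) {
    if (is.null(region) || is.null(mouse_id)) {
      abort("region and mouse_id must be given when reading a Phy directory")
    }
    spk <- read_phy_dir(spike_path)
    spk$region <- region
    spk$mouse_id <- mouse_id
  } else {
    # read as text and convert through strtod: exact for 17-digit output
    spk <- readr::read_csv(spike_path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    need <- c("unit_id", "spike_time_s", "region", "mouse_id")
    miss <- setdiff(need, names(spk))
    if (length(miss)) abort(paste0("spike table missing column(s): ",
                                   paste(miss, collapse = ", ")),
                            class = "wb_schema_error")
    spk$spike_time_s <- as.numeric(spk$spike_time_s)
    if ("depth_um" %in% names(spk)) spk$depth_um <- as.numeric(spk$depth_um)
    if ("shank" %in% names(spk)) spk$shank <- as.integer(spk$shank)
  }
  units <- spk |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      region = .data$region[1], mouse_id = .data$mouse_id[1],
      depth_um = if ("depth_um" %in% names(spk)) .data$depth_um[1] else NA_real_,
      shank = if ("shank" %in% names(spk)) .data$shank[1] else NA_integer_,
      spike_times = list(.data$spike_time_s), .groups = "drop")

  tr <- readr::read_csv(trial_path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("trial_id", "stimulus", "outcome", "context", "first_touch",
            "touch_times", "lick_times", "run_speed", "curvature")
  miss <- setdiff(need, names(tr))
  if (length(miss)) abort(paste0("trials table missing column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "wb_schema_error")
  tr$trial_id <- as.integer(tr$trial_id)
  for (nm in intersect(c("first_touch", "run_speed", "curvature",
                         "response_window"), names(tr))) {
    tr[[nm]] <- as.numeric(tr[[nm]])
  }
  tr$touch_times <- decode_times(tr$touch_times)
  tr$lick_times <- decode_times(tr$lick_times)
  wb_session(units, tr, task = task, sampling_dt = sampling_dt)
}

#' Write a session to disk
#'
#' Writes `spikes.csv` (long format, one row per spike) and `trials.csv`
#' (one row per trial, event lists semicolon-delimited) into `dir`. The pair
#' round-trips through [read_session()] with bitwise-equal event times for
#' every unit that has at least one spike (the long spike format cannot
#' represent a spike-less unit).
#'
#' @param session A `wb_session`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  u <- session$units
  spikes <- tibble::tibble(
    unit_id = rep(u$unit_id, lengths(u$spike_times)),
    spike_time_s = unlist(u$spike_times, use.names = FALSE),
    region = rep(u$region, lengths(u$spike_times)),
    mouse_id = rep(u$mouse_id, lengths(u$spike_times)),
    depth_um = rep(if ("depth_um" %in% names(u)) u$depth_um else NA_real_,
                   lengths(u$spike_times)),
    shank = rep(if ("shank" %in% names(u)) u$shank else NA_integer_,
                lengths(u$spike_times)))
  tr <- session$trials
  tr$touch_times <- encode_times(tr$touch_times)
  tr$lick_times <- encode_times(tr$lick_times)
  sp <- file.path(dir, "spikes.csv"); tp <- file.path(dir, "trials.csv")
  readr::write_csv(full_precision(spikes), sp, progress = FALSE)
  readr::write_csv(full_precision(tr), tp, progress = FALSE)
  invisible(c(spikes = sp, trials = tp))
}

#' Read a Kilosort/Phy sorted-output directory
#'
#' Expects `spike_times.npy` (spike sample indices), `spike_clusters.npy`
#' (cluster assignment per spike) and a plain-text `params.py` containing a
#' `sample_rate = <Hz>` line. Sample indices are divided by the sample rate to
#' give spike times in seconds.
#'
#' @param dir Directory path.
#' @return Tibble with `unit_id` (cluster id) and `spike_time_s`.
#' @export
read_phy_dir <- function(dir) {
  f_t <- file.path(dir, "spike_times.npy")
  f_c <- file.path(dir, "spike_clusters.npy")
  f_p <- file.path(dir, "params.py")
  for (f in c(f_t, f_c, f_p)) {
    if (!file.exists(f)) abort(paste0("Phy directory missing ", basename(f)),
                               class = "wb_schema_error")
  }
  par_lines <- readLines(f_p, warn = FALSE)
  sr_line <- grep("^\\s*sample_rate\\s*=", par_lines, value = TRUE)
  if (!length(sr_line)) abort("params.py has no sample_rate line",
                              class = "wb_schema_error")
  sample_rate <- as.numeric(sub(".*=\\s*([0-9.eE+]+).*", "\\1", sr_line[1]))
  samples <- read_npy(f_t)
  clusters <- read_npy(f_c)
  if (length(samples) != length(clusters)) {
    abort("spike_times.npy and spike_clusters.npy differ in length",
          class = "wb_schema_error")
  }
  tibble::tibble(unit_id = as.character(clusters),
                 spike_time_s = as.numeric(samples) / sample_rate) |>
    dplyr::arrange(.data$unit_id, .data$spike_time_s)
}

#' Write a result table as delimited text
#'
#' Header + rows, columns in the order given, floating values at full
#' (round-trip) precision. An empty table yields a header-only file.
#'
#' @param table Data frame whose rows carry `unit_id`/`mouse_id` keys.
#' @param path Output file path.
#' @export
write_results <- function(table, path) {
  readr::write_csv(full_precision(tibble::as_tibble(table)), path,
                   progress = FALSE)
  invisible(path)
}

# format doubles with 17 significant digits so a strtod round trip is exact
full_precision <- function(tab) {
  for (nm in names(tab)) {
    if (is.double(tab[[nm]])) {
      x <- sprintf("%.17g", tab[[nm]])
      x[is.na(tab[[nm]])] <- NA_character_
      tab[[nm]] <- x
    }
  }
  tab
}
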