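#' Read a DeepLabCut-style tracked-whisker CSV
#'
#' Wide layout: a `frame` column, then `x`, `y` (and optionally
#' `likelihood`) per label, named `x1, y1, l1, x2, ...`. Label coordinates
#' whose likelihood falls below `likelihood_min` are set to `NA` (missing
#' label).
#'
#' @param path CSV path.
#' @param fps Frame rate (default 500).
#' @param likelihood_min Threshold below which a label is treated as missing.
#' @return Tibble with `frame`, `time` (seconds) and the coordinate columns.
#' @export
read_whisker_track <- function(path, fps = 500, likelihood_min = 0.9) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"frame" %in% names(d)) abort("track file needs a 'frame' column",
                                    class = "wb_schema_error")
  lk <- grep("^l[0-9]+$", names(d), value = TRUE)
  for (l in lk) {
    idx <- sub("^l", "", l)
    bad <- d[[l]] < likelihood_min
    d[[paste0("x", idx)]][bad] <- NA_real_
    d[[paste0("y", idx)]][bad] <- NA_real_
  }
  d$time <- d$frame / fps
  tibble::as_tibble(d)
}

#' Whisker angle of a tracked label
#'
#' Signed angle between the vector from a user-defined face point to the
#' label and the image vertical axis, in degrees. Image coordinates have x
#' right-positive and y down-positive; "vertical" is the image column
#' direction (toward decreasing y), so a label directly above the face point
#' gives 0 degrees and a label along +x gives +90 degrees — with the face
#' point behind the whisker pad, protraction (forward sweep) is positive.
#' Frames where the label coincides with the face point are `NA` (flagged).
#'
#' @param track Tibble from [read_whisker_track()] (or with `x<i>`, `y<i>`
#'   columns).
#' @param label Label index (1-based).
#' @param face_point Length-2 numeric `c(x, y)`, pixels.
#' @return Numeric vector of degrees per frame.
#' @export
whisker_angle <- function(track, label, face_point) {
  dx <- track[[paste0("x", label)]] - face_point[1]
  dy <- track[[paste0("y", label)]] - face_point[2]
  ang <- atan2(dx, -dy) * 180 / pi
  ang[dx == 0 & dy == 0] <- NA_real_
  ang
}

#' Menger curvature of a point triple
#'
#' Reciprocal circumradius of three points:
#' `kappa = 4 * area(p1, p2, p3) / (|p1p2| |p2p3| |p3p1|)`, in 1/pixels.
#' Collinear points give 0; duplicate points are an error.
#'
#' @param p1,p2,p3 Length-2 numeric points, or matrices with one point per
#'   row for vectorized evaluation. Rows with missing coordinates give `NA`.
#' @return Curvature(s), 1/pixels.
#' @examples
#' menger_curvature(c(0, 0), c(1, 1), c(2, 0))  # circle of radius 1
#' @export
menger_curvature <- function(p1, p2, p3) {
  p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3)
  d12 <- sqrt(rowSums((p2 - p1)^2))
  d23 <- sqrt(rowSums((p3 - p2)^2))
  d31 <- sqrt(rowSums((p1 - p3)^2))
  if (any(stats::na.omit(d12 == 0 | d23 == 0 | d31 == 0))) {
    abort("duplicate points")
  }
  cross <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  area2 <- abs(cross)  # twice the triangle area
  unname(2 * area2 / (d12 * d23 * d31))
}

#' Mean Menger curvature over all label triples of each frame
#'
#' With 4 labels per whisker there are `choose(4, 3) = 4` triples; the frame
#' curvature is their mean. Frames with a missing label are `NA` (flagged).
#'
#' @param track Tibble with `x1..x4`, `y1..y4`.
#' @param labels Label indices to use (default 1:4).
#' @return Numeric curvature per frame, 1/pixels.
#' @export
frame_curvature <- function(track, labels = 1:4) {
  xs <- as.matrix(track[, paste0("x", labels)])
  ys <- as.matrix(track[, paste0("y", labels)])
  triples <- utils::combn(seq_along(labels), 3)
  acc <- matrix(NA_real_, nrow(xs), ncol(triples))
  for (k in seq_len(ncol(triples))) {
    i <- triples[, k]
    acc[, k] <- menger_curvature(cbind(xs[, i[1]], ys[, i[1]]),
                                 cbind(xs[, i[2]], ys[, i[2]]),
                                 cbind(xs[, i[3]], ys[, i[3]]))
  }
  rowMeans(acc)
}

# local maxima with a minimum prominence and minimum spacing (frames);
# plateaus (runs of equal samples) count once, at their first frame
find_peaks <- function(x, min_prominence, min_distance) {
  n <- length(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  v <- r$values
  m <- length(v)
  if (m < 3L) return(integer(0))
  is_pk <- c(FALSE, v[2:(m - 1L)] > v[1:(m - 2L)] & v[2:(m - 1L)] > v[3:m], FALSE)
  cand <- starts[is_pk]
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    left <- if (k == 1L) 1L else cand[k - 1L]
    right <- if (k == length(cand)) n else cand[k + 1L]
    prom <- x[i] - max(min(x[left:i]), min(x[i:right]))
    keep[k] <- prom >= min_prominence
  }
  pk <- cand[keep]
  if (length(pk) > 1L) {
    out <- pk[1]
    for (p in pk[-1]) {
      if (p - out[length(out)] >= min_distance) out <- c(out, p)
      else if (x[p] > x[out[length(out)]]) out[length(out)] <- p
    }
    pk <- out
  }
  pk
}

#' Detect touch onsets from whisker tracking
#'
#' Whisk cycles are delimited by successive protraction peaks of the angle
#' trace (local maxima with at least `min_prominence` degrees of prominence
#' and `min_period` spacing, covering the 10-25 Hz whisking envelope).
#' Within each cycle the first frame at which the tip label transitions from
#' outside to inside the surface ROI is a touch onset; at most one touch is
#' reported per cycle. Onsets on frames before the first peak (the partial
#' leading cycle) are also reported.
#'
#' @param track Tibble from [read_whisker_track()].
#' @param angle Whisker angle per frame, degrees (see [whisker_angle()];
#'   computed for the tip label).
#' @param roi Axis-aligned rectangle `c(xmin, xmax, ymin, ymax)`, pixels.
#' @param tip Tip (most distal) label index.
#' @param min_prominence Peak prominence, degrees.
#' @param min_period Minimum whisk period, seconds.
#' @param fps Frame rate.
#' @return Strictly increasing touch onset times, seconds, on the frame grid,
#'   with attribute `retraction`: `TRUE` for onsets occurring while the angle
#'   was falling (retraction-phase contacts; excluding the affected trials is
#'   left to the caller).
#' @export
detect_touches <- function(track, angle, roi, tip = 4,
                           min_prominence = 5, min_period = 0.040,
                           fps = 500) {
  x <- track[[paste0("x", tip)]]
  y <- track[[paste0("y", tip)]]
  inside <- x >= roi[1] & x <= roi[2] & y >= roi[3] & y <= roi[4]
  inside[is.na(inside)] <- FALSE
  if (all(inside)) abort("ROI misconfigured: tip never leaves the ROI")
  if (!any(inside)) return(numeric(0))
  entries <- which(inside & !dplyr::lag(inside, default = FALSE))
  peaks <- find_peaks(angle, min_prominence, round(min_period * fps))
  bounds <- c(0L, peaks, length(inside) + 1L)
  onsets <- integer(0)
  for (k in seq_len(length(bounds) - 1L)) {
    hit <- entries[entries > bounds[k] & entries <= bounds[k + 1L]]
    if (length(hit)) onsets <- c(onsets, hit[1])
  }
  onsets <- sort(unique(onsets))
  retract <- vapply(onsets, function(i) {
    i > 1L && !is.na(angle[i]) && !is.na(angle[i - 1L]) &&
      angle[i] < angle[i - 1L]
  }, logical(1))
  times <- if ("time" %in% names(track)) track$time[onsets] else (onsets - 1L) / fps
  attr(times, "retraction") <- retract
  times
}
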