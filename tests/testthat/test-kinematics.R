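test_that("whisker angle follows the image-vertical convention", {
  track <- tibble::tibble(x1 = c(10, 15, 10, 5), y1 = c(5, 10, 15, 10))
  face <- c(10, 10)
  ang <- whisker_angle(track, 1, face)
  expect_equal(ang, c(0, 90, 180, -90))
  # label on the face point is undefined
  track <- tibble::tibble(x1 = 10, y1 = 10)
  expect_true(is.na(whisker_angle(track, 1, face)))
})

test_that("rotating the face-to-label vector rotates the angle", {
  face <- c(50, 50)
  at_angle <- function(a, L = 12) {
    rad <- a * pi / 180
    tibble::tibble(x1 = face[1] + L * sin(rad), y1 = face[2] - L * cos(rad))
  }
  for (a0 in c(-40, 10, 120)) for (theta in c(15, 37, 90)) {
    a1 <- whisker_angle(at_angle(a0), 1, face)
    a2 <- whisker_angle(at_angle(a0 + theta), 1, face)
    expect_equal((a2 - a1) %% 360, theta, tolerance = 1e-9)
  }
})

test_that("Menger curvature honours circle and collinearity identities", {
  expect_equal(menger_curvature(c(0, 0), c(1, 1), c(2, 0)), 1)
  expect_equal(menger_curvature(c(0, 0), c(1, 0), c(2, 0)), 0)
  expect_error(menger_curvature(c(0, 0), c(0, 0), c(2, 0)), "duplicate")
})

test_that("Menger curvature is the reciprocal circumradius on random triples", {
  set.seed(51)
  circumradius <- function(p1, p2, p3) {
    # perpendicular-bisector intersection
    m1 <- (p1 + p2) / 2; m2 <- (p2 + p3) / 2
    d1 <- c(-(p2 - p1)[2], (p2 - p1)[1])
    d2 <- c(-(p3 - p2)[2], (p3 - p2)[1])
    A <- cbind(d1, -d2)
    t <- solve(A, m2 - m1)
    centre <- m1 + t[1] * d1
    sqrt(sum((p1 - centre)^2))
  }
  for (rep in 1:20) {
    p <- matrix(runif(6, -10, 10), 3, 2)
    r <- circumradius(p[1, ], p[2, ], p[3, ])
    expect_equal(menger_curvature(p[1, ], p[2, ], p[3, ]), 1 / r,
                 tolerance = 1e-9)
  }
})

test_that("Menger curvature is rigid-motion invariant and scales as 1/s", {
  set.seed(52)
  p <- matrix(runif(6, 0, 5), 3, 2)
  k0 <- menger_curvature(p[1, ], p[2, ], p[3, ])
  theta <- 0.7; R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  q <- p %*% R + matrix(c(3, -2), 3, 2, byrow = TRUE)
  expect_equal(menger_curvature(q[1, ], q[2, ], q[3, ]), k0, tolerance = 1e-9)
  s <- 4
  expect_equal(menger_curvature(s * p[1, ], s * p[2, ], s * p[3, ]), k0 / s,
               tolerance = 1e-9)
})

test_that("frame curvature averages the four label triples", {
  # 4 collinear labels -> 0
  track <- tibble::tibble(x1 = 0, x2 = 1, x3 = 2, x4 = 3,
                          y1 = 0, y2 = 1, y3 = 2, y4 = 3)
  expect_equal(frame_curvature(track), 0)
  # 4 labels on a circle of radius R -> 1/R
  R <- 7
  th <- c(0.2, 0.9, 1.7, 2.4)
  track <- tibble::tibble(
    x1 = R * cos(th[1]), x2 = R * cos(th[2]), x3 = R * cos(th[3]), x4 = R * cos(th[4]),
    y1 = R * sin(th[1]), y2 = R * sin(th[2]), y3 = R * sin(th[3]), y4 = R * sin(th[4]))
  expect_equal(frame_curvature(track), 1 / R, tolerance = 1e-9)
  # random frames versus a naive loop over the four triples
  set.seed(53)
  xs <- matrix(runif(8, 0, 20), 2, 4); ys <- matrix(runif(8, 0, 20), 2, 4)
  track <- tibble::tibble(x1 = xs[, 1], x2 = xs[, 2], x3 = xs[, 3], x4 = xs[, 4],
                          y1 = ys[, 1], y2 = ys[, 2], y3 = ys[, 3], y4 = ys[, 4])
  fc <- frame_curvature(track)
  for (f in 1:2) {
    ks <- apply(utils::combn(4, 3), 2, function(i) {
      menger_curvature(c(xs[f, i[1]], ys[f, i[1]]),
                       c(xs[f, i[2]], ys[f, i[2]]),
                       c(xs[f, i[3]], ys[f, i[3]]))
    })
    expect_equal(fc[f], mean(ks), tolerance = 1e-12)
  }
  # a missing label makes the frame undefined
  track$x2[1] <- NA
  expect_true(is.na(frame_curvature(track)[1]))
})

sin_track <- function(dur = 1, fps = 500, freq = 10, amp = 30, x0 = 100) {
  t <- seq(0, dur, by = 1 / fps)
  tibble::tibble(frame = seq_along(t) - 1L, time = t,
                 x4 = x0 + amp * sin(2 * pi * freq * t), y4 = 50)
}

test_that("touch onsets land once per whisk cycle at the constructed frames", {
  track <- sin_track()
  ang <- 20 * sin(2 * pi * 10 * track$time)
  roi <- c(120, 140, 40, 60)
  tt <- detect_touches(track, ang, roi)
  # tip crosses x = 120 upward at sin = 2/3, once per 100 ms cycle
  phase <- asin(2 / 3) / (2 * pi * 10)
  expected <- phase + 0.1 * (0:9)
  expect_equal(length(tt), 10)
  expect_true(all(abs(tt - expected) <= 0.002 + 1e-9))
  # onsets strictly increasing and on the 2 ms frame grid
  expect_true(all(diff(tt) > 0))
  expect_true(all(abs(tt * 500 - round(tt * 500)) < 1e-9))
})

test_that("only the first within-cycle ROI entry is a touch", {
  # two entries per cycle: tip dips out of and back into the ROI mid-cycle
  t <- seq(0, 0.4, by = 1 / 500)
  ang <- 20 * sin(2 * pi * 5 * t)
  x <- 100 + 30 * sin(2 * pi * 5 * t)
  # notch that exits the ROI briefly during the protraction phase, before
  # the angle peak that ends the cycle
  notch <- (t %% 0.2) > 0.03 & (t %% 0.2) < 0.04
  x[notch] <- 100
  track <- tibble::tibble(frame = seq_along(t) - 1L, time = t, x4 = x, y4 = 50)
  tt <- detect_touches(track, ang, c(120, 140, 40, 60), min_period = 0.1)
  per_cycle <- table(floor(tt / 0.2))
  expect_true(all(per_cycle == 1))
})

test_that("degenerate ROI configurations are handled", {
  track <- sin_track()
  ang <- 20 * sin(2 * pi * 10 * track$time)
  expect_identical(detect_touches(track, ang, c(500, 600, 40, 60)), numeric(0))
  expect_error(detect_touches(track, ang, c(0, 1000, 0, 1000)),
               "ROI misconfigured")
})

test_that("tracked-label CSVs read with likelihood thresholding", {
  f <- withr::local_tempfile(fileext = ".csv")
  d <- tibble::tibble(frame = 0:2,
                      x1 = c(1, 2, 3), y1 = c(4, 5, 6), l1 = c(0.99, 0.2, 0.95))
  readr::write_csv(d, f)
  tr <- read_whisker_track(f, likelihood_min = 0.9)
  expect_true(is.na(tr$x1[2]) && is.na(tr$y1[2]))
  expect_equal(tr$time, 0:2 / 500)
})

test_that("retraction-phase contacts are flagged but still reported", {
  # protraction peak mid-record; ROI entered once while rising, once falling
  t <- seq(0, 0.2, by = 1/500)
  ang <- 20 * sin(2 * pi * 5 * t)          # peak at 50 ms
  x <- 100 + 30 * sin(2 * pi * 5 * t)      # follows the angle
  track <- tibble::tibble(frame = seq_along(t) - 1L, time = t, x4 = x, y4 = 50)
  rising <- detect_touches(track, ang, c(120, 140, 40, 60), min_period = 0.1)
  expect_false(any(attr(rising, "retraction")))
  # phase-delayed tip: the ROI entry now falls after the angle peak
  track2 <- track; track2$x4 <- 100 + 30 * sin(2 * pi * 5 * (t - 0.04))
  falling <- detect_touches(track2, ang, c(120, 140, 40, 60), min_period = 0.1)
  expect_true(any(attr(falling, "retraction")))
})
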