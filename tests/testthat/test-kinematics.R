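test_that("textbook geometries give the expected angles", {
  expect_equal(angle_between(c(0, 0), c(0, 1), c(0, 2)), 0)
  expect_equal(angle_between(c(0, 0), c(1, 0), c(1, 1)), 90)
  expect_equal(angle_between(c(0, 0), c(1, 0), c(2, 1)), 45)
  # single-frame right angle in pixel coordinates (image y down)
  expect_equal(angle_between(c(0, 0), c(0, 100), c(100, 100)), 90)
})

test_that("degenerate zero-length segments are identified by pair", {
  expect_error(angle_between(c(1, 1), c(1, 1), c(2, 2)), "a-b",
               class = "gaitmark_computation_error")
  expect_error(angle_between(c(0, 0), c(1, 1), c(1, 1)), "b-c",
               class = "gaitmark_computation_error")
})

test_that("angles are invariant under random similarity transforms", {
  withr::local_seed(9)
  worst <- 0
  for (i in 1:50) {
    a <- runif(2, -5, 5); b <- runif(2, -5, 5); c <- runif(2, -5, 5)
    base <- angle_between(a, b, c)
    th <- runif(1, 0, 2 * pi)
    s <- runif(1, 0.1, 50)
    refl <- sample(c(1, -1), 1)
    R <- s * matrix(c(cos(th), sin(th), -refl * sin(th), refl * cos(th)), 2)
    shift <- runif(2, -100, 100)
    tr <- function(p) as.numeric(R %*% p + shift)
    worst <- max(worst, abs(angle_between(tr(a), tr(b), tr(c)) - base))
  }
  expect_lt(worst, 1e-9)
})

test_that("a fixed joint configuration yields a constant angle series", {
  # hip above knee above ankle with a 37-degree bend, held for 10 frames
  bend <- 37 * pi / 180
  pts <- rbind(c(0, 0), c(0, 100), c(100 * sin(bend), 100 + 100 * cos(bend)))
  s <- static_series(pts, n = 10)
  ang <- joint_angle_series(s, joint_spec("knee", "right"))
  expect_equal(ang$value_deg, rep(37, 10), tolerance = 1e-6)
  expect_equal(attr(ang, "convention"), "raw_theta")
})

test_that("low-visibility gaps are interpolated and long gaps rejected", {
  pts <- rbind(c(0, 0), c(0, 100), c(100, 100))
  s <- static_series(pts, n = 20)
  df <- as.data.frame(s)
  # a 3-frame dropout on the middle landmark: interpolation recovers the
  # constant geometry exactly
  drop <- df$landmark_id == 25 & df$frame %in% 5:7
  df$visibility[drop] <- 0.1
  df$x[drop] <- 9999  # corrupted coordinates must be ignored
  s2 <- landmark_series(df, fps = 30)
  ang <- joint_angle_series(s2, joint_spec("knee", "right"))
  expect_equal(ang$value_deg, rep(90, 20), tolerance = 1e-9)

  df$visibility[df$landmark_id == 25 & df$frame %in% 5:12] <- 0.1
  s3 <- landmark_series(df, fps = 30)
  expect_error(joint_angle_series(s3, joint_spec("knee", "right")),
               "gap", class = "gaitmark_computation_error")
})

test_that("a missing landmark is reported by id", {
  pts <- rbind(c(0, 0), c(0, 100), c(100, 100))
  s <- static_series(pts, n = 5, ids = c(23L, 25L, 27L))
  expect_error(joint_angle_series(s, joint_spec("ankle", "right")),
               "31", class = "gaitmark_validation_error")
})

test_that("anatomical conversion splits the ankle about a 90-degree neutral", {
  raw <- gaitmark:::new_angle_series(c(75, 90, 110), c(0, 1, 2) / 30, 0:2,
                                     "ankle", "right", 30, "raw_theta")
  ana <- to_anatomical(raw)
  expect_equal(ana$value_deg, c(15, 0, -20))
  expect_error(to_anatomical(ana), "already",
               class = "gaitmark_validation_error")

  knee <- gaitmark:::new_angle_series(c(50.87, 6.79), c(0, 1) / 30, 0:1,
                                      "knee", "right", 30, "raw_theta")
  expect_equal(to_anatomical(knee)$value_deg, c(50.87, 6.79))  # passthrough
})

test_that("ankle ROM is identical in raw and anatomical conventions", {
  r <- quick_trial(fps = 60)
  raw <- joint_angle_series(r$series, joint_spec("ankle", "right"))
  ana <- to_anatomical(raw)
  expect_equal(max(raw$value_deg) - min(raw$value_deg),
               max(ana$value_deg) - min(ana$value_deg), tolerance = 1e-12)
})

test_that("moving-average smoothing behaves analytically", {
  mk <- function(v) gaitmark:::new_angle_series(
    v, seq_along(v) / 30, seq_along(v) - 1, "knee", "right", 30,
    "anatomical")
  v <- sin(2 * pi * 0.02 * (0:199))
  s <- mk(v)
  expect_equal(smooth_angles(s, 1)$value_deg, v)           # identity
  expect_equal(smooth_angles(mk(rep(7, 50)), 9)$value_deg, rep(7, 50))
  w <- 5
  sm <- smooth_angles(s, w)$value_deg
  gain <- sin(pi * 0.02 * w) / (w * sin(pi * 0.02))  # Dirichlet kernel
  interior <- (w + 1):(200 - w)
  expect_equal(sm[interior], gain * v[interior], tolerance = 1e-6)
  # output range never exceeds input range
  expect_gte(min(sm), min(v))
  expect_lte(max(sm), max(v))
  expect_error(smooth_angles(s, 4), "odd",
               class = "gaitmark_validation_error")
})
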