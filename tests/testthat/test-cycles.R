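mk_knee <- function(v, fps = 30) {
  gaitmark:::new_angle_series(v, (seq_along(v) - 1) / fps,
                              seq_along(v) - 1, "knee", "right", fps,
                              "anatomical")
}

test_that("peak-to-peak segmentation gives k - 1 cycles from k peaks", {
  t <- seq(0, 4, by = 1 / 30)           # 4 full sine periods -> 4 maxima
  s <- mk_knee(25 + 25 * sin(2 * pi * t))
  cycles <- segment_cycles(s, min_prominence = 15, min_period = 0.6)
  expect_equal(nrow(cycles), 3)
  expect_true(all(cycles$end_frame > cycles$start_frame))
  expect_equal(cycles$anchor_peak_frame, cycles$start_frame)
  # consecutive, non-overlapping
  expect_equal(cycles$end_frame[-3], cycles$start_frame[-1])
})

test_that("a featureless series raises a no-cycles error", {
  expect_error(segment_cycles(mk_knee(rep(30, 100))), "peak",
               class = "gaitmark_computation_error")
  # peaks present but below prominence
  t <- seq(0, 4, by = 1 / 30)
  expect_error(segment_cycles(mk_knee(30 + 2 * sin(2 * pi * t)),
                              min_prominence = 15),
               class = "gaitmark_computation_error")
})

test_that("segmentation is invariant to constant offsets and frame shifts", {
  t <- seq(0, 5, by = 1 / 30)
  v <- 25 + 20 * sin(2 * pi * t / 1.1)
  base <- segment_cycles(mk_knee(v))
  shifted_value <- segment_cycles(mk_knee(v + 100))
  expect_equal(base, shifted_value)
  lagged <- segment_cycles(mk_knee(c(rep(5, 7), v)))
  expect_equal(lagged$start_frame, base$start_frame + 7)
  expect_equal(lagged$end_frame, base$end_frame + 7)
})

test_that("synthetic gait with 5 configured cycles yields 4 detected cycles", {
  r <- quick_trial(fps = 30, n_cycles = 5)
  knee <- to_anatomical(
    joint_angle_series(r$series, joint_spec("knee", "right")))
  cycles <- segment_cycles(knee)
  expect_equal(nrow(cycles), 4)
  spans <- (cycles$end_frame - cycles$start_frame) / 30
  expect_true(all(abs(spans - 1.1) <= 1 / 30 + 1e-9))
})

test_that("cycle parameters are the extrema over the half-open interval", {
  s <- mk_knee(c(0, 10, 50, 10, 5, 60))   # frame 5 excluded by end_frame = 5
  p <- cycle_parameters(s, list(start_frame = 0, end_frame = 5))
  expect_equal(p, tibble::tibble(max_deg = 50, min_deg = 0, rom_deg = 50))
  p2 <- cycle_parameters(mk_knee(rep(7, 10)),
                         list(start_frame = 2, end_frame = 8))
  expect_equal(p2$rom_deg, 0)
  expect_equal(p2$max_deg, 7)
  expect_error(cycle_parameters(s, list(start_frame = 50, end_frame = 60)),
               class = "gaitmark_validation_error")
})

test_that("session and subject aggregation are unweighted means", {
  params <- tibble::tibble(max_deg = c(48, 50, 52), min_deg = c(5, 6, 7),
                           rom_deg = c(43, 44, 45))
  s <- session_summary(params)
  expect_equal(s$max_deg, 50)
  expect_false(s$few_cycles)
  expect_warning(one <- session_summary(params[1, ]),
                 class = "gaitmark_few_cycles")
  expect_true(one$few_cycles)
  expect_equal(one$max_deg, 48)

  subj <- subject_summary(tibble::tibble(max_deg = c(50, 52),
                                         min_deg = c(6, 6),
                                         rom_deg = c(44, 46)))
  expect_equal(subj$max_deg, 51)
  expect_equal(subject_summary(s)$max_deg, s$max_deg)  # passthrough
  expect_error(session_summary(params[0, ]),
               class = "gaitmark_validation_error")
})

test_that("mean ROM equals mean max minus mean min at every level", {
  withr::local_seed(4)
  mx <- runif(5, 40, 60)
  mn <- runif(5, 0, 10)
  params <- tibble::tibble(max_deg = mx, min_deg = mn, rom_deg = mx - mn)
  s <- session_summary(params)
  expect_equal(s$rom_deg, s$max_deg - s$min_deg, tolerance = 1e-12)
  subj <- subject_summary(dplyr::bind_rows(s, s |>
                                             dplyr::mutate(max_deg = max_deg + 2,
                                                           rom_deg = rom_deg + 2)))
  expect_equal(subj$rom_deg, subj$max_deg - subj$min_deg, tolerance = 1e-12)
})

test_that("noiseless parameters are recovered within the sampling bound", {
  r120 <- quick_trial(fps = 120, n_cycles = 5)
  got <- analyze_session(r120$series) |>
    dplyr::left_join(r120$truth, by = c("joint", "side", "parameter"))
  expect_lt(max(abs(got$value_deg - got$true_value)), 0.1)

  r30 <- quick_trial(fps = 30, n_cycles = 5)
  got30 <- analyze_session(r30$series) |>
    dplyr::left_join(r30$truth, by = c("joint", "side", "parameter"))
  expect_lt(max(abs(got30$value_deg - got30$true_value)), 0.5)
})
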