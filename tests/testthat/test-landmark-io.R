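test_that("write then read is value-identical in both dialects", {
  r <- quick_trial(fps = 30, noise = noise_model(pixel_sd = 1.5, seed = 5))
  for (dialect in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_landmark_series(r$series, path, dialect = dialect)
    back <- read_landmark_series(path, dialect = dialect)
    expect_equal(as.data.frame(back), as.data.frame(r$series),
                 tolerance = 1e-12)
    expect_equal(series_meta <- attributes(back)[c("fps", "coordinate_mode")],
                 attributes(r$series)[c("fps", "coordinate_mode")])
  }
})

test_that("an empty series round-trips as a header-only file", {
  empty <- landmark_series(
    tibble::tibble(frame = integer(), landmark_id = integer(),
                   x = double(), y = double()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_series(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only
  expect_equal(nrow(read_landmark_series(path)), 0L)
})

test_that("schema violations are rejected before any computation", {
  bad_id <- tibble::tibble(frame = 0L, landmark_id = 33L, x = 1, y = 1)
  expect_error(landmark_series(bad_id), "33",
               class = "gaitmark_validation_error")

  expect_error(
    landmark_series(tibble::tibble(frame = 0L, x = 1, y = 1)),
    "landmark_id", class = "gaitmark_validation_error")

  dup <- tibble::tibble(frame = c(0L, 0L), landmark_id = c(23L, 23L),
                        x = 1, y = 1)
  expect_error(landmark_series(dup), class = "gaitmark_validation_error")

  vis <- tibble::tibble(frame = 0L, landmark_id = 23L, x = 1, y = 1,
                        visibility = 1.5)
  expect_error(landmark_series(vis), "visibility",
               class = "gaitmark_validation_error")

  norm <- tibble::tibble(frame = 0L, landmark_id = 23L, x = 1.2, y = 0.5)
  expect_error(landmark_series(norm, coordinate_mode = "normalized"),
               class = "gaitmark_validation_error")
})

test_that("normalized coordinates convert to pixels by the image size", {
  s <- landmark_series(
    tibble::tibble(frame = 0L, landmark_id = 23L, x = 0.5, y = 0.25),
    coordinate_mode = "normalized", image_width = 1920, image_height = 1080)
  px <- to_pixels(s)
  expect_equal(px$x, 960)
  expect_equal(px$y, 270)
  expect_equal(attr(px, "coordinate_mode"), "pixel")
})

test_that("joint specs map to the documented landmark triples", {
  expect_equal(joint_spec("knee", "right", "paper")$ids, c(23L, 25L, 27L))
  expect_equal(joint_spec("ankle", "right", "paper")$ids, c(25L, 27L, 31L))
  expect_equal(joint_spec("knee", "left", "paper")$ids, c(24L, 26L, 28L))
  expect_equal(joint_spec("ankle", "left", "paper")$ids, c(26L, 28L, 32L))
  # the official topology assigns those ids to the opposite side
  expect_equal(joint_spec("knee", "right", "official")$ids, c(24L, 26L, 28L))
  expect_equal(joint_spec("knee", "left", "official")$ids, c(23L, 25L, 27L))
  expect_error(joint_spec("knee", "right", "banana"),
               class = "gaitmark_validation_error")
})

test_that("summary tables round-trip through CSV", {
  tbl <- summary_table(c(50, 48, 52))
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(tbl, path)
  expect_equal(as.data.frame(read_summary_csv(path)), as.data.frame(tbl))
  expect_error(write_summary_csv(tbl[, -1], path),
               class = "gaitmark_validation_error")
})
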