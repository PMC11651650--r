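test_that("calibration maps reference anchors to 0 and 100 percent", {
  frame <- matrix(c(10, 10, 110, 110, 60, 60), 2, 3)
  neg <- col(frame) == 1
  pos <- col(frame) == 2
  cal <- calibrate_channel(frame, neg, pos, "red")
  expect_equal(cal$I_neg, 10)
  expect_equal(cal$I_pos, 110)
  expect_equal(relative_intensity(110, cal), 100)
  expect_equal(relative_intensity(10, cal), 0)
  expect_equal(relative_intensity(60, cal), 50)
  # clipping
  expect_equal(relative_intensity(1000, cal), 150)
  expect_equal(relative_intensity(-50, cal), 0)
  expect_error(calibrate_channel(frame, pos, neg), "not brighter")
  expect_error(calibrate_channel(frame, neg, neg), "disjoint")
})

test_that("pixel classification follows the 20/50 threshold scheme", {
  r <- matrix(c(60, 10, 30, 60, 10, 25, 30, 10, 55), 3, 3)
  g <- matrix(c(30, 10, 30, 60, 25, 10, 55, 60, 55), 3, 3)
  map <- classify_pixels(r, g)
  cls <- mixing_classes()[as.integer(map) + 1L]
  expect_equal(cls, c("majority_red", "background", "both_weak",
                      "mixed", "only_green", "only_red",
                      "majority_green", "only_green", "mixed"))
  # boundary values fall to the weaker category
  expect_equal(mixing_classes()[classify_pixels(matrix(20), matrix(20)) + 1L],
               "background")
  expect_equal(mixing_classes()[classify_pixels(matrix(50), matrix(50)) + 1L],
               "both_weak")
  expect_error(classify_pixels(matrix(0, 2, 2), matrix(0, 3, 3)),
               "same shape")
})

test_that("classification is exhaustive and commutes with channel swap", {
  set.seed(7)
  for (i in 1:5) {
    r <- matrix(runif(400, 0, 150), 20, 20)
    g <- matrix(runif(400, 0, 150), 20, 20)
    m <- classify_pixels(r, g)
    expect_true(all(as.integer(m) %in% 0:6))
    ms <- classify_pixels(g, r)
    swap <- c(0L, 5L, 4L, 3L, 2L, 1L, 6L)  # red<->green class exchange
    expect_equal(matrix(swap[as.integer(m) + 1L], 20, 20),
                 matrix(as.integer(ms), 20, 20))
  }
})

test_that("areas are pixel counts times pixel area and partition the frame", {
  m <- classify_pixels(matrix(60, 10, 10), matrix(60, 10, 10),
                       pixel_size = 0.5)
  a <- measure_areas(m)
  expect_equal(a[["mixed"]], 100 * 0.5^2)
  expect_equal(a[["only_red"]], 0)
  expect_equal(sum(a[mixing_classes()]), 10 * 10 * 0.5^2)
  expect_error(measure_areas(classify_pixels(matrix(1), matrix(1))),
               "pixel_size")
})

test_that("classification of a noiseless movie equals the generator truth", {
  mv <- gen_fusion_movie(small_fusion_config())
  ts <- mixing_timeseries(mv$stack, identity_calibration("red"),
                          identity_calibration("green"),
                          pixel_size = mv$pixel_size,
                          frame_times_hr = mv$times_hr,
                          median_filter = FALSE)
  maps <- attr(ts, "maps")
  for (f in seq_along(maps)) {
    expect_identical(as.integer(maps[[f]]),
                     as.integer(mv$truth$class_maps[[f]]))
    # partition identity: class areas sum to the frame area
    a <- measure_areas(maps[[f]])
    expect_equal(sum(a[mixing_classes()]),
                 prod(dim(maps[[f]])) * mv$pixel_size^2)
  }
  # pre-fusion frame has no mixing; mixed area is monotone after fusion
  expect_equal(ts$area_mixed[1], 0)
  expect_true(all(diff(ts$area_mixed) >= -mv$pixel_size^2))
})

test_that("mixing requires calibrations and enough frames", {
  mv <- gen_fusion_movie(small_fusion_config())
  expect_error(mixing_timeseries(mv$stack, pixel_size = 2),
               "calibration")
  expect_error(mixing_timeseries(mv$stack[1, , , , drop = FALSE],
                                 identity_calibration("red"),
                                 identity_calibration("green"),
                                 pixel_size = 2),
               "2 frames")
})

test_that("an immature pair (high D) reaches 90% mixing much sooner", {
  immature <- small_fusion_config()
  mature <- small_fusion_config(D_red = 0.3 / 4, D_green = 0.3 / 4,
                                n_frames = 25L)
  t90_post_fusion <- function(cfg) {
    mv <- gen_fusion_movie(cfg)
    ts <- mixing_timeseries(mv$stack, identity_calibration("red"),
                            identity_calibration("green"),
                            pixel_size = mv$pixel_size,
                            frame_times_hr = mv$times_hr,
                            median_filter = FALSE)
    fusion_hr <- mv$times_hr[cfg$fusion_frame]
    ts$time_hr[which(ts$mixed_pct >= 90)[1]] - fusion_hr
  }
  expect_gte(t90_post_fusion(mature) / t90_post_fusion(immature), 2.5)
})

test_that("area filter keeps cells within the inclusive bounds", {
  expect_equal(filter_cells_by_area(c(500, 1500, 12000)), 2L)
  expect_equal(filter_cells_by_area(c(1000, 10000)), c(1L, 2L))
  expect_equal(filter_cells_by_area(numeric()), integer())
  expect_equal(filter_cells_by_area(c(3, 30), min_area = 1, max_area = 10), 1L)
})

test_that("spread rate recovers an exact linear growth and its unit", {
  ts <- data.frame(time_hr = seq(0, 4, 0.5),
                   area_mixed = pmax(seq(0, 4, 0.5) - 0.5, 0) * 1000)
  sr <- spread_rate(ts)
  expect_equal(sr$rate_um2_per_hr, 1000, tolerance = 1e-9)
  expect_equal(round(sr$rate_um2_per_s, 1), 0.3)
  flat <- data.frame(time_hr = 0:5, area_mixed = 0)
  expect_warning(sr0 <- spread_rate(flat), "never grows")
  expect_equal(sr0$rate_um2_per_hr, 0)
})

test_that("gradient width matches the analytic crossing points", {
  x <- seq(0, 300, by = 0.5)
  # exponential invasion profile, lambda = 54.6 um -> width = lambda*ln(2.5)
  w <- gradient_width(x, 100 * exp(-x / 54.6))
  expect_equal(w, 54.6 * log(50 / 20), tolerance = 0.01)
  # a step has no transition zone at sampling resolution
  step <- ifelse(x < 150, 100, 0)
  expect_lt(gradient_width(x, step), 0.5)
  # profile below the weak threshold everywhere -> undefined
  expect_warning(w2 <- gradient_width(x, rep(10, length(x))), "undefined")
  expect_true(is.na(w2))
  # smoothing tolerates sample noise
  set.seed(1)
  wn <- gradient_width(x, 100 * exp(-x / 54.6) + rnorm(length(x), 0, 2),
                       smooth_window = 11)
  expect_equal(wn, 50, tolerance = 0.15)
})
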