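test_that("preprocessing subtracts background and divides flatfield", {
  const <- image_stack(array(7, c(3, 16, 16)), frame_interval_ms = 1000)
  out <- preprocess_movie(const, blur_sigma_px = 0)
  expect_true(all(out$data == 0))
  st <- gen_cell_movie(n_cells = 1, n_frames = 5, noise_sd = 0, seed = 1)$calcium
  id <- preprocess_movie(st, flatfield = matrix(1, 96, 96), blur_sigma_px = 0)
  noff <- preprocess_movie(st, blur_sigma_px = 0)
  expect_equal(id$data, noff$data)
  # vignetted stack divided by its matching flatfield comes out flat
  vig <- outer(seq(0.5, 1, length.out = 24), seq(0.5, 1, length.out = 24))
  arr <- array(0, c(2, 24, 24))
  for (f in 1:2) arr[f, , ] <- 100 * vig
  arr[, 1, 1] <- 0   # true zero floor so the background estimate is 0
  corrected <- preprocess_movie(image_stack(arr, frame_interval_ms = 1000),
                                flatfield = vig, blur_sigma_px = 0,
                                bg_percentile = 0)
  expect_lt(diff(range(corrected$data[, -1, -1])), 1e-9)
  bad <- matrix(1, 24, 24); bad[1, 1] <- 0
  expect_error(preprocess_movie(image_stack(arr, frame_interval_ms = 1000),
                                flatfield = bad), "non-positive flatfield")
})

test_that("stationary cells are tracked once and jittery tracks discarded", {
  mv <- gen_cell_movie(n_cells = 1, n_frames = 60, noise_sd = 1, seed = 2)
  ca <- preprocess_movie(mv$calcium)
  tr <- track_cells(ca, cell_radius_px = 5)
  expect_equal(nrow(tr), 1)
  cells <- attr(mv$truth, "cells")
  expect_equal(tr$row, cells$row, tolerance = 1)
  expect_equal(tr$col, cells$col, tolerance = 1)
  # two cells 50 px apart -> two tracks, no swaps
  mv2 <- gen_cell_movie(n_cells = 2, n_frames = 60, noise_sd = 1, seed = 3,
                        fov_px = 96)
  tr2 <- track_cells(preprocess_movie(mv2$calcium), cell_radius_px = 5)
  expect_equal(nrow(tr2), 2)
  # a maximum jittering by ~radius gets discarded
  set.seed(4)
  arr <- array(0, c(40, 48, 48))
  for (f in 1:40) {
    r <- 24 + round(rnorm(1, 0, 5)); c <- 24 + round(rnorm(1, 0, 5))
    arr[f, max(1, r), max(1, c)] <- 100
  }
  trj <- track_cells(image_stack(arr, frame_interval_ms = 1000),
                     cell_radius_px = 5)
  expect_equal(nrow(trj), 0)
})

test_that("track output is invariant to intensity rescaling", {
  mv <- gen_cell_movie(n_cells = 3, n_frames = 50, noise_sd = 1, seed = 5)
  ca <- preprocess_movie(mv$calcium)
  t1 <- track_cells(ca, cell_radius_px = 5)
  ca2 <- ca; ca2$data <- ca2$data * 4.2
  t2 <- track_cells(ca2, cell_radius_px = 5)
  expect_equal(t1$row, t2$row)
  expect_equal(t1$col, t2$col)
})

test_that("disk traces average the configured disk", {
  arr <- array(3.5, c(4, 32, 32))
  st <- image_stack(arr, frame_interval_ms = 1000)
  tracks <- data.frame(cell = 1L, row = 16, col = 16, sd_px = 0,
                       n_frames = 4L)
  attr(tracks, "cell_radius_px") <- 5
  tr <- extract_traces(st, tracks, smooth_sd = 0)
  expect_true(all(tr == 3.5))
  # direct pixel-average oracle on a structured frame
  set.seed(6)
  arr2 <- array(runif(32 * 32), c(1, 32, 32))
  st2 <- image_stack(arr2, frame_interval_ms = 1000)
  tr2 <- extract_traces(st2, tracks, smooth_sd = 0)
  sel <- outer((1:32 - 16)^2, (1:32 - 16)^2, "+") <= 25
  expect_equal(tr2[1, 1], mean(arr2[1, , ][sel]))
  # edge-clipped disk flagged but computed
  tre <- data.frame(cell = 1L, row = 2, col = 2, sd_px = 0, n_frames = 1L)
  attr(tre, "cell_radius_px") <- 5
  tr3 <- extract_traces(st2, tre, smooth_sd = 0)
  expect_true(attr(tr3, "edge_clipped"))
  expect_true(is.finite(tr3[1, 1]))
})

test_that("spike detection calls injected transients and rejects brief ones", {
  expect_equal(nrow(detect_spikes(rep(1, 100), 0.1)), 0)
  expect_error(detect_spikes(rep(1, 100), 0), "threshold")
  tr <- sim_spike_trace(c(80, 160, 280), noise_sd = 0.02, seed = 7)
  calls <- detect_spikes(tr, derivative_threshold = 0.1,
                         min_amplitude = 0.3, min_duration = 2)
  expect_equal(nrow(calls), 3)
  expect_true(all(abs(calls$onset_frame - c(80, 160, 280)) <= 3))
  expect_true(all(calls$amplitude > 0.5))
  # a 1-frame blip is removed by the duration filter
  blip <- rep(1, 120); blip[60] <- 2
  expect_equal(nrow(detect_spikes(blip, 0.1, min_duration = 3)), 0)
})

test_that("ROS percent change follows the windowed means and is scale-free", {
  tr <- c(rep(100, 100), rep(118, 100))
  expect_equal(ros_percent_change(tr, 100, 200, window = 50), 18)
  expect_equal(ros_percent_change(tr * 3.7, 100, 200, window = 50), 18)
  expect_equal(ros_percent_change(rep(5, 200), 100, 200), 0)
  # linear ramp: closed form 100 * s * df / F_initial
  s <- 0.2
  ramp <- 100 + s * pmax(0:299 - 100, 0)
  got <- ros_percent_change(ramp, 100, 300, window = 50)
  f_init <- 100
  f_fin <- mean(ramp[251:300])
  expect_equal(got, 100 * (f_fin - f_init) / f_init)
  expect_error(ros_percent_change(tr, 10, 200), "out of range")
  expect_error(ros_percent_change(rep(0, 200), 100, 200), "F_initial")
})

test_that("responding fractions count cells with post-stimulus spikes", {
  none <- data.frame(cell = integer(), onset_frame = integer())
  expect_equal(responding_fraction(none, 10), 0)
  all_cells <- data.frame(cell = 1:5, onset_frame = rep(60, 5))
  expect_equal(responding_fraction(all_cells, 5, stimulus_frame = 50), 1)
  some <- data.frame(cell = c(1, 1, 2, 3), onset_frame = c(60, 90, 20, 70))
  expect_equal(responding_fraction(some, 4, stimulus_frame = 50), 0.5)
})

test_that("the movie pipeline recovers spikes, responders and the ROS ramp", {
  mv <- gen_cell_movie(n_cells = 12, n_frames = 200, ros_ramp = 0.2,
                       responding = 9 / 12, noise_sd = 2, seed = 8,
                       fov_px = 96)
  res <- analyze_cell_movie(mv$calcium, mv$ros, derivative_threshold = 0.2,
                            stimulus_frame = 50, ionomycin_frame = 200)
  expect_equal(nrow(res$tracks), 12)
  expect_equal(res$responding_fraction, 0.75)
  # closed-form expected ramp: slope 0.2/frame over 125 frames to the
  # final window midpoint, relative to baseline 100
  expect_equal(stats::median(res$ros_change), 25, tolerance = 3)
  # zero-spike, zero-ramp control
  mv0 <- gen_cell_movie(n_cells = 6, n_frames = 150, responding = 0,
                        ros_ramp = 0, noise_sd = 2, seed = 9)
  res0 <- analyze_cell_movie(mv0$calcium, mv0$ros,
                             derivative_threshold = 0.2,
                             stimulus_frame = 40, ionomycin_frame = 150)
  expect_equal(res0$responding_fraction, 0)
  expect_lt(abs(stats::median(res0$ros_change)), 1)
})
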