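test_that("diff_stack counts threshold crossings per frame pair", {
  ev <- data.frame(frame_idx = 4L, n_pixels = 5L)
  st <- gen_image_stack(ev, frame_shape = c(8L, 8L), n_frames = 6L)
  d <- diff_stack(st)
  expect_equal(nrow(d), 5L)
  expect_equal(d$changed_pixels, c(0L, 0L, 0L, 5L, 0L))
  # threshold above the intensity delta -> nothing changes
  expect_true(all(diff_stack(st, binarize_threshold = 2)$changed_pixels == 0))
  expect_error(diff_stack(st[, , 1, drop = FALSE]), "single frame")
  expect_error(diff_stack(list(matrix(0, 8, 8), matrix(0, 9, 9))),
               "ragged")
})

test_that("filter_events drops noise and movement artifacts, keeping rows", {
  s <- as_frame_diff_series(data.frame(frame_idx = 1:4,
                                       n_pixels = c(5L, 5L, 5L, 500L)))
  f <- filter_events(s, min_size = 2, max_size_quantile = 0.99)
  expect_equal(f$kept, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(nrow(f), 4L)                      # original preserved
  # identity configuration
  f2 <- filter_events(s, min_size = 0, max_size_quantile = 1)
  expect_true(all(f2$kept))
  # single tiny event below min_size
  s1 <- as_frame_diff_series(data.frame(frame_idx = 1L, n_pixels = 1L))
  expect_error(filter_events(s1, min_size = 2), "filtered")
  s0 <- as_frame_diff_series(data.frame(frame_idx = 1:2,
                                        n_pixels = c(0L, 0L)))
  expect_error(filter_events(s0), "no embolism signal")
})

test_that("align_psi interpolates the psychrometer log linearly", {
  log <- data.frame(time_min = c(0, 10, 20), psi_mpa = c(-1, -2, -3))
  s <- as_frame_diff_series(data.frame(frame_idx = 1:3,
                                       time_min = c(5, 10, 15),
                                       n_pixels = c(1L, 1L, 1L)))
  psi <- align_psi(s, log)
  expect_equal(as.numeric(psi), c(-1.5, -2, -2.5))

  # closed-form check: psi(t) = -0.01 - 0.005 t sampled at t = 100
  t <- seq(0, 200, by = 10)
  log2 <- data.frame(time_min = t, psi_mpa = -0.01 - 0.005 * t)
  s2 <- as_frame_diff_series(data.frame(frame_idx = 1L, time_min = 100,
                                        n_pixels = 1L))
  expect_equal(as.numeric(align_psi(s2, log2)), -0.51)

  # extrapolation limited to one log interval, and flagged
  s3 <- as_frame_diff_series(data.frame(frame_idx = 1L, time_min = 25,
                                        n_pixels = 1L))
  psi3 <- align_psi(s3, log)
  expect_equal(as.numeric(psi3), -3.5)
  expect_equal(attr(psi3, "extrapolated"), 1L)
  s4 <- as_frame_diff_series(data.frame(frame_idx = 1L, time_min = 500,
                                        n_pixels = 1L))
  expect_error(align_psi(s4, log), "overlap|beyond")
})

test_that("cumulate normalizes to exactly 100 percent", {
  s <- as_frame_diff_series(data.frame(frame_idx = 1:3,
                                       n_pixels = c(10L, 30L, 60L)))
  tr <- cumulate(s, psi = c(-1, -2, -3))
  expect_equal(tr$cum_pct, c(10, 40, 100))
  expect_s3_class(tr, "embolism_trace")
  # single event steps straight to 100
  s1 <- as_frame_diff_series(data.frame(frame_idx = 1L, n_pixels = 7L))
  expect_equal(cumulate(s1, -1)$cum_pct, 100)
  # filtering then cumulating equals cumulating the kept subset
  s2 <- filter_events(as_frame_diff_series(
    data.frame(frame_idx = 1:4, n_pixels = c(1L, 10L, 30L, 60L))),
    min_size = 2, max_size_quantile = 1)
  tr2 <- cumulate(s2, psi = c(-1, -2, -3, -4))
  expect_equal(tr2$cum_pct, c(0, 10, 40, 100))
  expect_error(cumulate(as_frame_diff_series(
    data.frame(frame_idx = 1:2, n_pixels = c(0L, 0L))), c(-1, -2)),
    "zero total")
})

test_that("stack pipeline and event-table pipeline agree end to end", {
  p <- schotia_params()
  camp <- gen_embolism_campaign(p, gen_config(seed = 11, n_pixels = 40))
  n_frames <- max(camp$events$frame_idx) + 1L
  st <- gen_image_stack(camp$events, frame_shape = c(32L, 32L),
                        n_frames = n_frames)
  frame_times <- seq(0, by = 5, length.out = n_frames)
  # differencing recovers the event table exactly
  d <- diff_stack(st)
  expect_equal(d$changed_pixels[match(camp$events$frame_idx, d$frame_idx)],
               camp$events$n_pixels)
  expect_equal(sum(d$changed_pixels), sum(camp$events$n_pixels))
  # and the cumulative traces agree at the event frames
  tr_stack <- ov_quantify(stack = st, psychrometer = camp$psychrometer,
                          frame_times = frame_times, min_size = 1,
                          max_size_quantile = 1)
  tr_events <- ov_quantify(camp$events, camp$psychrometer, min_size = 1,
                           max_size_quantile = 1)
  at_events <- match(camp$events$frame_idx, tr_stack$frame_idx)
  expect_equal(tr_stack$cum_pct[at_events], tr_events$cum_pct)
})

test_that("generated traces reproduce the sampled logistic distribution", {
  # Kolmogorov distance between the cumulative trace and the true
  # sigmoid stays small at n = 2000
  p <- euclea_params()
  tr <- synthetic_trace(p, seed = 21, n_pixels = 2000)
  ks <- max(abs(tr$cum_pct - sigmoid_pe(tr$psi_mpa, p$a, p$b)) / 100)
  expect_lt(ks, 0.05)
  expect_equal(tail(tr$cum_pct, 1), 100)
  expect_true(all(diff(tr$cum_pct) >= 0))
})
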