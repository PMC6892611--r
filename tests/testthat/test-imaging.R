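test_that("roi sets validate bounds, disjointness and emptiness", {
  shape <- c(16, 16)
  a <- cbind(3:5, 3:5)
  b <- cbind(10:11, 10:11)
  expect_s3_class(roi_set(list(a, b), shape), "roi_set")
  expect_error(roi_set(list(a, a), shape), "overlap")
  expect_error(roi_set(list(cbind(20, 3)), shape), "bounds")
  expect_error(roi_set(list(a[0, , drop = FALSE]), shape), "empty")
})

test_that("roi extraction sums pixels and is local to each roi", {
  shape <- c(8, 8)
  rois <- roi_set(list(cbind(c(2, 2, 3), c(2, 3, 2)), cbind(6, 6)), shape)
  stack <- array(3, c(8, 8, 4))
  f <- extract_roi_traces(stack, rois)
  expect_equal(f[, 1], rep(9, 4))   # 3 pixels x value 3
  expect_equal(f[, 2], rep(3, 4))
  expect_equal(extract_roi_traces(array(0, c(8, 8, 2)), rois),
               matrix(0, 2, 2), ignore_attr = TRUE)
  # editing pixels of one ROI leaves the other's trace unchanged
  stack2 <- stack
  stack2[6, 6, ] <- 99
  f2 <- extract_roi_traces(stack2, rois)
  expect_equal(f2[, 1], f[, 1])
  expect_equal(f2[, 2], rep(99, 4))
})

test_that("dff uses the within-trial percentile baseline", {
  expect_equal(compute_dff(rep(100, 10))$dff, rep(0, 10))
  f <- c(rep(100, 8), 150, 200)
  res <- compute_dff(f)
  expect_equal(res$f_baseline, 100)
  expect_equal(max(res$dff), 1.0)
  # scale invariance: dff unchanged under F -> cF for c > 0
  expect_equal(compute_dff(3.7 * f)$dff, res$dff, tolerance = 1e-12)
  # a constant pad at the trace floor leaves dff of the original samples
  # unchanged when it does not move the 30th percentile
  padded <- compute_dff(c(rep(100, 4), f))$dff
  expect_equal(padded[-(1:4)], res$dff, tolerance = 1e-12)
  expect_error(compute_dff(numeric()), "empty")
  expect_error(compute_dff(c(-5, -4, 10)), "baseline")
})

test_that("movement activity picks nearest frames with earlier tie-break", {
  # 6 Hz grid: onset 2.0 s sits on a frame; baseline target 1.4 s is
  # nearest to the frame at 1.3333 s
  ft <- (0:17) / 6
  dff <- seq(0, 1.7, by = 0.1)
  res <- movement_activity(dff, ft, movement_onset_s = 2.0)
  expect_equal(ft[res$movement_frame_idx], 2.0)
  expect_equal(ft[res$baseline_frame_idx], 8 / 6, tolerance = 1e-9)
  expect_equal(res$R, dff[res$movement_frame_idx] -
                 dff[res$baseline_frame_idx])
  # flat dff gives R = 0
  expect_equal(movement_activity(rep(0.2, 18), ft, 2.0)$R, 0)
  # exact midpoint ties resolve to the earlier frame
  ft2 <- c(0, 1, 2, 3)
  res2 <- movement_activity(c(0, 0.1, 0.4, 0.9), ft2, 2.5,
                            baseline_offset_s = 1.5)
  expect_equal(res2$movement_frame_idx, 3)  # frame at 2 s, not 3 s
  # onset too early for the 600 ms baseline: trial unusable
  expect_null(movement_activity(c(0, 1), c(0, 0.5), 0.4))
})

test_that("simple arithmetic example: baseline 0.1, movement 0.5", {
  res <- movement_activity(c(0.1, 0.5), c(0, 0.6), 0.6)
  expect_equal(res$R, 0.4)
})

test_that("registration recovers constructed and simulated shifts", {
  set.seed(12)
  ref <- matrix(rnorm(32 * 32, 50, 10), 32, 32)
  shifted <- mosaccade:::translate_frame(ref, 2, 3)
  stack <- array(c(ref, shifted), c(32, 32, 2))
  reg <- register_frames(stack, max_shift_px = 5)
  expect_equal(reg$shifts$dy[2], 2)
  expect_equal(reg$shifts$dx[2], 3)
  # identical frames give a zero shift
  stack0 <- array(rep(ref, 3), c(32, 32, 3))
  expect_true(all(register_frames(stack0, 4)$shifts[, c("dy", "dx")] == 0))
  expect_error(register_frames(stack, max_shift_px = 16), "half")
})

test_that("rendered movies carry their ground-truth jitter", {
  rois <- roi_set(list(cbind(c(10, 10, 11, 11), c(10, 11, 10, 11)),
                       cbind(c(20, 20), c(20, 21))), c(32, 32))
  traces <- matrix(c(seq(100, 150, length.out = 12),
                     seq(80, 90, length.out = 12)), 12, 2)
  mv <- render_movie(rois, traces, jitter_sd_px = 1.2, seed = 9)
  expect_equal(dim(mv$frames)[3], nrow(traces))
  reg <- register_frames(mv$frames, max_shift_px = 5)
  expect_equal(reg$shifts$dy, mv$true_shifts$dy)
  expect_equal(reg$shifts$dx, mv$true_shifts$dx)
  # jitter 0 leaves every frame in place
  mv0 <- render_movie(rois, traces, jitter_sd_px = 0, seed = 9)
  expect_true(all(mv0$true_shifts[, c("dy", "dx")] == 0))
  # registration + extraction reproduce the jitter-free traces exactly:
  # each ROI sums its painted pixel value times its pixel count
  f <- extract_roi_traces(reg$corrected, rois)
  expect_equal(f[, 1], 4 * traces[, 1])
  expect_equal(f[, 2], 2 * traces[, 2])
})

test_that("movie rendering is deterministic and validates inputs", {
  rois <- roi_set(list(cbind(5, 5)), c(16, 16))
  tr <- matrix(1:6, 6, 1)
  m1 <- render_movie(rois, tr, seed = 4)
  m2 <- render_movie(rois, tr, seed = 4)
  expect_identical(m1$frames, m2$frames)
  expect_error(render_movie(rois, cbind(tr, tr), seed = 1), "one column")
})
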