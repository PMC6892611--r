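#' Rigid integer-shift registration of a frame stack
#'
#' Aligns every frame to the first frame of the stack by exhaustive search
#' over integer translations within `±max_shift_px`, maximizing the Pearson
#' correlation between the overlapping regions (rigid cross-correlation
#' alignment). Vacated pixels in the corrected frames are filled with the
#' frame median. Sub-pixel and non-rigid corrections are out of scope.
#'
#' @param stack rows x cols x frames array with at least two frames.
#' @param max_shift_px maximum absolute shift searched, pixels; must be less
#'   than half the smaller image dimension.
#' @return List with `shifts` (tibble `frame`, `dy`, `dx`: the detected
#'   displacement of each frame relative to the reference) and `corrected`
#'   (the re-aligned stack).
#' @export
register_frames <- function(stack, max_shift_px = 5L) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2)
    stop_config("stack must be a 3-d array with >= 2 frames")
  m <- as.integer(max_shift_px)
  if (m >= min(d[1], d[2]) / 2)
    stop_config("max_shift_px must be below half the image size")
  ref <- stack[, , 1]
  n_frames <- d[3]
  dy <- integer(n_frames)
  dx <- integer(n_frames)
  corrected <- stack
  grid <- expand.grid(dy = -m:m, dx = -m:m)
  for (k in 2:n_frames) {
    img <- stack[, , k]
    best <- -Inf
    best_dy <- 0L
    best_dx <- 0L
    for (g in seq_len(nrow(grid))) {
      sdy <- grid$dy[g]
      sdx <- grid$dx[g]
      # overlap of ref with img shifted back by (sdy, sdx)
      r_ref <- max(1, 1 + sdy):min(d[1], d[1] + sdy)
      c_ref <- max(1, 1 + sdx):min(d[2], d[2] + sdx)
      a <- ref[r_ref - sdy, c_ref - sdx]
      b <- img[r_ref, c_ref]
      cc <- stats::cor(as.vector(a), as.vector(b))
      if (!is.na(cc) && cc > best) {
        best <- cc
        best_dy <- sdy
        best_dx <- sdx
      }
    }
    dy[k] <- best_dy
    dx[k] <- best_dx
    corrected[, , k] <- translate_frame(img, -best_dy, -best_dx)
  }
  list(shifts = tibble::tibble(frame = seq_len(n_frames), dy = dy, dx = dx),
       corrected = corrected)
}

#' Sum pixel values within each ROI, per frame
#'
#' @param stack rows x cols x frames array.
#' @param rois a [roi_set()] matching the stack shape.
#' @return frames x ROIs matrix of raw fluorescence (pixel sums).
#' @export
extract_roi_traces <- function(stack, rois) {
  stopifnot(inherits(rois, "roi_set"))
  d <- dim(stack)
  if (length(d) != 3 || any(d[1:2] != rois$image_shape))
    stop_config("stack shape does not match the ROI set")
  n_frames <- d[3]
  out <- matrix(0, n_frames, length(rois$linear))
  npix <- d[1] * d[2]
  flat <- matrix(stack, npix, n_frames)
  for (j in seq_along(rois$linear)) {
    px <- rois$linear[[j]]
    out[, j] <- if (length(px) == 1) flat[px, ] else colSums(flat[px, ])
  }
  colnames(out) <- as.character(rois$roi_id)
  out
}

#' Within-trial dF/F from a raw fluorescence series
#'
#' `F_baseline` is the within-trial percentile of the raw series (linear
#' interpolation between order statistics, the default 30th percentile);
#' `dF/F = (F - F_baseline) / F_baseline`. The result is invariant to
#' rescaling the raw series by any positive constant.
#'
#' @param f numeric raw fluorescence series for one trial (non-empty).
#' @param baseline_percentile percentile in (0, 100).
#' @return List with `dff` (series, same length) and `f_baseline`.
#' @export
compute_dff <- function(f, baseline_percentile = 30) {
  if (length(f) == 0) stop_config("empty fluorescence series")
  if (anyNA(f)) stop_config("fluorescence series contains NA")
  fb <- unname(quantile(f, baseline_percentile / 100, type = 7))
  if (fb <= 0)
    stop_config("non-positive baseline fluorescence; raw units invalid")
  list(dff = (f - fb) / fb, f_baseline = fb)
}

# index of the frame nearest to `t`; exact midpoint ties go to the earlier
# frame
nearest_frame <- function(frame_times, t) {
  d <- abs(frame_times - t)
  i <- which(d <= min(d) + 1e-12)
  i[1]
}

#' Movement-related activity R for one trial
#'
#' `R` is the dF/F increase between the frame at baseline
#' (`baseline_offset_s` before movement onset, default 600 ms) and the frame
#' at the time of movement. Frames are chosen by nearest timestamp with ties
#' broken toward the earlier frame.
#'
#' @param dff dF/F series for the trial.
#' @param frame_times_s frame timestamps (same length as `dff`), seconds.
#' @param movement_onset_s movement onset, seconds (same clock).
#' @param baseline_offset_s baseline lead time before movement onset.
#' @return List with `R`, `movement_frame_idx`, `baseline_frame_idx`; or
#'   `NULL` when the required frames fall outside the trial (the trial is
#'   unusable).
#' @export
movement_activity <- function(dff, frame_times_s, movement_onset_s,
                              baseline_offset_s = 0.6) {
  stopifnot(length(dff) == length(frame_times_s))
  t_base <- movement_onset_s - baseline_offset_s
  if (t_base < frame_times_s[1] ||
      movement_onset_s > frame_times_s[length(frame_times_s)])
    return(NULL)
  i_mov <- nearest_frame(frame_times_s, movement_onset_s)
  i_base <- nearest_frame(frame_times_s, t_base)
  if (i_base >= i_mov) return(NULL)
  list(R = dff[i_mov] - dff[i_base],
       movement_frame_idx = i_mov, baseline_frame_idx = i_base)
}

#' Per-trial movement-related activity for every neuron
#'
#' Cuts the fluorescence matrix into trials, computes within-trial dF/F per
#' neuron, and extracts `R` at each trial's ground-truth (or detected)
#' movement onset. Only completed trials with a movement onset are used;
#' trials whose baseline frame would precede the trial start are excluded.
#'
#' @param fluor a `fluor_data` object from [simulate_calcium()], or a list
#'   with `frame_times_s` and `f` (frames x neurons matrix).
#' @param schedule tibble with `trial_id`, `target_side`, `fix_start_s`,
#'   `trial_end_s` and a movement-onset column.
#' @param onset_col name of the movement-onset column in `schedule`.
#' @param hemisphere hemisphere under study, for the condition label.
#' @param baseline_percentile within-trial dF/F baseline percentile.
#' @param baseline_offset_s baseline lead time for `R`, seconds.
#' @return Tibble `neuron_id`, `trial_id`, `condition`, `R`.
#' @export
trial_activity <- function(fluor, schedule, onset_col = "true_onset_s",
                           hemisphere = c("right", "left"),
                           baseline_percentile = 30,
                           baseline_offset_s = 0.6) {
  hemisphere <- match.arg(hemisphere)
  ft <- fluor$frame_times_s
  f <- fluor$f
  done <- schedule[!is.na(schedule[[onset_col]]), ]
  rows <- vector("list", nrow(done))
  n_neurons <- ncol(f)
  for (k in seq_len(nrow(done))) {
    tr <- done[k, ]
    idx <- which(ft >= tr$fix_start_s & ft <= tr$trial_end_s)
    if (length(idx) < 2) next
    onset <- tr[[onset_col]]
    sub_t <- ft[idx]
    sub_f <- f[idx, , drop = FALSE]
    t_base <- onset - baseline_offset_s
    if (t_base < sub_t[1] || onset > sub_t[length(sub_t)]) next
    i_mov <- nearest_frame(sub_t, onset)
    i_base <- nearest_frame(sub_t, t_base)
    if (i_base >= i_mov) next
    fb <- apply(sub_f, 2, quantile, probs = baseline_percentile / 100,
                type = 7, names = FALSE)
    if (any(fb <= 0))
      stop_config("non-positive baseline fluorescence in trial %d",
                  tr$trial_id)
    r <- (sub_f[i_mov, ] - sub_f[i_base, ]) / fb
    rows[[k]] <- tibble::tibble(
      neuron_id = seq_len(n_neurons),
      trial_id = tr$trial_id,
      condition = movement_condition(tr$target_side, hemisphere),
      R = unname(r))
  }
  dplyr::bind_rows(rows)
}
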