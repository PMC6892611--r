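#' Construct a validated ROI set
#'
#' @param pixels list of integer matrices, one per ROI, two columns
#'   (row, col), 1-based, all inside `image_shape` and pairwise disjoint.
#' @param image_shape integer c(rows, cols) of the frames the ROIs index.
#' @param roi_id optional ids; defaults to `seq_along(pixels)`.
#' @return Object of class `roi_set`.
#' @export
roi_set <- function(pixels, image_shape, roi_id = seq_along(pixels)) {
  stopifnot(is.list(pixels), length(image_shape) == 2)
  if (length(pixels) == 0) stop_config("ROI set must be non-empty")
  lin <- lapply(pixels, function(p) {
    p <- as.matrix(p)
    if (nrow(p) == 0) stop_config("empty ROI")
    if (any(p < 1) || any(p[, 1] > image_shape[1]) ||
        any(p[, 2] > image_shape[2]))
      stop_config("ROI pixels out of image bounds")
    (p[, 2] - 1) * image_shape[1] + p[, 1]
  })
  all_lin <- unlist(lin)
  if (anyDuplicated(all_lin)) stop_config("ROIs overlap")
  structure(list(pixels = pixels, linear = lin,
                 image_shape = as.integer(image_shape),
                 roi_id = roi_id), class = "roi_set")
}

#' Render a synthetic imaging movie with rigid jitter
#'
#' Paints each ROI's pixels with its fluorescence value over a fixed textured
#' background, then translates every frame by an integer shift drawn from a
#' rounded Gaussian. The true shifts are returned so registration can be
#' checked against ground truth. Out-of-frame pixels after translation are
#' filled with the frame median.
#'
#' @param rois a [roi_set()].
#' @param neuron_traces frames x ROIs matrix of fluorescence values.
#' @param jitter_sd_px s.d. of the per-frame shift before rounding; 0 gives
#'   all-zero shifts.
#' @param background_sd s.d. of the static Gaussian background texture.
#' @param background_mean mean background intensity.
#' @param seed integer seed (jitter and texture substreams).
#' @return List of class `movie_data`: `frames` (rows x cols x n_frames
#'   array), `true_shifts` (tibble `frame`, `dy`, `dx`), `rois`.
#' @export
render_movie <- function(rois, neuron_traces, jitter_sd_px = 1,
                         background_sd = 5, background_mean = 20,
                         seed = 1L) {
  stopifnot(inherits(rois, "roi_set"), is.matrix(neuron_traces))
  if (ncol(neuron_traces) != length(rois$pixels))
    stop_config("neuron_traces must have one column per ROI")
  nr <- rois$image_shape[1]
  nc <- rois$image_shape[2]
  n_frames <- nrow(neuron_traces)
  with_seed(substream_seed(seed, "movie"), {
    background <- matrix(background_mean +
                           rnorm(nr * nc, 0, background_sd), nr, nc)
    # the first frame is the registration reference and stays in place
    shifts <- if (jitter_sd_px > 0 && n_frames > 1) {
      rbind(c(0, 0),
            matrix(round(rnorm(2 * (n_frames - 1), 0, jitter_sd_px)),
                   n_frames - 1, 2))
    } else matrix(0L, n_frames, 2)
    frames <- array(0, c(nr, nc, n_frames))
    for (k in seq_len(n_frames)) {
      img <- background
      for (j in seq_along(rois$linear)) {
        img[rois$linear[[j]]] <- neuron_traces[k, j]
      }
      frames[, , k] <- translate_frame(img, shifts[k, 1], shifts[k, 2])
    }
    structure(list(frames = frames,
                   true_shifts = tibble::tibble(frame = seq_len(n_frames),
                                                dy = shifts[, 1],
                                                dx = shifts[, 2]),
                   rois = rois), class = "movie_data")
  })
}

# integer translation by (dy, dx); vacated pixels filled with the image median
translate_frame <- function(img, dy, dx, fill = stats::median(img)) {
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Intensities are clipped to `[0, clip_max]` and scaled to the 16-bit range.
#' Requires the `tiff` package.
#'
#' @param movie a `movie_data` object (or a raw rows x cols x frames array).
#' @param path output file path.
#' @param clip_max intensity mapped to the top of the 16-bit range.
#' @return Invisibly, `path`.
#' @export
write_movie_tiff <- function(movie, path, clip_max = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_config("the 'tiff' package is required to write movies")
  frames <- if (inherits(movie, "movie_data")) movie$frames else movie
  if (is.null(clip_max)) clip_max <- max(frames)
  pages <- lapply(seq_len(dim(frames)[3]), function(k)
    pmin(pmax(frames[, , k] / clip_max, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
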