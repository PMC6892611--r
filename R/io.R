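#' Read a simulation configuration from YAML or JSON
#'
#' The file holds fields named exactly as the [sim_config()] arguments;
#' unknown fields are rejected. YAML requires the `yaml` package.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  }
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(fields), allowed)
  if (length(unknown) > 0)
    stop_config("unknown config fields: %s", paste(unknown, collapse = ", "))
  do.call(sim_config, fields)
}

#' Read an eye trace from a two-column CSV
#'
#' @param path CSV with header columns `time_s`, `position_deg`.
#' @return An [eye_trace()].
#' @export
read_eye_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "position_deg") %in% names(df)))
    stop_config("eye-trace CSV needs columns time_s, position_deg")
  eye_trace(df$time_s, df$position_deg)
}

#' Read a trial schedule from CSV
#'
#' @param path CSV with at least `trial_id`, `target_side`, `suppressed`,
#'   `target_onset_s`.
#' @return Tibble.
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial_id", "target_side", "suppressed", "target_onset_s")
  if (!all(need %in% names(df)))
    stop_config("schedule CSV needs columns %s", paste(need, collapse = ", "))
  tibble::as_tibble(df)
}

#' Read an ROI set from JSON
#'
#' The JSON layout is a list of objects with `roi_id` and `pixels`, where
#' `pixels` is a list of `[row, col]` pairs, 0-based, origin top-left.
#'
#' @param path JSON file path.
#' @param image_shape integer c(rows, cols).
#' @return A [roi_set()].
#' @export
read_roi_json <- function(path, image_shape) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  pixels <- lapply(raw, function(r) {
    m <- do.call(rbind, lapply(r$pixels, function(p)
      c(as.integer(p[[1]]), as.integer(p[[2]]))))
    m + 1L  # 0-based on disk, 1-based in memory
  })
  ids <- vapply(raw, function(r) r$roi_id %||% NA_integer_, numeric(1))
  roi_set(pixels, image_shape, roi_id = ids)
}

#' Write an ROI set to JSON (0-based pixel coordinates)
#'
#' @param rois a [roi_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_roi_json <- function(rois, path) {
  out <- lapply(seq_along(rois$pixels), function(j) {
    m <- as.matrix(rois$pixels[[j]]) - 1L
    list(roi_id = rois$roi_id[[j]],
         pixels = lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ])))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}
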