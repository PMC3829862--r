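STACK_CHANNELS <- c("nuclear", "donor", "acceptor")

#' Write a time-lapse stack as multi-page TIFF + JSON sidecar
#'
#' Pages are written time-major (frame 1 channels nuclear/donor/acceptor,
#' then frame 2, ...) as 32-bit float samples scaled into \[0, 1\] by an
#' `intensity_scale` recorded in the sidecar. The sidecar (`<path>.json`)
#' documents axis order (`"tcyx"`), channel names, the timebase (times,
#' 0-based `dispense_index`, `n_pre`), the well id and the scale; pixel
#' coordinates in all exported tables are 0-based (row, col) half-open masks.
#'
#' @param stack a `timelapse_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly usable (returned).
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$frames)
  scale <- max(stack$frames, 1)
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) {
    k <- k + 1L
    pages[[k]] <- stack$frames[t, c, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  sidecar <- list(
    well_id = stack$well_id,
    axes = "tcyx",
    channels = STACK_CHANNELS,
    n_frames = d[1],
    height = d[3], width = d[4],
    times = stack$timebase$times,
    dispense_index = stack$timebase$dispense_index,
    n_pre = stack$timebase$n_pre,
    intensity_scale = scale,
    coordinates = "0-based (row, col), half-open pixel masks")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  path
}

#' Read a time-lapse stack written by [write_stack]
#'
#' Validates the sidecar (axis order, channel set, frame count) and
#' reassembles the `[time, channel, y, x]` array, un-applying the intensity
#' scale. Errors name the missing or inconsistent field.
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return a `timelapse_stack` (without ground truth).
#' @export
read_stack <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path)) stop("missing sidecar JSON: ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (field in c("well_id", "axes", "channels", "n_frames", "times",
                  "dispense_index", "n_pre", "intensity_scale"))
    if (is.null(sc[[field]])) stop("sidecar is missing field '", field, "'")
  if (!identical(sc$axes, "tcyx"))
    stop("unsupported axis order '", sc$axes, "' (field 'axes'; expected \"tcyx\")")
  miss <- setdiff(STACK_CHANNELS, sc$channels)
  if (length(miss))
    stop("stack is missing channel '", miss[1], "' (field 'channels')")
  pages <- tiff::readTIFF(path, all = TRUE)
  n_t <- as.integer(sc$n_frames); n_c <- length(sc$channels)
  if (length(pages) != n_t * n_c)
    stop(sprintf("page count %d does not match n_frames x channels = %d (field 'n_frames')",
                 length(pages), n_t * n_c))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(n_t, n_c, h, w),
                  dimnames = list(NULL, sc$channels, NULL, NULL))
  k <- 0L
  for (t in seq_len(n_t)) for (c in seq_len(n_c)) {
    k <- k + 1L
    frames[t, c, , ] <- pages[[k]] * sc$intensity_scale
  }
  # reorder channels to the canonical order if needed
  frames <- frames[, STACK_CHANNELS, , , drop = FALSE]
  structure(list(frames = frames,
                 timebase = timebase(sc$times, as.integer(sc$n_pre)),
                 well_id = sc$well_id),
            class = "timelapse_stack")
}

#' Read and validate a plate-layout CSV
#'
#' Expects columns well_id, role, compound_id, concentration_uM, replicate
#' (UTF-8, comma separated, header row, "." decimal, zero-padded well ids).
#' Unknown roles and duplicate well ids are rejected with the offending row
#' number; an empty table is an error.
#'
#' @param path CSV path.
#' @return a `plate_layout` data.frame.
#' @export
read_layout <- function(path) {
  layout <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_layout(layout)
  layout$compound_id <- as.character(layout$compound_id)
  layout$compound_id[layout$compound_id %in% c("", "NA")] <- NA_character_
  class(layout) <- c("plate_layout", "data.frame")
  layout
}

#' Write the analysis result tables
#'
#' Writes `well_results.csv`, `screen_results.csv`, `plate_qc.csv` and, when
#' given, `traces.csv` (long format) into `dir`. Every table carries the run
#' `config_hash` as a column.
#'
#' @param results named list with any of `well_results`, `screen_table`,
#'   `plate_qc` (a `plate_qc` object or data.frame), `traces`.
#' @param dir output directory (created if needed).
#' @param config_hash character hash stamped on each table.
#' @return invisible character vector of written paths.
#' @export
write_results <- function(results, dir, config_hash = NA_character_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    df$config_hash <- config_hash
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  if (!is.null(results$well_results)) emit(results$well_results, "well_results.csv")
  if (!is.null(results$screen_table)) emit(results$screen_table, "screen_results.csv")
  if (!is.null(results$plate_qc)) {
    qc <- results$plate_qc
    if (inherits(qc, "plate_qc")) qc <- as.data.frame(qc)
    emit(qc, "plate_qc.csv")
  }
  if (!is.null(results$traces)) emit(results$traces, "traces.csv")
  invisible(written)
}

#' Per-cell trace table in long format
#'
#' @param traces list of normalized `calcium_trace`s.
#' @param tb a [timebase].
#' @param well_id well identifier.
#' @return data.frame: well_id, cell_id, frame (1-based), t_s, donor,
#'   acceptor, ratio, dff.
#' @export
traces_to_table <- function(traces, tb, well_id = NA_character_) {
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(well_id = well_id, cell_id = tr$cell_id,
               frame = seq_along(tr$ratio), t_s = tb$times,
               donor = tr$donor, acceptor = tr$acceptor,
               ratio = tr$ratio,
               dff = if (is.null(tr$dff)) NA_real_ else tr$dff)
  }))
}
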