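#' Extract a background-corrected ratio trace for one cell
#'
#' Per-frame mean donor and acceptor intensity within the cell mask, minus a
#' per-frame background estimate (the mean over pixels outside every cell
#' region, `background_policy = "field"`; or no correction, `"none"`), and
#' the acceptor/donor ratio. A trace whose corrected donor drops to <= 0 in
#' any frame is flagged invalid.
#'
#' @param stack a `timelapse_stack`.
#' @param cell_mask logical matrix (the cell's pixels), or an integer label
#'   matrix together with `cell_id`.
#' @param background_policy `"field"` (default) or `"none"`.
#' @param cell_id label to extract when `cell_mask` is a label matrix.
#' @return object of class `calcium_trace`: `cell_id`, `donor`, `acceptor`,
#'   `ratio` (per-frame), `baseline_donor`, `baseline_acceptor` (raw,
#'   uncorrected pre-dispense means used by artifact filters), `valid`.
#' @export
extract_trace <- function(stack, cell_mask, background_policy = c("field", "none"),
                          cell_id = NA_integer_) {
  background_policy <- match.arg(background_policy)
  if (!is.logical(cell_mask)) {
    if (is.na(cell_id)) stop("`cell_id` required when `cell_mask` is a label matrix")
    cell_mask <- cell_mask == cell_id
  }
  if (!any(cell_mask)) stop("empty cell mask")
  tr <- extract_traces_core(stack, list(which(cell_mask)),
                            background_policy)
  trace <- list(cell_id = cell_id, donor = tr$donor[1, ], acceptor = tr$acceptor[1, ],
                ratio = tr$ratio[1, ],
                baseline_donor = tr$baseline_donor[1],
                baseline_acceptor = tr$baseline_acceptor[1],
                valid = tr$valid[1])
  class(trace) <- "calcium_trace"
  trace
}

# Shared mean-extraction over a list of pixel index sets.
extract_traces_core <- function(stack, px_sets, background_policy) {
  n_frames <- dim(stack$frames)[1]
  n <- length(px_sets)
  donor <- acceptor <- matrix(NA_real_, n, n_frames)
  npx <- lengths(px_sets)
  all_cell <- unlist(px_sets, use.names = FALSE)
  h <- dim(stack$frames)[3]; w <- dim(stack$frames)[4]
  bg_px <- setdiff(seq_len(h * w), all_cell)
  raw_donor <- raw_acceptor <- matrix(NA_real_, n, n_frames)
  for (t in seq_len(n_frames)) {
    dframe <- stack$frames[t, "donor", , ]
    aframe <- stack$frames[t, "acceptor", , ]
    bg_d <- if (background_policy == "field" && length(bg_px))
      mean(dframe[bg_px]) else 0
    bg_a <- if (background_policy == "field" && length(bg_px))
      mean(aframe[bg_px]) else 0
    for (i in seq_len(n)) {
      md <- mean(dframe[px_sets[[i]]])
      ma <- mean(aframe[px_sets[[i]]])
      raw_donor[i, t] <- md; raw_acceptor[i, t] <- ma
      donor[i, t] <- md - bg_d
      acceptor[i, t] <- ma - bg_a
    }
  }
  valid <- apply(donor, 1, function(z) all(z > 0))
  ratio <- acceptor / donor
  ratio[!valid, ] <- NA_real_
  n_pre <- stack$timebase$n_pre
  list(donor = donor, acceptor = acceptor, ratio = ratio, valid = valid,
       baseline_donor = rowMeans(raw_donor[, seq_len(n_pre), drop = FALSE]),
       baseline_acceptor = rowMeans(raw_acceptor[, seq_len(n_pre), drop = FALSE]))
}

#' Extract ratio traces for every cell of a segmentation
#'
#' Vectorized multi-cell version of [extract_trace], using the
#' first-timepoint segmentation for every frame.
#'
#' @param stack a `timelapse_stack`.
#' @param seg a `cell_segmentation` (edge-excluded labels are used).
#' @param background_policy `"field"` or `"none"`.
#' @return list of `calcium_trace` objects (one per retained cell).
#' @export
extract_traces <- function(stack, seg, background_policy = c("field", "none")) {
  background_policy <- match.arg(background_policy)
  lab <- seg$cell_labels
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(list())
  pos <- which(lab > 0L)
  px_sets <- split(pos, lab[pos])
  px_sets <- px_sets[as.character(ids)]
  core <- extract_traces_core(stack, px_sets, background_policy)
  lapply(seq_along(ids), function(i) {
    structure(list(cell_id = ids[i], donor = core$donor[i, ],
                   acceptor = core$acceptor[i, ], ratio = core$ratio[i, ],
                   baseline_donor = core$baseline_donor[i],
                   baseline_acceptor = core$baseline_acceptor[i],
                   valid = core$valid[i]),
              class = "calcium_trace")
  })
}

#' Baseline-normalize a ratio trace
#'
#' F0 is the mean ratio over the pre-dispense frames; the normalized series
#' is dF/F0 = (F - F0) / F0 where F is the ratio at each frame.
#'
#' @param trace a `calcium_trace`.
#' @param tb a [timebase] (must have `n_pre >= 1`).
#' @return the trace with `f0` and `dff` fields added; a trace with
#'   `f0 <= 0` (or an already-invalid trace) is marked invalid.
#' @export
normalize_trace <- function(trace, tb) {
  if (tb$n_pre < 1L) stop("timebase must have at least one pre-dispense frame")
  if (!trace$valid) {
    trace$f0 <- NA_real_; trace$dff <- rep(NA_real_, length(trace$ratio))
    return(trace)
  }
  f0 <- mean(trace$ratio[seq_len(tb$n_pre)])
  if (!is.finite(f0) || f0 <= 0) {
    trace$valid <- FALSE
    trace$f0 <- NA_real_; trace$dff <- rep(NA_real_, length(trace$ratio))
    return(trace)
  }
  trace$f0 <- f0
  trace$dff <- (trace$ratio - f0) / f0
  trace
}

#' Peak evoked amplitude of a normalized trace
#'
#' Maximum of dF/F0 over the frames at/after the agonist dispense; frames in
#' the baseline window are ignored even if larger.
#'
#' @param trace a normalized `calcium_trace` (with `dff`).
#' @param tb a [timebase].
#' @return numeric peak (NA for invalid traces).
#' @export
peak_amplitude <- function(trace, tb) {
  if (is.null(trace$dff)) stop("trace is not normalized; call normalize_trace() first")
  if (!trace$valid) return(NA_real_)
  max(trace$dff[post_dispense_frames(tb)])
}

#' Classify a cell as agonist-responsive
#'
#' Responsive iff peak dF/F0 >= `threshold` (boundary inclusive). The default
#' 0.1 sits well below evoked peaks at default optics and above the noise
#' floor; [calibrate_threshold] helps pick a value from control wells.
#'
#' @param peak peak dF/F0.
#' @param threshold positive responsiveness threshold.
#' @return logical flag (NA peak gives FALSE).
#' @export
classify_responsive <- function(peak, threshold = 0.1) {
  if (threshold <= 0) stop("`threshold` must be positive")
  !is.na(peak) & peak >= threshold
}

#' Responsiveness threshold achieving a target responsive fraction
#'
#' Given peak amplitudes from control wells, returns the threshold at which
#' a `target_fraction` of cells would be called responsive (the
#' `1 - target_fraction` quantile of the peaks).
#'
#' @param peaks numeric vector of peak dF/F0 values.
#' @param target_fraction desired responsive fraction in (0, 1).
#' @return numeric threshold.
#' @export
calibrate_threshold <- function(peaks, target_fraction) {
  if (target_fraction <= 0 || target_fraction >= 1)
    stop("`target_fraction` must lie in (0, 1)")
  unname(stats::quantile(peaks[!is.na(peaks)], 1 - target_fraction, type = 7))
}

#' Summarize one well's traces
#'
#' Normalizes every trace, computes peak amplitudes and responsiveness calls,
#' and aggregates: cell counts, responsive fraction, and mean/sd of the peak
#' over responsive cells — the well's final assay readout. A well with fewer
#' than `min_responsive_cells` responsive cells (or no traces at all) is
#' marked invalid.
#'
#' @param traces list of `calcium_trace` objects from one well.
#' @param tb a [timebase].
#' @param threshold responsiveness threshold (see [classify_responsive]).
#' @param min_responsive_cells QC floor on responsive-cell count.
#' @param well_id identifier copied into the result.
#' @return one-row data.frame of class `well_result`: `well_id`, `n_cells`,
#'   `n_responsive`, `responsive_fraction`, `mean_peak_responsive`,
#'   `sd_peak_responsive`, `mean_peak_all` (mean peak over all cells — the
#'   statistic used for plate QC, where suppressed positive-control wells
#'   have too few responsive cells for the responsive-only readout),
#'   `baseline_donor`, `baseline_acceptor` (well means of the raw per-cell
#'   baselines), `valid`.
#' @export
summarize_well <- function(traces, tb, threshold = 0.1,
                           min_responsive_cells = 20L, well_id = NA_character_) {
  if (length(traces) == 0L)
    return(data.frame(well_id = well_id, n_cells = 0L, n_responsive = 0L,
                      responsive_fraction = NA_real_,
                      mean_peak_responsive = NA_real_,
                      sd_peak_responsive = NA_real_,
                      mean_peak_all = NA_real_,
                      baseline_donor = NA_real_, baseline_acceptor = NA_real_,
                      valid = FALSE))
  traces <- lapply(traces, normalize_trace, tb = tb)
  ok <- vapply(traces, `[[`, logical(1), "valid")
  peaks <- vapply(traces, function(tr)
    if (tr$valid) peak_amplitude(tr, tb) else NA_real_, numeric(1))
  resp <- classify_responsive(peaks, threshold)
  n_cells <- sum(ok)
  n_resp <- sum(resp[ok])
  valid <- n_resp >= min_responsive_cells
  data.frame(
    well_id = well_id,
    n_cells = n_cells,
    n_responsive = n_resp,
    responsive_fraction = if (n_cells > 0) n_resp / n_cells else NA_real_,
    mean_peak_responsive = if (valid) mean(peaks[ok & resp]) else NA_real_,
    sd_peak_responsive = if (valid) stats::sd(peaks[ok & resp]) else NA_real_,
    mean_peak_all = if (n_cells > 0) mean(peaks[ok]) else NA_real_,
    baseline_donor = mean(vapply(traces, `[[`, numeric(1), "baseline_donor")),
    baseline_acceptor = mean(vapply(traces, `[[`, numeric(1), "baseline_acceptor")),
    valid = valid)
}

#' Segment, extract and summarize one well
#'
#' The per-well single-cell analysis used by the pipeline: [segment_well],
#' [extract_traces], [summarize_well].
#'
#' @inheritParams summarize_well
#' @param stack a `timelapse_stack`.
#' @param background_policy see [extract_traces].
#' @param ... passed to [segment_well].
#' @return a `well_result` row (see [summarize_well]).
#' @export
analyze_well <- function(stack, threshold = 0.1, min_responsive_cells = 20L,
                         background_policy = "field", ...) {
  seg <- segment_well(stack, ...)
  traces <- extract_traces(stack, seg, background_policy)
  summarize_well(traces, stack$timebase, threshold, min_responsive_cells,
                 well_id = stack$well_id)
}
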