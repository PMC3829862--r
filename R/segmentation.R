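#' Segment nuclei from the nuclear-dye channel
#'
#' Gaussian smoothing, global thresholding (Otsu by default, or a fixed
#' absolute value), then distance-transform watershed to split touching
#' nuclei; components below `min_area_px` are dropped. Coordinates follow the
#' matrix convention (row = y, col = x), 1-based in R; exported tables use the
#' 0-based convention documented in the I/O sidecar.
#'
#' @param nuclear_frame 2-D non-negative numeric matrix.
#' @param min_area_px minimum object area in pixels.
#' @param smoothing_sigma Gaussian sigma in pixels.
#' @param threshold `"otsu"` or a numeric absolute intensity threshold.
#' @return integer label matrix (0 background, labels 1..n).
#' @export
segment_nuclei <- function(nuclear_frame, min_area_px = 20,
                           smoothing_sigma = 1, threshold = "otsu") {
  if (!is.matrix(nuclear_frame) || any(nuclear_frame < 0))
    stop("`nuclear_frame` must be a 2-D non-negative matrix")
  rng <- range(nuclear_frame)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(nuclear_frame), ncol(nuclear_frame)))
  sm <- EBImage::gblur(nuclear_frame, sigma = smoothing_sigma)
  if (identical(threshold, "otsu")) {
    norm <- (sm - min(sm)) / (max(sm) - min(sm))
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > th
  } else if (is.numeric(threshold)) {
    mask <- sm > threshold
  } else stop("`threshold` must be \"otsu\" or a numeric value")
  if (!any(mask)) return(matrix(0L, nrow(sm), ncol(sm)))
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- matrix(as.integer(lab), nrow(sm), ncol(sm))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area_px)
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  out[pos] <- relab[lab[pos]]
  out
}

#' Assign a cell region to every nucleus
#'
#' Nucleus-seeded region growing on a reference intensity image (typically
#' donor + acceptor at the first timepoint): pixels above an Otsu foreground
#' threshold and within `max_radius_px` of a nucleus are partitioned between
#' the seeds by intensity-guided propagation, so contested pixels between
#' adjacent cells are split along the dimmer boundary and no pixel is owned
#' by two cells. Every nucleus receives exactly one region (at least its own
#' pixels).
#'
#' @param nuclei_labels integer label matrix from [segment_nuclei].
#' @param reference_frame 2-D intensity matrix of the same size.
#' @param max_radius_px maximum distance a cell region may extend from its
#'   nucleus boundary's nearest pixel.
#' @return list: `cell_labels` (integer matrix, labels matching nuclei) and
#'   `map` (data.frame cell_id, nucleus_id — identical by construction).
#' @export
assign_cell_regions <- function(nuclei_labels, reference_frame, max_radius_px = 10) {
  if (!all(dim(nuclei_labels) == dim(reference_frame)))
    stop("`nuclei_labels` and `reference_frame` must have identical dimensions")
  ids <- sort(unique(nuclei_labels[nuclei_labels > 0L]))
  if (length(ids) == 0L)
    return(list(cell_labels = matrix(0L, nrow(nuclei_labels), ncol(nuclei_labels)),
                map = data.frame(cell_id = integer(0), nucleus_id = integer(0))))
  norm <- reference_frame - min(reference_frame)
  if (max(norm) > 0) norm <- norm / max(norm)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > th
  # distance from each pixel to the nearest nucleus pixel
  d <- EBImage::distmap(nuclei_labels == 0L)
  mask <- (fg & (d <= max_radius_px)) | nuclei_labels > 0L
  lab <- EBImage::propagate(EBImage::Image(norm), seeds = nuclei_labels,
                            mask = mask)
  cell_labels <- matrix(as.integer(lab), nrow(nuclei_labels), ncol(nuclei_labels))
  list(cell_labels = cell_labels,
       map = data.frame(cell_id = ids, nucleus_id = ids))
}

#' Remove cells touching the image border
#'
#' Any cell whose region has at least one pixel on the first or last row or
#' column of the frame is excluded (the strict whole-cell reading of the
#' edge rule); interior cells are untouched. Labels are preserved, not
#' renumbered.
#'
#' @param cell_labels integer label matrix.
#' @param nuclei_labels optional matching nucleus label matrix, filtered with
#'   the same label set.
#' @return object of class `cell_segmentation`: `cell_labels`,
#'   `nuclei_labels`, `cells` (data.frame cell_id, y, x centroid, area_px,
#'   edge_flag — edge cells retained in the table with `edge_flag = TRUE` but
#'   removed from the label images), `n_cells` (interior cells).
#' @export
exclude_edge_cells <- function(cell_labels, nuclei_labels = NULL) {
  ids <- sort(unique(cell_labels[cell_labels > 0L]))
  border <- c(cell_labels[1, ], cell_labels[nrow(cell_labels), ],
              cell_labels[, 1], cell_labels[, ncol(cell_labels)])
  edge_ids <- sort(unique(border[border > 0L]))
  pos <- which(cell_labels > 0L)
  labv <- cell_labels[pos]
  rows <- (pos - 1L) %% nrow(cell_labels) + 1L
  cols <- (pos - 1L) %/% nrow(cell_labels) + 1L
  area <- tabulate(labv)
  cy <- rowsum(as.numeric(rows), labv)[, 1] / area[sort(unique(labv))]
  cx <- rowsum(as.numeric(cols), labv)[, 1] / area[sort(unique(labv))]
  cells <- data.frame(cell_id = ids,
                      y = unname(cy), x = unname(cx),
                      area_px = area[ids],
                      edge_flag = ids %in% edge_ids)
  out_cells <- cell_labels
  out_cells[out_cells %in% edge_ids] <- 0L
  out_nuc <- nuclei_labels
  if (!is.null(out_nuc)) out_nuc[out_nuc %in% edge_ids] <- 0L
  structure(list(cell_labels = out_cells, nuclei_labels = out_nuc,
                 cells = cells, n_cells = sum(!cells$edge_flag)),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("cell_segmentation: %d cells retained (%d excluded at frame edge)\n",
              x$n_cells, sum(x$cells$edge_flag)))
  invisible(x)
}

#' Segment one well's stack
#'
#' Full segmentation of a time-lapse stack from its first timepoint only
#' (cells are assumed static): nuclei from the nuclear channel, cell regions
#' from the summed donor + acceptor image, then edge-cell exclusion. The
#' resulting labels are reused for every frame downstream.
#'
#' @param stack a `timelapse_stack`.
#' @param min_area_px,smoothing_sigma,threshold passed to [segment_nuclei].
#' @param max_radius_px passed to [assign_cell_regions].
#' @return a `cell_segmentation` (see [exclude_edge_cells]).
#' @export
segment_well <- function(stack, min_area_px = 20, smoothing_sigma = 1,
                         threshold = "otsu", max_radius_px = 10) {
  nuclear <- stack$frames[1, "nuclear", , ]
  reference <- stack$frames[1, "donor", , ] + stack$frames[1, "acceptor", , ]
  nuclei <- segment_nuclei(nuclear, min_area_px, smoothing_sigma, threshold)
  regions <- assign_cell_regions(nuclei, reference, max_radius_px)
  exclude_edge_cells(regions$cell_labels, nuclei)
}

#' Match detected nuclei to planted ground truth
#'
#' Greedy one-to-one matching of detected nucleus centroids to planted
#' centers within `max_dist` pixels; reports recall (planted cells found) and
#' precision (detections that correspond to a planted cell).
#'
#' @param seg a `cell_segmentation` (all detections, including edge cells).
#' @param truth_cells ground-truth cell table (columns y, x).
#' @param max_dist maximum center distance for a match (default one nucleus
#'   diameter's worth: 2 * 4 px).
#' @return list with `recall`, `precision`, `n_matched`.
#' @export
match_detections <- function(seg, truth_cells, max_dist = 8) {
  det <- seg$cells
  if (nrow(det) == 0L || nrow(truth_cells) == 0L)
    return(list(recall = 0, precision = 0, n_matched = 0L))
  d <- outer(det$y, truth_cells$y, "-")^2 + outer(det$x, truth_cells$x, "-")^2
  d <- sqrt(d)
  matched_det <- logical(nrow(det)); matched_tr <- logical(nrow(truth_cells))
  repeat {
    d[matched_det, ] <- Inf; d[, matched_tr] <- Inf
    m <- which.min(d)
    if (!length(m) || d[m] > max_dist) break
    i <- (m - 1L) %% nrow(d) + 1L; j <- (m - 1L) %/% nrow(d) + 1L
    matched_det[i] <- TRUE; matched_tr[j] <- TRUE
  }
  n <- sum(matched_det)
  list(recall = n / nrow(truth_cells), precision = n / nrow(det), n_matched = n)
}
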