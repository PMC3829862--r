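#' Simulate the ground-truth cell field of one well
#'
#' Places `n_cells` nucleus centers uniformly over the field by random
#' sequential adsorption (rejecting candidates closer than
#' `params$min_spacing` to an accepted center) and draws per-cell latent
#' state: responder flag, evoked-amplitude multiplier, baseline calcium and
#' transient time constants. Centers may fall near the border, so some
#' cytoplasm disks are clipped by the frame edge — those cells are the ones a
#' downstream edge filter is expected to discard.
#'
#' @param n_cells number of cells to place (>= 0).
#' @param field_shape height, width in pixels.
#' @param params a [sim_params].
#' @param seed integer seed; the field is deterministic given `seed`.
#' @return data.frame (one row per cell): `cell_id`, `y`, `x` (pixel coords,
#'   1-based), `nucleus_radius`, `cytoplasm_radius`, `is_responder`,
#'   `peak_scale` (0 for non-responders), `baseline_calcium`, `rise_tau`,
#'   `decay_tau`.
#' @export
simulate_field <- function(n_cells = NULL, field_shape = NULL, params = sim_params(),
                           seed = 1L) {
  if (is.null(n_cells)) n_cells <- params$n_cells
  if (is.null(field_shape)) field_shape <- params$field_shape
  n_cells <- as.integer(n_cells)
  if (n_cells < 0) stop("`n_cells` must be >= 0")
  h <- field_shape[1]; w <- field_shape[2]
  cols <- c("cell_id", "y", "x", "nucleus_radius", "cytoplasm_radius",
            "is_responder", "peak_scale", "baseline_calcium",
            "rise_tau", "decay_tau")
  if (n_cells == 0L) {
    out <- as.data.frame(stats::setNames(replicate(length(cols), numeric(0),
                                                   simplify = FALSE), cols))
    out$is_responder <- logical(0)
    return(out)
  }
  set.seed(seed)
  ys <- numeric(n_cells); xs <- numeric(n_cells)
  placed <- 0L
  max_tries <- 400L * n_cells
  tries <- 0L
  min2 <- params$min_spacing^2
  while (placed < n_cells) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf("could not place %d cells with min spacing %.1f in a %dx%d field (packing too dense)",
                   n_cells, params$min_spacing, h, w))
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    if (placed > 0L) {
      d2 <- (ys[seq_len(placed)] - cy)^2 + (xs[seq_len(placed)] - cx)^2
      if (min(d2) < min2) next
    }
    placed <- placed + 1L
    ys[placed] <- cy; xs[placed] <- cx
  }
  responder <- stats::runif(n_cells) < params$responder_fraction
  peak_scale <- pmax(stats::rnorm(n_cells, mean = 1, sd = params$peak_scale_sd), 0.5)
  peak_scale[!responder] <- 0
  data.frame(
    cell_id = seq_len(n_cells),
    y = ys, x = xs,
    nucleus_radius = params$nucleus_radius,
    cytoplasm_radius = params$cytoplasm_radius,
    is_responder = responder,
    peak_scale = peak_scale,
    baseline_calcium = params$baseline_calcium,
    rise_tau = params$rise_tau,
    decay_tau = params$decay_tau)
}

# Normalized transient shape: 0 before/at dispense, rises with tau_r and
# decays with tau_d afterwards, scaled so its continuous-time maximum is 1.
transient_shape <- function(t_rel, rise_tau, decay_tau) {
  s <- ifelse(t_rel <= 0, 0,
              (1 - exp(-t_rel / rise_tau)) * exp(-t_rel / decay_tau))
  t_peak <- rise_tau * log1p(decay_tau / rise_tau)
  s_max <- (1 - exp(-t_peak / rise_tau)) * exp(-t_peak / decay_tau)
  s / s_max
}

#' Per-cell calcium time course
#'
#' Deterministic latent calcium series for one cell: flat at
#' `baseline_calcium` before the agonist dispense; responders then add an
#' evoked transient (fast exponential rise, slower exponential decay) with
#' amplitude `evoked_amplitude * peak_scale * genotype_amplitude *
#' (1 - suppression)`. Non-responders (`peak_scale = 0`) and fully suppressed
#' wells (`suppression = 1`) give a constant series.
#'
#' @param cell one row of a [simulate_field] data.frame (list-like with
#'   `baseline_calcium`, `peak_scale`, `rise_tau`, `decay_tau`).
#' @param tb a [timebase].
#' @param suppression evoked-release suppression in \[0, 1\].
#' @param genotype_amplitude genotype fold-change multiplier.
#' @param evoked_amplitude evoked calcium amplitude at unit multipliers.
#' @return numeric vector of calcium values, one per frame.
#' @export
calcium_series <- function(cell, tb, suppression = 0, genotype_amplitude = 1,
                           evoked_amplitude = 0.6) {
  if (suppression < 0 || suppression > 1)
    stop("`suppression` must lie in [0, 1]")
  if (cell$rise_tau <= 0 || cell$decay_tau <= 0)
    stop("time constants must be positive")
  amp <- evoked_amplitude * cell$peak_scale * genotype_amplitude * (1 - suppression)
  base <- rep(cell$baseline_calcium, length(tb$times))
  if (amp == 0) return(base)
  base + amp * transient_shape(tb$times - tb$dispense_time,
                               cell$rise_tau, cell$decay_tau)
}

#' FRET-sensor ratio map
#'
#' Saturating Hill-type map from calcium to the acceptor/donor emission
#' ratio: `r0 + r_dyn * ca / (ca + k_half)`. Monotone increasing, saturating
#' at `r0 + r_dyn`; the defaults place half-saturation far above the evoked
#' calcium range so screen-relevant responses stay near-linear.
#'
#' @param calcium calcium values (arbitrary units, >= 0).
#' @param sensor sensor parameter list (see [sim_params]).
#' @return emission ratio values.
#' @export
sensor_ratio <- function(calcium, sensor = sim_params()$sensor) {
  sensor$r0 + sensor$r_dyn * calcium / (calcium + sensor$k_half)
}

# Ground-truth label image: each pixel within cytoplasm_radius of a center is
# owned by the nearest center (contested pixels go to the closer nucleus, ties
# to the lower cell_id). Returns an integer matrix; 0 = background.
field_label_image <- function(cells, field_shape) {
  h <- field_shape[1]; w <- field_shape[2]
  lab <- matrix(0L, h, w)
  if (nrow(cells) == 0L) return(lab)
  best <- matrix(Inf, h, w)
  for (i in seq_len(nrow(cells))) {
    r <- cells$cytoplasm_radius[i]
    y0 <- max(1L, floor(cells$y[i] - r)); y1 <- min(h, ceiling(cells$y[i] + r))
    x0 <- max(1L, floor(cells$x[i] - r)); x1 <- min(w, ceiling(cells$x[i] + r))
    yy <- y0:y1; xx <- x0:x1
    d2 <- outer((yy - cells$y[i])^2, (xx - cells$x[i])^2, "+")
    inside <- d2 <= r^2
    sub_best <- best[yy, xx, drop = FALSE]
    take <- inside & (d2 < sub_best)
    if (any(take)) {
      sub_lab <- lab[yy, xx, drop = FALSE]
      sub_lab[take] <- cells$cell_id[i]
      sub_best[take] <- d2[take]
      lab[yy, xx] <- sub_lab
      best[yy, xx] <- sub_best
    }
  }
  lab
}

# Nucleus-only mask (integer labels) from a field data.frame.
nucleus_label_image <- function(cells, field_shape) {
  h <- field_shape[1]; w <- field_shape[2]
  lab <- matrix(0L, h, w)
  for (i in seq_len(nrow(cells))) {
    r <- cells$nucleus_radius[i]
    y0 <- max(1L, floor(cells$y[i] - r)); y1 <- min(h, ceiling(cells$y[i] + r))
    x0 <- max(1L, floor(cells$x[i] - r)); x1 <- min(w, ceiling(cells$x[i] + r))
    yy <- y0:y1; xx <- x0:x1
    d2 <- outer((yy - cells$y[i])^2, (xx - cells$x[i])^2, "+")
    sub <- lab[yy, xx, drop = FALSE]
    sub[d2 <= r^2] <- cells$cell_id[i]
    lab[yy, xx] <- sub
  }
  lab
}

add_shot_noise <- function(img, scale) {
  if (scale <= 0) return(img)
  pmax(img + scale * sqrt(pmax(img, 0)) * stats::rnorm(length(img)), 0)
}

#' Render a time-lapse stack from ground truth
#'
#' Converts per-cell calcium series into a three-channel image stack. The
#' nuclear channel is static (bright nucleus disks over background). Donor and
#' acceptor intensities split a constant per-pixel sensor emission according
#' to the [sensor_ratio] map, so acceptor/donor equals the mapped ratio
#' exactly at zero noise and increases with calcium. Gaussian shot noise
#' (sd = `photon_noise_scale * sqrt(intensity)`) and uniform per-channel
#' background are added; optional autofluorescence offsets emulate fluorescent
#' compounds.
#'
#' @param cells field data.frame from [simulate_field].
#' @param calcium matrix \[cells x frames\] of calcium values (one row per
#'   cell, in `cells` order).
#' @param tb a [timebase].
#' @param params a [sim_params] (optics, noise, background).
#' @param seed integer seed for the noise draws.
#' @param well_id well identifier stored on the stack.
#' @return An object of class `timelapse_stack`: list with `frames` (array
#'   `[time, channel, y, x]`, channels nuclear/donor/acceptor), `timebase`,
#'   `well_id`, and ground truth attached as `truth` (the `cells` table plus
#'   label images `cell_labels`, `nuclei_labels`).
#' @export
render_stack <- function(cells, calcium, tb, params = sim_params(), seed = 1L,
                         well_id = "A01") {
  n_frames <- length(tb$times)
  if (nrow(cells) > 0L &&
      (!is.matrix(calcium) || nrow(calcium) != nrow(cells) ||
       ncol(calcium) != n_frames))
    stop("`calcium` must be a [cells x frames] matrix matching `cells` and `tb`")
  h <- params$field_shape[1]; w <- params$field_shape[2]
  lab <- field_label_image(cells, params$field_shape)
  nuc <- nucleus_label_image(cells, params$field_shape)
  bg <- params$background
  af <- params$autofluorescence
  sens <- params$sensor
  set.seed(seed)
  frames <- array(0, dim = c(n_frames, 3L, h, w),
                  dimnames = list(NULL, c("nuclear", "donor", "acceptor"), NULL, NULL))
  cellpx <- which(lab > 0L)
  labv <- lab[cellpx]
  nuc_img <- matrix(bg[["nuclear"]], h, w)
  nuc_img[nuc > 0L] <- bg[["nuclear"]] + params$nuclear_amplitude
  for (t in seq_len(n_frames)) {
    donor <- matrix(bg[["donor"]] + af[["donor"]], h, w)
    acceptor <- matrix(bg[["acceptor"]] + af[["acceptor"]], h, w)
    if (length(cellpx)) {
      ratio_t <- sensor_ratio(calcium[, t], sens)
      donor_cell <- sens$total / (1 + ratio_t)
      acceptor_cell <- sens$total - donor_cell
      donor[cellpx] <- donor[cellpx] + donor_cell[labv]
      acceptor[cellpx] <- acceptor[cellpx] + acceptor_cell[labv]
    }
    frames[t, "nuclear", , ] <- add_shot_noise(nuc_img, params$photon_noise_scale)
    frames[t, "donor", , ] <- add_shot_noise(donor, params$photon_noise_scale)
    frames[t, "acceptor", , ] <- add_shot_noise(acceptor, params$photon_noise_scale)
  }
  structure(
    list(frames = frames, timebase = tb, well_id = well_id,
         truth = list(cells = cells, cell_labels = lab, nuclei_labels = nuc)),
    class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("timelapse_stack %s: %d frames x %d channels x %dx%d px\n",
              x$well_id, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Simulate one complete well (field, dynamics, rendering)
#'
#' Convenience wrapper: [simulate_field], per-cell [calcium_series] under the
#' given suppression, then [render_stack]. Toxicity reduces the number of
#' cells seeded; the responder flags and amplitudes come from the field draw.
#'
#' @inheritParams render_stack
#' @param suppression evoked-release suppression applied to the whole well.
#' @param n_cells override of `params$n_cells` (before toxicity).
#' @return a `timelapse_stack` with ground truth attached (including the
#'   applied `suppression` in `truth$suppression`).
#' @export
simulate_well <- function(params = sim_params(), seed = 1L, suppression = 0,
                          well_id = "A01", n_cells = NULL) {
  if (is.null(n_cells)) n_cells <- params$n_cells
  n_eff <- as.integer(round(n_cells * (1 - params$toxicity)))
  cells <- simulate_field(n_eff, params$field_shape, params, seed = seed)
  tb <- default_timebase()
  calcium <- matrix(0, nrow(cells), length(tb$times))
  for (i in seq_len(nrow(cells)))
    calcium[i, ] <- calcium_series(cells[i, ], tb, suppression,
                                   params$genotype_amplitude,
                                   params$evoked_amplitude)
  stack <- render_stack(cells, calcium, tb, params, seed = seed + 500000L,
                        well_id = well_id)
  stack$truth$suppression <- suppression
  stack
}
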