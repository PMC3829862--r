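#' Simulation parameters for synthetic plates
#'
#' Bundles every knob of the synthetic-plate generator. Defaults emulate the
#' screening cell line: an FAD-mutant presenilin background in which nearly the
#' whole population responds to carbachol and the evoked peak is about 3-fold
#' the wild-type amplitude. Use `genotype = "WT"` for the wild-type presets
#' (29% responders, unit amplitude).
#'
#' The calcium scale is arbitrary (the sensor map converts it to a FRET ratio):
#' resting calcium sits at `baseline_calcium`, and a responding cell adds an
#' evoked component of amplitude
#' `evoked_amplitude * peak_scale * genotype_amplitude * (1 - suppression)`.
#' With the default sensor map (half-saturation far above the evoked range)
#' the measured dF/F0 is close to linear in that amplitude, so the 3-fold
#' genotype multiplier propagates to an approximately 3-fold measured peak.
#'
#' @param genotype `"FAD"` (default) or `"WT"`; sets `genotype_amplitude` and
#'   `responder_fraction` presets, both overridable.
#' @param genotype_amplitude evoked-amplitude fold-change versus wild type.
#' @param responder_fraction probability that a cell is agonist-responsive.
#' @param n_cells cells seeded per field (default 175, the midpoint of the
#'   150-200 cells typically detected per well).
#' @param field_shape image height and width in pixels.
#' @param nucleus_radius,cytoplasm_radius disk radii in pixels.
#' @param min_spacing minimum distance between nucleus centers in pixels.
#' @param baseline_calcium resting calcium, arbitrary units.
#' @param evoked_amplitude evoked calcium amplitude at unit `peak_scale`,
#'   unit genotype multiplier and zero suppression.
#' @param peak_scale_sd per-cell lognormal-like spread of the evoked amplitude
#'   (normal sd around 1, truncated below at 0.5).
#' @param rise_tau,decay_tau transient rise/decay time constants in seconds.
#' @param sensor list with `r0` (ratio at zero calcium), `r_dyn` (dynamic
#'   range of the ratio), `k_half` (half-saturation calcium) and `total`
#'   (summed donor+acceptor emission per cytoplasm pixel, counts).
#' @param background per-channel background level in counts
#'   (named: nuclear, donor, acceptor).
#' @param nuclear_amplitude nuclear-dye intensity above background, counts.
#' @param photon_noise_scale multiplier on sqrt(intensity) Gaussian shot
#'   noise; 0 disables noise.
#' @param control_suppression evoked-release suppression applied in
#'   positive-control (TP/CPA/TMB-8) wells.
#' @param autofluorescence per-channel additive intensity emulating an
#'   autofluorescent compound (named: donor, acceptor), counts.
#' @param toxicity fraction of seeded cells killed in the well (reduces
#'   cell count), in \[0, 1\].
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(genotype = c("FAD", "WT"),
                       genotype_amplitude = NULL,
                       responder_fraction = NULL,
                       n_cells = 175L,
                       field_shape = c(420L, 420L),
                       nucleus_radius = 4,
                       cytoplasm_radius = 9,
                       min_spacing = 19,
                       baseline_calcium = 0.1,
                       evoked_amplitude = 0.6,
                       peak_scale_sd = 0.15,
                       rise_tau = 0.8,
                       decay_tau = 4,
                       sensor = list(r0 = 1, r_dyn = 32, k_half = 80, total = 600),
                       background = c(nuclear = 50, donor = 100, acceptor = 100),
                       nuclear_amplitude = 800,
                       photon_noise_scale = 1,
                       control_suppression = 0.9,
                       autofluorescence = c(donor = 0, acceptor = 0),
                       toxicity = 0) {
  genotype <- match.arg(genotype)
  if (is.null(genotype_amplitude))
    genotype_amplitude <- if (genotype == "FAD") 3 else 1
  if (is.null(responder_fraction))
    responder_fraction <- if (genotype == "FAD") 0.96 else 0.29
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("`responder_fraction` must lie in [0, 1]")
  if (toxicity < 0 || toxicity > 1)
    stop("`toxicity` must lie in [0, 1]")
  if (genotype_amplitude < 0) stop("`genotype_amplitude` must be >= 0")
  if (rise_tau <= 0 || decay_tau <= 0) stop("time constants must be positive")
  if (nucleus_radius <= 0 || cytoplasm_radius <= 0) stop("radii must be positive")
  stopifnot(all(c("r0", "r_dyn", "k_half", "total") %in% names(sensor)),
            all(c("nuclear", "donor", "acceptor") %in% names(background)),
            all(c("donor", "acceptor") %in% names(autofluorescence)))
  structure(
    list(genotype = genotype,
         genotype_amplitude = genotype_amplitude,
         responder_fraction = responder_fraction,
         n_cells = as.integer(n_cells),
         field_shape = as.integer(field_shape),
         nucleus_radius = nucleus_radius,
         cytoplasm_radius = cytoplasm_radius,
         min_spacing = min_spacing,
         baseline_calcium = baseline_calcium,
         evoked_amplitude = evoked_amplitude,
         peak_scale_sd = peak_scale_sd,
         rise_tau = rise_tau,
         decay_tau = decay_tau,
         sensor = sensor,
         background = background,
         nuclear_amplitude = nuclear_amplitude,
         photon_noise_scale = photon_noise_scale,
         control_suppression = control_suppression,
         autofluorescence = autofluorescence,
         toxicity = toxicity),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "sim_params: %s-like (amplitude x%.1f, responder fraction %.2f), %d cells/field, field %dx%d px, noise scale %.2f\n",
    x$genotype, x$genotype_amplitude, x$responder_fraction, x$n_cells,
    x$field_shape[1], x$field_shape[2], x$photon_noise_scale))
  invisible(x)
}
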