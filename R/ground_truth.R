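# Forward and inverse maps between planted suppression and the normalized
# response the assay would measure on an ideal (noiseless, unit peak_scale)
# well. Used to plant screens with known truth and to verify recovery.

# Sampled maximum of the normalized transient shape on the default frame grid.
sampled_peak_factor <- function(params, tb = default_timebase()) {
  max(transient_shape(tb$times - tb$dispense_time,
                      params$rise_tau, params$decay_tau))
}

#' Noise-free normalized response implied by a suppression level
#'
#' Evaluates the generator's own forward model: the peak dF/F0 a unit-scale
#' cell would show under suppression `s`, divided by the same quantity at
#' suppression 0 — i.e. the true normalized ER calcium response planted in a
#' well. Accounts for the sensor map's (mild) saturation and the frame
#' sampling of the transient.
#'
#' @param suppression suppression value(s) in \[0, 1\].
#' @param params a [sim_params].
#' @return normalized response value(s) in \[0, 1\].
#' @export
true_normalized_response <- function(suppression, params = sim_params()) {
  m <- sampled_peak_factor(params)
  b <- params$baseline_calcium
  A <- params$evoked_amplitude * params$genotype_amplitude
  r0 <- sensor_ratio(b, params$sensor)
  dff <- function(s) (sensor_ratio(b + A * (1 - s) * m, params$sensor) - r0) / r0
  dff(suppression) / dff(0)
}

#' Suppression that plants a target normalized response
#'
#' Inverts [true_normalized_response] by root finding, so a synthetic screen
#' can be seeded with compounds of exactly known activity.
#'
#' @param target target normalized response(s) in \[0, 1\].
#' @param params a [sim_params].
#' @return suppression value(s).
#' @export
suppression_for_normalized_response <- function(target, params = sim_params()) {
  vapply(target, function(r) {
    if (r >= 1) return(0)
    if (r <= 0) return(1)
    stats::uniroot(function(s) true_normalized_response(s, params) - r,
                   c(0, 1), tol = 1e-12)$root
  }, numeric(1))
}
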