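#' Normalize well readouts to same-plate DMSO controls
#'
#' Divides every valid well's mean responsive-cell peak by the mean of the
#' valid DMSO wells' readout on the same plate — the "normalized ER calcium
#' response" score (DMSO wells average ~1 by construction).
#'
#' @param well_results data.frame of `well_result` rows (one plate).
#' @param layout the plate layout (well_id, role, compound_id, replicate).
#' @return `well_results` joined with layout columns plus
#'   `normalized_response` (NA for invalid wells).
#' @export
normalize_to_dmso <- function(well_results, layout) {
  m <- merge(well_results, layout[, c("well_id", "role", "compound_id", "replicate")],
             by = "well_id", sort = FALSE)
  dmso <- m$role == "DMSO" & m$valid
  if (!any(dmso)) stop("no valid DMSO well on the plate")
  ref <- mean(m$mean_peak_responsive[dmso])
  if (!is.finite(ref) || ref <= 0) stop("DMSO reference mean is not positive")
  m$normalized_response <- ifelse(m$valid, m$mean_peak_responsive / ref, NA_real_)
  m
}

#' Aggregate replicate wells per compound
#'
#' Arithmetic mean and sample sd of the normalized response over a compound's
#' valid replicate wells; invalid replicates are excluded and counted. A
#' compound with no valid replicate is flagged unmeasured.
#'
#' @param normalized data.frame from [normalize_to_dmso].
#' @return data.frame of class `screen_table`: `compound_id`,
#'   `n_replicates`, `n_valid`, `normalized_response_mean`,
#'   `normalized_response_sd`, `unmeasured`.
#' @export
aggregate_replicates <- function(normalized) {
  cmp <- normalized[normalized$role == "compound", ]
  if (nrow(cmp) == 0L)
    return(data.frame(compound_id = character(0), n_replicates = integer(0),
                      n_valid = integer(0), normalized_response_mean = numeric(0),
                      normalized_response_sd = numeric(0), unmeasured = logical(0)))
  out <- do.call(rbind, lapply(split(cmp, cmp$compound_id), function(g) {
    v <- g$normalized_response[g$valid]
    data.frame(compound_id = g$compound_id[1],
               n_replicates = nrow(g),
               n_valid = length(v),
               normalized_response_mean = if (length(v)) mean(v) else NA_real_,
               normalized_response_sd = if (length(v) > 1) stats::sd(v) else
                 if (length(v) == 1) NA_real_ else NA_real_,
               unmeasured = length(v) == 0L)
  }))
  rownames(out) <- NULL
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Call screening hits
#'
#' A compound is a hit iff its mean normalized response is strictly below
#' `cutoff` (default 0.9, i.e. the evoked peak attenuated to <90% of the
#' DMSO controls) and it carries no artifact flag. The boundary value
#' exactly at `cutoff` is not a hit.
#'
#' @param screen_table a `screen_table`, optionally already carrying
#'   `autofluorescent`/`toxic` columns (see [flag_artifacts]).
#' @param cutoff hit threshold on the normalized response.
#' @return the table with a logical `hit` column added.
#' @export
call_hits <- function(screen_table, cutoff = 0.9) {
  artifact <- rep(FALSE, nrow(screen_table))
  if (!is.null(screen_table$autofluorescent))
    artifact <- artifact | screen_table$autofluorescent
  if (!is.null(screen_table$toxic))
    artifact <- artifact | screen_table$toxic
  screen_table$hit <- !screen_table$unmeasured &
    !is.na(screen_table$normalized_response_mean) &
    screen_table$normalized_response_mean < cutoff &
    !artifact
  screen_table
}

#' Flag autofluorescent and toxic compounds
#'
#' Autofluorescent: a compound whose wells' raw pre-dispense per-cell donor
#' or acceptor baseline exceeds the DMSO-well mean by more than `k_sd`
#' standard deviations (of the DMSO wells). Toxic: detected cell count below
#' fraction `f_count` of the plate median. A compound is flagged if the
#' majority of its replicate wells trigger the rule.
#'
#' @param normalized per-well data.frame from [normalize_to_dmso].
#' @param screen_table per-compound `screen_table` to annotate.
#' @param k_sd baseline outlier multiplier (default 5).
#' @param f_count toxic cell-count fraction of the plate median (default 0.3).
#' @return `screen_table` with logical `autofluorescent` and `toxic` columns.
#' @export
flag_artifacts <- function(normalized, screen_table, k_sd = 5, f_count = 0.3) {
  dmso <- normalized[normalized$role == "DMSO" & normalized$valid, ]
  if (nrow(dmso) < 2L) stop("need >= 2 valid DMSO wells to set artifact baselines")
  mu_d <- mean(dmso$baseline_donor); sd_d <- stats::sd(dmso$baseline_donor)
  mu_a <- mean(dmso$baseline_acceptor); sd_a <- stats::sd(dmso$baseline_acceptor)
  med_count <- stats::median(normalized$n_cells, na.rm = TRUE)
  # margin floored at a small relative value so a degenerate zero-variance
  # baseline (e.g. an idealized noise-free plate) cannot flag float jitter
  marg_d <- max(k_sd * sd_d, 1e-6 * abs(mu_d))
  marg_a <- max(k_sd * sd_a, 1e-6 * abs(mu_a))
  well_af <- (normalized$baseline_donor > mu_d + marg_d) |
    (normalized$baseline_acceptor > mu_a + marg_a)
  well_tox <- normalized$n_cells < f_count * med_count
  per_compound <- function(flags) {
    cmp <- normalized$role == "compound"
    v <- tapply(flags[cmp], normalized$compound_id[cmp],
                function(z) mean(z) > 0.5)
    stats::setNames(as.logical(v), names(v))
  }
  af <- per_compound(well_af)
  tox <- per_compound(well_tox)
  screen_table$autofluorescent <- unname(af[screen_table$compound_id])
  screen_table$toxic <- unname(tox[screen_table$compound_id])
  screen_table$autofluorescent[is.na(screen_table$autofluorescent)] <- FALSE
  screen_table$toxic[is.na(screen_table$toxic)] <- FALSE
  screen_table
}

#' Z'-factor plate quality control
#'
#' Screening-window statistic from positive (TP) and negative (DMSO) control
#' wells. Two variants are computed: the canonical Zhang et al. definition
#' `1 - 3 (sd_TP + sd_DMSO) / |mean_TP - mean_DMSO|` (the default and the
#' recommended one), and an "as printed" variant
#' `1 - (3 sd_TP + sd_DMSO) / |mean_TP - mean_DMSO|` that weights only the
#' positive-control sd by 3 (a formula that appears in some reports; the two
#' coincide when sd_DMSO = 0). Z' <= 1 always; > 0.5 indicates an excellent
#' assay.
#'
#' @param tp_values,dmso_values control-well readouts (>= 2 each).
#' @param plate_id identifier copied into the result.
#' @return object of class `plate_qc`: `plate_id`, `mu_tp`, `sigma_tp`,
#'   `mu_dmso`, `sigma_dmso`, `zprime_canonical`, `zprime_as_printed`.
#' @export
zprime <- function(tp_values, dmso_values, plate_id = NA_character_) {
  if (length(tp_values) < 2L || length(dmso_values) < 2L)
    stop("need at least 2 wells per control group")
  mu_tp <- mean(tp_values); sd_tp <- stats::sd(tp_values)
  mu_dmso <- mean(dmso_values); sd_dmso <- stats::sd(dmso_values)
  sep <- abs(mu_tp - mu_dmso)
  if (sep == 0) stop("Z' undefined: control means are equal")
  structure(
    list(plate_id = plate_id, mu_tp = mu_tp, sigma_tp = sd_tp,
         mu_dmso = mu_dmso, sigma_dmso = sd_dmso,
         zprime_canonical = 1 - 3 * (sd_tp + sd_dmso) / sep,
         zprime_as_printed = 1 - (3 * sd_tp + sd_dmso) / sep),
    class = "plate_qc")
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf("plate_qc%s: TP %.3f +/- %.3f, DMSO %.3f +/- %.3f, Z' = %.3f (canonical), %.3f (as printed)\n",
              if (is.na(x$plate_id)) "" else paste0(" ", x$plate_id),
              x$mu_tp, x$sigma_tp, x$mu_dmso, x$sigma_dmso,
              x$zprime_canonical, x$zprime_as_printed))
  invisible(x)
}

#' @export
as.data.frame.plate_qc <- function(x, ...) {
  data.frame(plate_id = x$plate_id, mu_tp = x$mu_tp, sigma_tp = x$sigma_tp,
             mu_dmso = x$mu_dmso, sigma_dmso = x$sigma_dmso,
             zprime_canonical = x$zprime_canonical,
             zprime_as_printed = x$zprime_as_printed)
}

#' Responsive-fraction summary by condition
#'
#' Mean and sd of the per-well responsive fraction and responsive-cell peak
#' for wells grouped by an experimental condition (e.g. genotype).
#'
#' @param well_results data.frame of `well_result` rows.
#' @param condition character/factor vector, one entry per well.
#' @return data.frame: `condition`, `n_wells`, `responsive_fraction_mean`,
#'   `responsive_fraction_sd`, `mean_peak_mean`, `mean_peak_sd`.
#' @export
responsive_fraction_report <- function(well_results, condition) {
  stopifnot(length(condition) == nrow(well_results))
  out <- do.call(rbind, lapply(split(well_results, condition), function(g) {
    data.frame(condition = NA_character_,
               n_wells = nrow(g),
               responsive_fraction_mean = mean(g$responsive_fraction, na.rm = TRUE),
               responsive_fraction_sd = stats::sd(g$responsive_fraction),
               mean_peak_mean = mean(g$mean_peak_responsive, na.rm = TRUE),
               mean_peak_sd = stats::sd(g$mean_peak_responsive))
  }))
  out$condition <- names(split(well_results, condition))
  rownames(out) <- NULL
  out[, c("condition", "n_wells", "responsive_fraction_mean",
          "responsive_fraction_sd", "mean_peak_mean", "mean_peak_sd")]
}
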