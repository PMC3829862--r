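PLATE_ROLES <- c("compound", "DMSO", "untreated", "TP", "CPA", "TMB-8")
CONTROL_ROLES <- c("TP", "CPA", "TMB-8")

#' Well identifiers of a 384-well plate
#' @return character vector "A01".."P24" in row-major order.
#' @export
well_ids_384 <- function() {
  as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0)))
}

#' Build a screening plate layout
#'
#' Lays out compounds (each in `replicates` adjacent wells at a single
#' concentration) together with DMSO vehicle, untreated and positive-control
#' (TP/CPA/TMB-8) wells on a 384-well grid. The number of control wells per
#' plate is a free parameter of the design.
#'
#' @param compound_ids character vector of compound identifiers.
#' @param replicates wells per compound (default 4).
#' @param concentration_uM screening concentration (default 10).
#' @param n_dmso,n_untreated,n_tp,n_cpa,n_tmb8 numbers of control wells.
#' @return data.frame of class `plate_layout` with columns `well_id`, `role`,
#'   `compound_id` (NA for non-compound wells), `concentration_uM`,
#'   `replicate`.
#' @export
plate_layout <- function(compound_ids = character(), replicates = 4L,
                         concentration_uM = 10,
                         n_dmso = 16L, n_untreated = 4L,
                         n_tp = 16L, n_cpa = 4L, n_tmb8 = 4L) {
  n_needed <- length(compound_ids) * replicates + n_dmso + n_untreated +
    n_tp + n_cpa + n_tmb8
  ids <- well_ids_384()
  if (n_needed > length(ids))
    stop(sprintf("layout needs %d wells but a plate has %d", n_needed, length(ids)))
  if (n_dmso < 1L || n_tp < 1L)
    stop("every plate needs at least one DMSO and one TP well")
  role <- c(rep("DMSO", n_dmso), rep("untreated", n_untreated),
            rep("TP", n_tp), rep("CPA", n_cpa), rep("TMB-8", n_tmb8),
            rep(rep("compound", replicates), length(compound_ids)))
  compound <- c(rep(NA_character_, n_dmso + n_untreated + n_tp + n_cpa + n_tmb8),
                rep(compound_ids, each = replicates))
  replicate <- c(rep(1L, n_dmso + n_untreated + n_tp + n_cpa + n_tmb8),
                 rep(seq_len(replicates), length(compound_ids)))
  out <- data.frame(well_id = ids[seq_along(role)], role = role,
                    compound_id = compound,
                    concentration_uM = ifelse(role == "compound",
                                              concentration_uM, NA_real_),
                    replicate = replicate)
  class(out) <- c("plate_layout", "data.frame")
  out
}

validate_layout <- function(layout) {
  req <- c("well_id", "role", "compound_id", "concentration_uM", "replicate")
  miss <- setdiff(req, names(layout))
  if (length(miss))
    stop("layout is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(layout) == 0L) stop("layout is empty")
  if (nrow(layout) > 384L) stop("a plate holds at most 384 wells")
  dup <- layout$well_id[duplicated(layout$well_id)]
  if (length(dup))
    stop(sprintf("duplicate well_id '%s' (row %d)", dup[1],
                 which(layout$well_id == dup[1])[2]))
  bad <- !(layout$role %in% PLATE_ROLES)
  if (any(bad))
    stop(sprintf("unknown role '%s' (row %d)", layout$role[bad][1], which(bad)[1]))
  invisible(layout)
}

# True evoked-release suppression for each well of a layout.
well_suppression <- function(layout, params, compound_suppression = NULL) {
  vapply(seq_len(nrow(layout)), function(i) {
    role <- layout$role[i]
    if (role %in% CONTROL_ROLES) return(params$control_suppression)
    if (role %in% c("DMSO", "untreated")) return(0)
    if (role == "compound") {
      cid <- layout$compound_id[i]
      if (!is.null(compound_suppression) && cid %in% names(compound_suppression))
        return(unname(compound_suppression[cid]))
      return(0)
    }
    stop("unknown role: ", role)
  }, numeric(1))
}

#' Simulate a whole plate
#'
#' Simulates every well of a layout with [simulate_well]. Positive-control
#' wells (TP/CPA/TMB-8) are rendered with `params$control_suppression`
#' (near-complete block of the evoked release); DMSO and untreated wells with
#' suppression 0; compound wells with the per-compound true suppression in
#' `compound_suppression`. Wells are processed one at a time: stacks are
#' either written to `dir` as TIFF + JSON sidecar, handed to `sink`, or (for
#' small layouts) kept in memory.
#'
#' @param layout a [plate_layout] (or any data.frame with its columns).
#' @param params a [sim_params].
#' @param seed integer; well `i` uses `seed + i` so the plate is deterministic.
#' @param compound_suppression named numeric vector (compound_id ->
#'   suppression in \[0, 1\]).
#' @param dir if non-NULL, write each stack with [write_stack] into `dir`
#'   along with `layout.csv` and `ground_truth.csv`.
#' @param sink if non-NULL, a `function(stack)` called per well (stack not
#'   retained); used to stream large plates through an analysis.
#' @param keep_stacks keep all stacks in memory (only sensible for small
#'   layouts); default when `dir` and `sink` are both NULL.
#' @return list with `layout`, `truth` (per-well data.frame: well_id, role,
#'   compound_id, suppression, n_cells_planted, n_responders_planted) and,
#'   if kept, `stacks` (named list) or `paths` (named TIFF paths).
#' @export
simulate_plate <- function(layout, params = sim_params(), seed = 1L,
                           compound_suppression = NULL, dir = NULL,
                           sink = NULL, keep_stacks = is.null(dir) && is.null(sink)) {
  validate_layout(layout)
  supp <- well_suppression(layout, params, compound_suppression)
  stacks <- if (keep_stacks) vector("list", nrow(layout)) else NULL
  paths <- if (!is.null(dir)) character(nrow(layout)) else NULL
  truth <- data.frame(well_id = layout$well_id, role = layout$role,
                      compound_id = layout$compound_id, suppression = supp,
                      n_cells_planted = NA_integer_,
                      n_responders_planted = NA_integer_)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(layout))) {
    st <- simulate_well(params, seed = seed + i, suppression = supp[i],
                        well_id = layout$well_id[i])
    truth$n_cells_planted[i] <- nrow(st$truth$cells)
    truth$n_responders_planted[i] <- sum(st$truth$cells$is_responder)
    if (!is.null(dir))
      paths[i] <- write_stack(st, file.path(dir, paste0(layout$well_id[i], ".tif")))
    if (!is.null(sink)) sink(st)
    if (keep_stacks) stacks[[i]] <- st
  }
  if (!is.null(dir)) {
    utils::write.csv(as.data.frame(layout), file.path(dir, "layout.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  out <- list(layout = layout, truth = truth)
  if (keep_stacks) out$stacks <- stats::setNames(stacks, layout$well_id)
  if (!is.null(dir)) out$paths <- stats::setNames(paths, layout$well_id)
  out
}

#' Simulate control-well readouts at the well level
#'
#' Draws per-well normalized assay readouts for positive (TP-like) and
#' negative (DMSO-like) control wells directly at the well level, for plate
#' quality-control studies where the image-level detail is irrelevant.
#' Defaults put DMSO at mean 1.0 (sd 0.03) and TP at mean 0.3 (sd 0.01).
#'
#' @param n_tp,n_dmso wells per control group.
#' @param mu_tp,sd_tp,mu_dmso,sd_dmso control means and well-level sds.
#' @param seed integer seed.
#' @return data.frame with columns `well_id`, `role`, `value`.
#' @export
simulate_control_wells <- function(n_tp = 16L, n_dmso = 16L,
                                   mu_tp = 0.3, sd_tp = 0.01,
                                   mu_dmso = 1.0, sd_dmso = 0.03,
                                   seed = 1L) {
  set.seed(seed)
  data.frame(
    well_id = sprintf("W%02d", seq_len(n_tp + n_dmso)),
    role = c(rep("TP", n_tp), rep("DMSO", n_dmso)),
    value = c(stats::rnorm(n_tp, mu_tp, sd_tp),
              stats::rnorm(n_dmso, mu_dmso, sd_dmso)))
}
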