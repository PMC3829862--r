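#' Tanimoto dissimilarity between binary fingerprints
#'
#' `1 - |a AND b| / |a OR b|`: 0 for identical fingerprints, 1 for disjoint
#' ones.
#'
#' @param fp_a,fp_b binary vectors (0/1 or logical) of equal length, each
#'   with at least one set bit.
#' @return dissimilarity in \[0, 1\].
#' @export
tanimoto_dissimilarity <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprints must have equal bit-length")
  a <- as.logical(fp_a); b <- as.logical(fp_b)
  if (!any(a) || !any(b)) stop("fingerprints must each have at least one set bit")
  1 - sum(a & b) / sum(a | b)
}

# All-pairs Tanimoto dissimilarity for a 0/1 matrix (compounds x bits).
tanimoto_matrix <- function(fps) {
  m <- (fps > 0) * 1
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  d
}

validate_fingerprints <- function(fps) {
  if (!is.matrix(fps)) fps <- as.matrix(fps)
  if (any(rowSums(fps > 0) == 0))
    stop("every fingerprint needs at least one set bit")
  fps
}

#' OptiSim representative selection
#'
#' Iterative dissimilarity-based subset selection. Compounds are first put in
#' canonical order (by name, so input permutation does not change the
#' result for a given seed). Then, repeatedly: the eligible pool is every
#' unselected compound farther than `radius_r` (Tanimoto dissimilarity) from
#' all current representatives; a random subsample of at most `subsample_k`
#' eligible compounds is drawn without replacement; the candidate with the
#' largest minimum dissimilarity to the selected set joins the selection
#' (ties to the earlier compound in canonical order; the very first
#' representative is the first subsample draw). Selection stops when no
#' compound is eligible.
#'
#' @param fps binary fingerprint matrix (compounds x bits), rownames =
#'   compound ids (optional).
#' @param subsample_k subsample size (>= 1).
#' @param radius_r exclusion radius in \[0, 1\].
#' @param seed integer seed; the selection is deterministic given the seed.
#' @return integer vector of selected row indices (in selection order), with
#'   compound ids as names when available.
#' @export
optisim_select <- function(fps, subsample_k = 10L, radius_r = 0.4, seed = 1L) {
  if (NROW(fps) == 0L) return(integer(0))
  fps <- validate_fingerprints(fps)
  if (subsample_k < 1L) stop("`subsample_k` must be >= 1")
  if (radius_r < 0 || radius_r > 1) stop("`radius_r` must lie in [0, 1]")
  n <- nrow(fps)
  ord <- if (!is.null(rownames(fps))) order(rownames(fps)) else seq_len(n)
  d <- tanimoto_matrix(fps[ord, , drop = FALSE])
  set.seed(seed)
  selected <- integer(0)
  min_dist <- rep(Inf, n)  # min dissimilarity to the selected set
  repeat {
    eligible <- which(min_dist > radius_r & !(seq_len(n) %in% selected))
    if (!length(eligible)) break
    k_eff <- min(subsample_k, length(eligible))
    sub <- eligible[sample.int(length(eligible), k_eff)]
    pick <- if (!length(selected)) sub[1] else {
      sub_sorted <- sort(sub)  # canonical tie-break
      sub_sorted[which.max(min_dist[sub_sorted])]
    }
    selected <- c(selected, pick)
    min_dist <- pmin(min_dist, d[, pick])
  }
  out <- ord[selected]
  if (!is.null(rownames(fps))) names(out) <- rownames(fps)[out]
  out
}

#' Cluster a screened compound set around OptiSim representatives
#'
#' Reproduces the screen's structure-activity clustering procedure:
#' (1) representatives are OptiSim-selected from the ACTIVE compounds
#' (normalized response < 0.9); (2) every active compound is assigned to its
#' nearest representative; (3) inactive compounds join the nearest
#' representative if within `assign_radius`, otherwise they fall into an
#' "unclustered" pool; (4) clusters whose representatives chain together
#' within `merge_radius` (single link) are merged; per-cluster activity
#' statistics are computed.
#'
#' @param fps binary fingerprint matrix with rownames = compound ids.
#' @param active logical vector, one flag per compound.
#' @param subsample_k,radius_r OptiSim parameters (see [optisim_select]).
#' @param assign_radius maximum dissimilarity for an inactive compound to
#'   join a cluster (default `radius_r`).
#' @param merge_radius single-link merge radius between representatives
#'   (default `radius_r`).
#' @param seed OptiSim seed.
#' @return object of class `compound_clusters`: `clusters` (data.frame
#'   cluster_id, representative, n_total, n_active, active_fraction, star,
#'   highlighted), `membership` (data.frame compound_id, cluster_id — 0 for
#'   the unclustered pool —, is_representative, active), `unclustered`
#'   (compound ids).
#' @export
cluster_compounds <- function(fps, active, subsample_k = 10L, radius_r = 0.4,
                              assign_radius = radius_r,
                              merge_radius = radius_r, seed = 1L) {
  fps <- validate_fingerprints(fps)
  if (is.null(rownames(fps)))
    rownames(fps) <- sprintf("C%03d", seq_len(nrow(fps)))
  stopifnot(length(active) == nrow(fps))
  ids <- rownames(fps)
  n <- nrow(fps)
  if (!any(active)) {
    memb <- data.frame(compound_id = ids, cluster_id = 0L,
                       is_representative = FALSE, active = active)
    return(structure(list(clusters = data.frame(), membership = memb,
                          unclustered = ids), class = "compound_clusters"))
  }
  act_idx <- which(active)
  reps_local <- optisim_select(fps[act_idx, , drop = FALSE], subsample_k,
                               radius_r, seed)
  reps <- act_idx[reps_local]
  d <- tanimoto_matrix(fps)
  # single-link merge of representatives within merge_radius (union-find)
  parent <- seq_along(reps)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(reps)) for (j in seq_along(reps)) {
    if (i < j && d[reps[i], reps[j]] <= merge_radius) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  group <- vapply(seq_along(reps), find, integer(1))
  cluster_of_rep <- match(group, sort(unique(group)))
  # assignment: nearest representative (ties -> earlier-selected rep)
  dist_to_reps <- d[, reps, drop = FALSE]
  nearest <- apply(dist_to_reps, 1, which.min)
  nearest_d <- dist_to_reps[cbind(seq_len(n), nearest)]
  cluster_id <- integer(n)
  cluster_id[active] <- cluster_of_rep[nearest[active]]
  inact <- which(!active)
  joins <- inact[nearest_d[inact] <= assign_radius]
  cluster_id[joins] <- cluster_of_rep[nearest[joins]]
  memb <- data.frame(compound_id = ids, cluster_id = cluster_id,
                     is_representative = seq_len(n) %in% reps,
                     active = active)
  clusters <- do.call(rbind, lapply(sort(unique(cluster_id[cluster_id > 0L])),
                                    function(cid) {
    in_c <- cluster_id == cid
    rep_id <- ids[reps[cluster_of_rep == cid][1]]
    n_tot <- sum(in_c); n_act <- sum(in_c & active)
    data.frame(cluster_id = cid, representative = rep_id,
               n_total = n_tot, n_active = n_act,
               active_fraction = n_act / n_tot,
               star = n_act / n_tot > 0.5,
               highlighted = (n_act / n_tot > 0.5) && (n_act > 4L))
  }))
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, membership = memb,
                 unclustered = ids[cluster_id == 0L]),
            class = "compound_clusters")
}

#' Annotate clusters with the map's display rules
#'
#' One row per cluster with the activity annotation used on the
#' structure-activity map: a cluster is a "star" when more than 50% of its
#' members are active, and "highlighted" when additionally its absolute
#' number of active compounds is greater than four.
#'
#' @param clusters a `compound_clusters` object (or its `clusters` table).
#' @return data.frame: cluster_id, representative, n_total, n_active,
#'   active_fraction, star, highlighted.
#' @export
annotate_clusters <- function(clusters) {
  tab <- if (inherits(clusters, "compound_clusters")) clusters$clusters else clusters
  if (NROW(tab) == 0L)
    return(data.frame(cluster_id = integer(0), representative = character(0),
                      n_total = integer(0), n_active = integer(0),
                      active_fraction = numeric(0), star = logical(0),
                      highlighted = logical(0)))
  tab$star <- tab$n_active / tab$n_total > 0.5
  tab$highlighted <- tab$star & tab$n_active > 4L
  tab
}

#' @export
print.compound_clusters <- function(x, ...) {
  cat(sprintf("compound_clusters: %d clusters, %d compounds (%d unclustered)\n",
              NROW(x$clusters), nrow(x$membership), length(x$unclustered)))
  invisible(x)
}

#' Random binary fingerprints for benchmarking
#'
#' Draws compounds around a few structural "scaffolds": each scaffold is a
#' random bit template and members flip a small fraction of bits, giving
#' realistic within/between-group Tanimoto structure.
#'
#' @param n_compounds number of compounds.
#' @param n_bits fingerprint length.
#' @param n_scaffolds number of scaffold templates.
#' @param flip_prob per-bit mutation probability within a scaffold.
#' @param density expected fraction of set bits in a template.
#' @param seed RNG seed.
#' @return 0/1 matrix with rownames `C001..`, and scaffold index as
#'   attribute `scaffold`.
#' @export
simulate_fingerprints <- function(n_compounds, n_bits = 128L, n_scaffolds = 4L,
                                  flip_prob = 0.05, density = 0.25, seed = 1L) {
  set.seed(seed)
  templates <- matrix(stats::runif(n_scaffolds * n_bits) < density,
                      n_scaffolds, n_bits)
  scaf <- sample.int(n_scaffolds, n_compounds, replace = TRUE)
  fps <- templates[scaf, , drop = FALSE]
  flips <- matrix(stats::runif(n_compounds * n_bits) < flip_prob,
                  n_compounds, n_bits)
  fps <- (fps != flips) * 1
  empty <- rowSums(fps) == 0
  fps[empty, 1] <- 1
  rownames(fps) <- sprintf("C%03d", seq_len(n_compounds))
  attr(fps, "scaffold") <- scaf
  fps
}
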