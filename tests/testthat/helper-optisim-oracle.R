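# Brute-force reference implementation of the OptiSim selection rule, written
# with naive loops and per-pair Tanimoto recomputation. It follows the same
# documented random-subsample protocol (canonical ordering, set.seed,
# sample.int) so results are comparable draw for draw.

optisim_oracle <- function(fps, subsample_k, radius_r, seed) {
  ord <- if (!is.null(rownames(fps))) order(rownames(fps)) else seq_len(nrow(fps))
  f <- fps[ord, , drop = FALSE]
  n <- nrow(f)
  tan <- function(i, j) {
    a <- f[i, ] > 0; b <- f[j, ] > 0
    1 - sum(a & b) / sum(a | b)
  }
  set.seed(seed)
  sel <- integer(0)
  repeat {
    elig <- integer(0)
    for (i in seq_len(n)) {
      if (i %in% sel) next
      ok <- TRUE
      for (s in sel) if (tan(i, s) <= radius_r) { ok <- FALSE; break }
      if (ok) elig <- c(elig, i)
    }
    if (!length(elig)) break
    k_eff <- min(subsample_k, length(elig))
    sub <- elig[sample.int(length(elig), k_eff)]
    if (!length(sel)) {
      pick <- sub[1]
    } else {
      sub <- sort(sub)
      best <- -1; pick <- sub[1]
      for (i in sub) {
        md <- Inf
        for (s in sel) md <- min(md, tan(i, s))
        if (md > best) { best <- md; pick <- i }
      }
    }
    sel <- c(sel, pick)
  }
  out <- ord[sel]
  if (!is.null(rownames(fps))) names(out) <- rownames(fps)[out]
  out
}
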