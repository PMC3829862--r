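# Small, fast parameter sets used across tests. "ideal" = noise-free plates
# with identical cells, where the pipeline should recover planted values to
# float precision.

fast_params <- function(...) {
  sim_params(n_cells = 30L, field_shape = c(160L, 160L), ...)
}

ideal_params <- function(...) {
  sim_params(photon_noise_scale = 0, peak_scale_sd = 0,
             responder_fraction = 1, n_cells = 30L,
             field_shape = c(160L, 160L), ...)
}

# A minimal hand-built calcium_trace.
make_trace <- function(ratio, donor = rep(100, length(ratio)),
                       acceptor = ratio * donor, cell_id = 1L) {
  structure(list(cell_id = cell_id, donor = donor, acceptor = acceptor,
                 ratio = ratio, baseline_donor = donor[1],
                 baseline_acceptor = acceptor[1], valid = TRUE),
            class = "calcium_trace")
}
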