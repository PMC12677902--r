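# Shared fixtures: reduced networks keep unit tests fast; the one
# full-size default motif used by the acceptance checks is computed once
# and cached for the whole session.

small_config <- function(n_circuits = 6L) {
  cfg <- network_config()
  cfg$n_circuits <- n_circuits
  cfg$pools <- c(RA = 6L * n_circuits, INT = 2L * n_circuits,
                 X = 2L * n_circuits)
  cfg$ra_per_circuit <- c(3L, 10L)
  cfg
}

short_solver <- function(duration = 250) solver_config(duration = duration)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

default_motif <- function(seed = 1L) {
  cached(paste0("motif", seed),
         run_motif(network_seed = seed, kick_nA = 0.5, kick_ms = 18,
                   solver = solver_config(duration = 420)))
}

small_motif <- function(seed = 1L, noise = noise_config(0), duration = 220) {
  cached(paste0("small", seed, "-", noise$sigma_pct, "-", noise$seed),
         run_motif(config = small_config(), network_seed = seed,
                   noise = noise, kick_nA = 0.5, kick_ms = 18,
                   solver = solver_config(duration = duration)))
}

# synthetic hvc_sim with prescribed spike trains (for validator fixtures)
fake_sim <- function(spikes, classes, duration = 300) {
  structure(list(time = seq(0, duration, by = 0.1),
                 V = NULL, spikes = spikes, stim = NULL,
                 seeds = list(network = 0L, noise = 0L),
                 solver = solver_config(duration = duration),
                 classes = classes, neuron_ids = seq_along(spikes)),
            class = "hvc_sim")
}
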