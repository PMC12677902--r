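## Time integration of the full network system.
##
## Default integrator: fixed-step RK4 for the deterministic terms with an
## Euler-Maruyama noise increment on each membrane potential (adaptive
## solvers are ill-posed with white noise). A noiseless adaptive reference
## (deSolve::lsoda on the same right-hand side) is retained for
## cross-integrator verification.

#' Solver configuration
#'
#' @param method `"fixed_rk4_em"` (default) or `"adaptive_reference"`.
#' @param dt Fixed step (ms).
#' @param duration Total simulated time (ms).
#' @param record_stride Trace recording stride, in steps (default records V
#'   every 0.1 ms at the default dt).
#' @param rel_tol,abs_tol Tolerances for the adaptive reference.
#' @return List of solver settings.
#' @export
solver_config <- function(method = c("fixed_rk4_em", "adaptive_reference"),
                          dt = 0.01, duration = 1000, record_stride = 10L,
                          rel_tol = 1e-6, abs_tol = 1e-8) {
  method <- match.arg(method)
  stopifnot(dt > 0, duration > 0, record_stride >= 1)
  list(method = method, dt = dt, duration = duration,
       record_stride = as.integer(record_stride),
       rel_tol = rel_tol, abs_tol = abs_tol)
}

#' Stimulus protocol
#'
#' A DC pulse or a train of identical pulses delivered to one or more
#' neurons. Returned as a data.frame of (target, t_on, t_off, amp_pA) rows;
#' several protocols can be row-bound together.
#'
#' @param targets Neuron id(s).
#' @param amplitude_nA Pulse amplitude in nA.
#' @param onsets Pulse onset time(s), ms (sorted).
#' @param pulse_width Pulse width, ms.
#' @return data.frame describing the stimulus.
#' @export
stimulus_protocol <- function(targets, amplitude_nA, onsets, pulse_width) {
  stopifnot(is.finite(amplitude_nA), pulse_width > 0, !is.unsorted(onsets))
  expand <- expand.grid(target = targets, t_on = onsets)
  data.frame(target = expand$target, t_on = expand$t_on,
             t_off = expand$t_on + pulse_width,
             amp_pA = amplitude_nA * 1000)
}

.empty_stim <- function() {
  data.frame(target = integer(0), t_on = numeric(0), t_off = numeric(0),
             amp_pA = numeric(0))
}

## resting state per neuron, cached by parameter signature; perturbed cells
## that no longer settle (e.g. tonically active after a conductance change)
## fall back to the end of the relaxation trajectory
.init_states <- function(cells) {
  cache <- new.env(parent = emptyenv())
  lapply(cells, function(np) {
    key <- paste(np$neuron_class, paste(.par_row(np), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    st <- tryCatch(unclass(resting_state(np)), error = function(e) {
      .state_list(e$trajectory$state, np$neuron_class)
    })
    cache[[key]] <- st
    st
  })
}

## map an hvc_network (or a bare cell list) to the compiled-integrator inputs
.pack_network <- function(cells, classes, synapses) {
  list(cls = vapply(classes, .class_code, integer(1)),
       pars = do.call(rbind, lapply(cells, .par_row)),
       kin = .kin_matrix(list(RA = .default_kinetics("RA"),
                              X = .default_kinetics("X"),
                              INT = .default_kinetics("INT"))),
       syn_pre = as.integer(synapses$pre) - 1L,
       syn_post = as.integer(synapses$post) - 1L,
       syn_kind = as.integer(synapses$kind == "GABA_A"),
       syn_g = as.numeric(synapses$g),
       syn_kin = .syn_kin_vec())
}

#' Simulate the network
#'
#' Integrates all neuron and synapse state variables jointly from per-class
#' resting states (synapse gates at 0) under the given stimulus, solver and
#' noise settings. Fully reproducible from `(net$seed, noise$seed, solver)`.
#'
#' @param net An `hvc_network` (must pass [validate_graph()]).
#' @param stim Stimulus data.frame from [stimulus_protocol()] (or `NULL`).
#' @param solver Settings from [solver_config()].
#' @param noise An `hvc_noise` config; `sigma_pct` is converted to a current
#'   amplitude via the mean synaptic conductance (see [noise_config()]).
#' @param record_traces Keep strided voltage traces (default `TRUE`).
#' @param spike_threshold,spike_refractory Spike (peak) detection settings
#'   applied at full step resolution inside the integrator.
#' @param init Optional full initial state vector (advanced use).
#' @return An object of class `hvc_sim`: `time`, `V` (time x neuron), per-
#'   neuron `spikes` (peak times, ms), `stim`, `seeds`, `solver`, `classes`.
#' @export
simulate <- function(net, stim = NULL, solver = solver_config(),
                     noise = noise_config(0), record_traces = TRUE,
                     spike_threshold = -20, spike_refractory = 1,
                     init = NULL) {
  viol <- validate_graph(net)
  if (length(viol)) {
    stop("invalid network:\n  ", paste(viol, collapse = "\n  "))
  }
  if (is.null(stim)) stim <- .empty_stim()
  if (nrow(stim) && !all(stim$target %in% net$neurons$id)) {
    stop("stimulus targets unknown neuron id(s)")
  }
  pk <- .pack_network(net$cells, net$neurons$class, net$synapses)
  if (is.null(init)) {
    states <- .init_states(net$cells)
    init <- c(unlist(lapply(seq_along(states), function(i)
      .state_vec(states[[i]], net$neurons$class[i]))),
      rep(0, nrow(net$synapses)))
  }
  sigma <- .noise_sigma_pA(noise, net)
  stim_m <- as.matrix(cbind(stim$target - 1L, stim$t_on, stim$t_off,
                            stim$amp_pA))
  if (!nrow(stim_m)) stim_m <- matrix(0, 0, 4)
  out <- sim_network_cpp(pk$cls, pk$pars, pk$kin, pk$syn_pre, pk$syn_post,
                         pk$syn_kind, pk$syn_g, pk$syn_kin, stim_m,
                         solver$dt, solver$duration, solver$record_stride,
                         sigma, noise$seed, init, spike_threshold,
                         spike_refractory, record_traces)
  structure(list(time = out$time, V = out$V, spikes = out$spikes,
                 state = out$state, stim = stim,
                 seeds = list(network = net$seed, noise = noise$seed),
                 solver = solver, noise = noise,
                 classes = net$neurons$class, neuron_ids = net$neurons$id),
            class = "hvc_sim")
}

#' @export
print.hvc_sim <- function(x, ...) {
  ns <- vapply(x$spikes, length, integer(1))
  cat("HVC simulation: ", length(x$spikes), " neurons, ",
      max(x$time), " ms, ", sum(ns), " spikes (",
      sum(ns > 0), " neurons active)\n", sep = "")
  invisible(x)
}

#' Simulate a single neuron (or a small hand-built motif)
#'
#' Convenience wrapper around the network integrator for isolated cells and
#' few-cell motifs used in calibration: takes bare `hvc_neuron` parameter
#' sets and an explicit synapse table instead of a full `hvc_network`.
#'
#' @param cells One `hvc_neuron` or a list of them (neuron ids are
#'   1..length(cells)).
#' @param synapses Optional data.frame (pre, post, kind, g).
#' @param stim Stimulus data.frame, see [stimulus_protocol()].
#' @param duration,dt,record_stride Solver settings.
#' @param sigma_pA Noise current amplitude in pA (applied to every cell).
#' @param noise_seed Seed for the noise stream.
#' @param state Optional named initial state (single cell) or list of named
#'   states; defaults to each cell's relaxed state.
#' @inheritParams simulate
#' @return An `hvc_sim` object.
#' @export
simulate_neuron <- function(cells, synapses = NULL, stim = NULL,
                            duration = 1000, dt = 0.01, record_stride = 10L,
                            sigma_pA = 0, noise_seed = 1L, state = NULL,
                            spike_threshold = -20, spike_refractory = 1) {
  if (inherits(cells, "hvc_neuron")) cells <- list(cells)
  classes <- vapply(cells, function(x) x$neuron_class, character(1))
  if (is.null(synapses)) {
    synapses <- data.frame(pre = integer(0), post = integer(0),
                           kind = character(0), g = numeric(0))
  }
  if (is.null(stim)) stim <- .empty_stim()
  pk <- .pack_network(cells, classes, synapses)
  if (is.null(state)) {
    states <- .init_states(cells)
  } else {
    if (!is.null(names(state))) state <- list(state)
    states <- state
  }
  init <- c(unlist(lapply(seq_along(states), function(i)
    .state_vec(states[[i]], classes[i]))), rep(0, nrow(synapses)))
  stim_m <- as.matrix(cbind(stim$target - 1L, stim$t_on, stim$t_off,
                            stim$amp_pA))
  if (!nrow(stim_m)) stim_m <- matrix(0, 0, 4)
  out <- sim_network_cpp(pk$cls, pk$pars, pk$kin, pk$syn_pre, pk$syn_post,
                         pk$syn_kind, pk$syn_g, pk$syn_kin, stim_m,
                         dt, duration, as.integer(record_stride),
                         sigma_pA, noise_seed, init, spike_threshold,
                         spike_refractory, TRUE)
  structure(list(time = out$time, V = out$V, spikes = out$spikes,
                 state = out$state, stim = stim,
                 seeds = list(noise = noise_seed),
                 solver = list(method = "fixed_rk4_em", dt = dt,
                               duration = duration,
                               record_stride = record_stride),
                 classes = classes, neuron_ids = seq_along(cells)),
            class = "hvc_sim")
}

#' Build and run one full song motif
#'
#' Wires the network (unless one is supplied), applies the kick-start DC
#' stimulus to the first RA neuron of the first microcircuit, and simulates
#' the full motif. A failure of the sequence to propagate is an analysis
#' outcome, not an error.
#'
#' @param config Network configuration, see [network_config()].
#' @param network_seed Construction seed (ignored if `net` is given).
#' @param net Optional pre-built (possibly perturbed) `hvc_network`.
#' @param noise An `hvc_noise` config.
#' @param solver Solver settings; the default simulates 1000 ms, long
#'   enough for the default 20 circuits to complete.
#' @param kick_nA,kick_ms Kick-start DC amplitude (nA) and duration (ms).
#' @param record_traces Keep voltage traces.
#' @return List with `net` and `result` (an `hvc_sim`).
#' @export
run_motif <- function(config = network_config(), network_seed = 1L,
                      net = NULL, noise = noise_config(0),
                      solver = solver_config(), kick_nA = 0.5,
                      kick_ms = 18, record_traces = TRUE) {
  if (is.null(net)) net <- wire_network(config, network_seed)
  first_ra <- net$circuits[[1]]$ra_ids[1]
  stim <- stimulus_protocol(first_ra, kick_nA, onsets = 10,
                            pulse_width = kick_ms)
  res <- simulate(net, stim, solver, noise, record_traces = record_traces)
  list(net = net, result = res)
}

#' Adaptive reference integration of a cell or motif
#'
#' Integrates the same right-hand side with `deSolve::lsoda` (noiseless),
#' used as the independent cross-check of the fixed-step engine.
#'
#' @inheritParams simulate_neuron
#' @return List with `time`, `V` matrix, and the deSolve output.
#' @export
simulate_reference <- function(cells, synapses = NULL, stim = NULL,
                               duration = 1000, dt_out = 0.05,
                               rel_tol = 1e-6, abs_tol = 1e-8, state = NULL) {
  if (!requireNamespace("deSolve", quietly = TRUE)) {
    stop("the adaptive reference requires the deSolve package")
  }
  if (inherits(cells, "hvc_neuron")) cells <- list(cells)
  classes <- vapply(cells, function(x) x$neuron_class, character(1))
  if (is.null(synapses)) {
    synapses <- data.frame(pre = integer(0), post = integer(0),
                           kind = character(0), g = numeric(0))
  }
  if (is.null(stim)) stim <- .empty_stim()
  pk <- .pack_network(cells, classes, synapses)
  if (is.null(state)) {
    states <- .init_states(cells)
  } else {
    if (!is.null(names(state))) state <- list(state)
    states <- state
  }
  y0 <- c(unlist(lapply(seq_along(states), function(i)
    .state_vec(states[[i]], classes[i]))), rep(0, nrow(synapses)))
  offs <- cumsum(c(0, vapply(classes, function(cl)
    length(.state_names(cl)), integer(1))))
  n <- length(cells)
  deriv <- function(t, y, parms) {
    Iext <- numeric(n)
    if (nrow(stim)) {
      for (s in seq_len(nrow(stim))) {
        if (t >= stim$t_on[s] && t < stim$t_off[s]) {
          Iext[stim$target[s]] <- Iext[stim$target[s]] + stim$amp_pA[s]
        }
      }
    }
    list(network_rhs_cpp(pk$cls, pk$pars, pk$kin, pk$syn_pre, pk$syn_post,
                         pk$syn_kind, pk$syn_g, pk$syn_kin, y, Iext))
  }
  ## integrate piecewise between stimulus discontinuities
  brk <- sort(unique(c(0, stim$t_on, stim$t_off, duration)))
  brk <- brk[brk >= 0 & brk <= duration]
  sol <- NULL
  y <- y0
  for (k in seq_len(length(brk) - 1)) {
    times <- unique(c(seq(brk[k], brk[k + 1], by = dt_out), brk[k + 1]))
    seg <- deSolve::lsoda(y, times, deriv, parms = NULL, rtol = rel_tol,
                          atol = abs_tol, maxsteps = 1e6)
    y <- as.numeric(seg[nrow(seg), -1])
    sol <- if (is.null(sol)) seg else rbind(sol, seg[-1, , drop = FALSE])
  }
  Vcols <- 1 + offs[seq_len(n)] + 1
  list(time = sol[, 1], V = sol[, Vcols, drop = FALSE], sol = sol)
}
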