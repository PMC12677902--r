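## Scripted in-silico experiments: paired-recording calibration motifs,
## targeted conductance perturbations, population variability, admissible
## conductance-range searches, and noise-tolerance scans.

#' Paired-recording calibration motifs
#'
#' Runs the five dual-recording stimulation motifs used to calibrate the
#' synapses: (A) RA -> INT -> X disynaptic pathway with pulses to RA,
#' (B) RA -> INT with pulses to RA, (C) INT -> X with pulses to INT,
#' (D) INT -> X with a 500 ms DC pulse to INT, (E) X -> INT with pulses to
#' X. Pulses are 10 ms, 0.5 nA (four pulses); the DC motif is 0.5 nA for
#' 500 ms. Reported per motif: PSP polarity and amplitude in the recorded
#' (postsynaptic) neuron.
#'
#' @param g Named synaptic conductances per motif edge. The defaults are
#'   single-pair calibration values: in the slice experiments the recorded
#'   PSPs are subthreshold, so the isolated pair uses weaker conductances
#'   than the network's per-edge ranges (whose model neurons stand for
#'   whole populations).
#' @param zero_g If `TRUE`, run with all synaptic conductances at zero
#'   (disconnected control).
#' @return data.frame with one row per motif: motif, recorded class,
#'   polarity, amplitude (mV).
#' @export
paired_recording_suite <- function(g = NULL, zero_g = FALSE) {
  if (is.null(g)) {
    ## motif A needs the interneuron to spike (it relays the disynaptic
    ## inhibition), so its RA->INT edge is stronger than the subthreshold
    ## dPSP motif B
    g <- c("RA->INT" = 2, "RA->INT(A)" = 12, "INT->X" = 10, "X->INT" = 2)
  }
  if (!"RA->INT(A)" %in% names(g)) g[["RA->INT(A)"]] <- g[["RA->INT"]]
  if (zero_g) g[] <- 0
  pulses <- function(target) {
    stimulus_protocol(target, 0.5, onsets = c(100, 200, 300, 400),
                      pulse_width = 10)
  }
  ## inhibitory responses are measured around the first pulse, before the
  ## post-inhibitory rebound depolarization dominates the trace
  run <- function(cells, syn, stim, rec, dur = 600, resp = c(95, dur)) {
    sim <- simulate_neuron(cells, syn, stim, duration = dur, dt = 0.01)
    psp_metrics(sim$V[, rec], sim$time, baseline_window = c(0, 90),
                response_window = resp)
  }
  ra <- neuron_params("RA"); int <- neuron_params("INT"); x <- neuron_params("X")
  rows <- list()
  ## A: RA -> INT -> X, record X (disynaptic iPSP)
  syn <- data.frame(pre = c(1, 2), post = c(2, 3),
                    kind = c("AMPA", "GABA_A"),
                    g = c(g[["RA->INT(A)"]], g[["INT->X"]]))
  m <- run(list(ra, int, x), syn, pulses(1), rec = 3, resp = c(95, 140))
  rows$A <- data.frame(motif = "A: RA->X (disynaptic)", recorded = "X",
                       polarity = m$polarity, amplitude = m$amplitude)
  ## B: RA -> INT, record INT (dPSP)
  syn <- data.frame(pre = 1, post = 2, kind = "AMPA", g = g[["RA->INT"]])
  m <- run(list(ra, int), syn, pulses(1), rec = 2)
  rows$B <- data.frame(motif = "B: RA->INT", recorded = "INT",
                       polarity = m$polarity, amplitude = m$amplitude)
  ## C: INT -> X, pulses, record X (iPSP)
  syn <- data.frame(pre = 1, post = 2, kind = "GABA_A", g = g[["INT->X"]])
  m <- run(list(int, x), syn, pulses(1), rec = 2, resp = c(95, 140))
  rows$C <- data.frame(motif = "C: INT->X (pulses)", recorded = "X",
                       polarity = m$polarity, amplitude = m$amplitude)
  ## D: INT -> X, 500 ms DC, record X (sustained hyperpolarization + sag;
  ## the response window covers the stimulation epoch, before the
  ## post-release rebound)
  stim <- stimulus_protocol(1, 0.5, onsets = 100, pulse_width = 500)
  sim <- simulate_neuron(list(int, x), syn, stim, duration = 700, dt = 0.01)
  m <- psp_metrics(sim$V[, 2], sim$time, c(0, 90), c(95, 595))
  ## sag: minimum during DC precedes the late (pre-release) level
  inwin <- sim$time >= 110 & sim$time <= 600
  vmin_t <- sim$time[inwin][which.min(sim$V[inwin, 2])]
  late <- mean(sim$V[sim$time >= 550 & sim$time <= 595, 2])
  sag <- late - min(sim$V[inwin, 2])
  rows$D <- data.frame(motif = "D: INT->X (500 ms DC)", recorded = "X",
                       polarity = m$polarity, amplitude = m$amplitude)
  rows$D$sag_mV <- sag
  rows$D$sag_min_precedes_release <- vmin_t < 550
  ## E: X -> INT, record INT (dPSP)
  syn <- data.frame(pre = 1, post = 2, kind = "AMPA", g = g[["X->INT"]])
  m <- run(list(x, int), syn, pulses(1), rec = 2)
  rows$E <- data.frame(motif = "E: X->INT", recorded = "INT",
                       polarity = m$polarity, amplitude = m$amplitude)
  out <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$sag_mV)) { r$sag_mV <- NA_real_; r$sag_min_precedes_release <- NA }
    r
  }))
  rownames(out) <- NULL
  out
}

#' Apply a conductance perturbation to a network copy
#'
#' Returns a deep copy of the network in which the named maximal
#' conductance of the selected neurons is scaled or set; the original
#' network is untouched.
#'
#' @param net An `hvc_network`.
#' @param class Target class (`"RA"`, `"X"`, `"INT"`).
#' @param ids Neuron ids to perturb, or `"population"` for every neuron of
#'   the class.
#' @param parameter Conductance name (`"g_SK"`, `"g_H"`, `"g_A"`,
#'   `"g_CaT"`, ...); must exist for the class.
#' @param mode `"scale"` (multiply) or `"set"` (absolute nS).
#' @param value Fold-change (> 0) or absolute value (>= 0).
#' @return The perturbed `hvc_network`.
#' @export
apply_perturbation <- function(net, class, ids = "population", parameter,
                               mode = c("scale", "set"), value) {
  mode <- match.arg(mode)
  stopifnot(class %in% .CLASSES)
  if (mode == "scale" && value <= 0) stop("fold-change must be > 0")
  if (identical(ids, "population")) {
    ids <- net$neurons$id[net$neurons$class == class]
  }
  if (!all(net$neurons$class[match(ids, net$neurons$id)] == class)) {
    stop("some target ids are not of class ", class)
  }
  probe <- net$cells[[ids[1]]]$pars
  if (!parameter %in% names(probe)) {
    stop("parameter '", parameter, "' does not exist for class ", class)
  }
  relevant <- switch(parameter,
                     g_CaT = c("X", "INT"), g_H = c("X", "INT"),
                     g_SK = c("RA", "X"), g_A = "RA", .CLASSES)
  if (!class %in% relevant) {
    stop("parameter '", parameter, "' is not expressed in class ", class)
  }
  for (id in ids) {
    old <- net$cells[[id]]$pars[[parameter]]
    new <- if (mode == "scale") old * value else value
    args <- stats::setNames(list(new), parameter)
    net$cells[[id]] <- do.call(neuron_params, c(list(class), args))
  }
  net
}

## desired-activity classifier for whole runs: complete ordered sequence,
## every RA burst realistic, and the X population within bounds up to a
## population-level tolerance (individual model neurons stand for pools)
.desired_activity_ok <- function(rep, x_tolerance = 0.75) {
  rep$sequence_complete && rep$all_ra_ok && mean(rep$x$ok) >= x_tolerance
}

.CANONICAL_PERTURBATIONS <- function(fold_up = 20) {
  list(
    list(label = "baseline", class = NA, parameter = NA, mode = NA, value = NA),
    list(label = "RA g_A up", class = "RA", parameter = "g_A",
         mode = "scale", value = fold_up),
    list(label = "RA g_SK up", class = "RA", parameter = "g_SK",
         mode = "scale", value = fold_up),
    list(label = "INT g_CaT x10", class = "INT", parameter = "g_CaT",
         mode = "scale", value = 10),
    list(label = "INT g_H x10", class = "INT", parameter = "g_H",
         mode = "scale", value = 10),
    list(label = "X g_H x10", class = "X", parameter = "g_H",
         mode = "scale", value = 10),
    list(label = "X g_CaT x15", class = "X", parameter = "g_CaT",
         mode = "scale", value = 15),
    list(label = "X g_SK to 0", class = "X", parameter = "g_SK",
         mode = "set", value = 0)
  )
}

#' Canonical perturbation battery
#'
#' Runs the motif unperturbed (baseline) and once per canonical
#' perturbation, each applied to a single mid-chain neuron of the target
#' class (or, for X with population-level intrinsic properties, to the
#' whole X population when `population_x = TRUE`). Reports whether the RA
#' sequence completes and where it breaks.
#'
#' @param config Network configuration (a reduced circuit count keeps the
#'   battery fast).
#' @param network_seed Construction seed.
#' @param fold_up Fold-change used for the RA `g_A`/`g_SK` up-regulations.
#' @param population_x Apply X-class perturbations to the whole population
#'   (mirrors the population-level treatment of X intrinsic properties).
#' @param solver Solver settings.
#' @return data.frame: label, sequence_complete, break_point.
#' @export
perturbation_battery <- function(config = network_config(), network_seed = 1L,
                                 fold_up = 20, population_x = TRUE,
                                 solver = solver_config()) {
  net0 <- wire_network(config, network_seed)
  perts <- .CANONICAL_PERTURBATIONS(fold_up)
  rows <- lapply(perts, function(p) {
    net <- net0
    if (!is.na(p$class)) {
      ids <- if (p$class == "X" && population_x) "population" else {
        cand <- net$neurons$id[net$neurons$class == p$class]
        cand[ceiling(length(cand) / 2)]
      }
      net <- apply_perturbation(net, p$class, ids, p$parameter, p$mode,
                                p$value)
    }
    run <- run_motif(net = net, solver = solver, record_traces = FALSE)
    rep <- sequence_metrics(run$result, net)
    data.frame(label = p$label, sequence_complete = rep$sequence_complete,
               break_point = rep$break_point,
               desired_ok = .desired_activity_ok(rep))
  })
  do.call(rbind, rows)
}

#' Population-level variability of X-projecting intrinsic conductances
#'
#' Draws, for each simulation, one random `(g_CaT, g_SK, g_H)` triple
#' (uniform over the given ranges), sets it across the whole X population,
#' runs the motif, and classifies the outcome with the desired-activity
#' validator. A run counts as disrupted if the RA sequence breaks or any
#' class leaves its realistic firing bounds.
#'
#' @param n_sims Number of simulations.
#' @param ranges Named list of `c(lo, hi)` for `g_CaT`, `g_SK`, `g_H`.
#' @param config,network_seed Network settings.
#' @param seed Seed for the conductance draws.
#' @param solver Solver settings.
#' @return List: `disrupted_fraction`, binomial `conf_int` (95%), and the
#'   per-run table.
#' @export
population_variability_experiment <- function(n_sims = 100,
                                              ranges = x_conductance_ranges(),
                                              config = network_config(),
                                              network_seed = 1L, seed = 1L,
                                              solver = solver_config()) {
  net0 <- wire_network(config, network_seed)
  draws <- .with_seed(seed, data.frame(
    g_CaT = stats::runif(n_sims, ranges$g_CaT[1], ranges$g_CaT[2]),
    g_SK = stats::runif(n_sims, ranges$g_SK[1], ranges$g_SK[2]),
    g_H = stats::runif(n_sims, ranges$g_H[1], ranges$g_H[2])))
  disrupted <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    net <- net0
    for (p in names(draws)) {
      net <- apply_perturbation(net, "X", "population", p, "set", draws[i, p])
    }
    run <- run_motif(net = net, solver = solver, record_traces = FALSE)
    rep <- sequence_metrics(run$result, net)
    disrupted[i] <- !.desired_activity_ok(rep)
  }
  k <- sum(disrupted)
  ci <- stats::binom.test(k, n_sims)$conf.int
  list(disrupted_fraction = k / n_sims, conf_int = as.numeric(ci),
       runs = cbind(draws, disrupted = disrupted))
}

#' Default variability ranges for the X-projecting key conductances
#'
#' The admissible ranges over which the three principal X-projecting
#' conductances may vary while single-cell behavior stays realistic;
#' used by [population_variability_experiment()].
#'
#' @return Named list of `c(lo, hi)` (nS).
#' @export
x_conductance_ranges <- function() {
  d <- .default_conductances("X")
  list(g_CaT = d$g_CaT * c(0.4, 1.8),
       g_SK = d$g_SK * c(0.3, 2.0),
       g_H = d$g_H * c(0.4, 2.2))
}

#' Admissible range search for one conductance
#'
#' Expands a tested interval around the default value of a (ionic or
#' synaptic) conductance, multiplicatively and symmetrically, until the
#' desired-activity validator fails on each side; returns the widest tested
#' interval over which all tested points pass, with the tested grid logged.
#'
#' @param parameter For `level = "ionic"`: conductance name with `class`
#'   (e.g. `"g_SK"`); for `level = "synaptic"`: a pair key (e.g.
#'   `"INT->RA"`), scaling all edges of that pair.
#' @param class Target class for ionic parameters.
#' @param level `"ionic"` or `"synaptic"`.
#' @param factors Increasing multiplicative fold-changes (> 1) probed on
#'   each side of the default.
#' @param config,network_seed,solver As elsewhere.
#' @return List: `lo`, `hi` (admissible bounds as fold-changes), `grid`
#'   (tested fold-changes with pass/fail).
#' @export
conductance_range_search <- function(parameter, class = NULL,
                                     level = c("ionic", "synaptic"),
                                     factors = c(1.25, 1.5, 2, 3, 5),
                                     config = network_config(),
                                     network_seed = 1L,
                                     solver = solver_config()) {
  level <- match.arg(level)
  net0 <- wire_network(config, network_seed)
  test_at <- function(fold) {
    net <- net0
    if (level == "ionic") {
      net <- apply_perturbation(net, class, "population", parameter,
                                "scale", fold)
    } else {
      sel <- .pair_key(net) == parameter
      if (!any(sel)) stop("no synapses of pair ", parameter)
      net$synapses$g[sel] <- net$synapses$g[sel] * fold
    }
    run <- run_motif(net = net, solver = solver, record_traces = FALSE)
    rep <- sequence_metrics(run$result, net)
    rep$sequence_complete && rep$all_ra_ok
  }
  if (!test_at(1)) stop("baseline network fails the validator; ",
                        "range search is undefined")
  grid <- data.frame(fold = 1, pass = TRUE)
  lo <- hi <- 1
  for (f in factors) {
    ok <- test_at(f)
    grid <- rbind(grid, data.frame(fold = f, pass = ok))
    if (ok) hi <- f else break
  }
  for (f in 1 / factors) {
    ok <- test_at(f)
    grid <- rbind(grid, data.frame(fold = f, pass = ok))
    if (ok) lo <- f else break
  }
  list(lo = lo, hi = hi, grid = grid[order(grid$fold), ])
}

.pair_key <- function(net) {
  cls <- stats::setNames(net$neurons$class, net$neurons$id)
  paste0(cls[as.character(net$synapses$pre)], "->",
         cls[as.character(net$synapses$post)])
}

#' Noise-tolerance scan
#'
#' Runs the motif at each noise amplitude in `sigma_grid` (percent of the
#' mean synaptic conductance), with `n_seeds` independent noise seeds each,
#' and reports the largest amplitude at which every seed preserved the
#' complete RA sequence.
#'
#' @param sigma_grid Noise amplitudes (percent).
#' @param n_seeds Noise seeds per amplitude.
#' @param config,network_seed,solver As elsewhere.
#' @return List: `largest_passing_sigma`, per-(sigma, seed) table.
#' @export
noise_tolerance_scan <- function(sigma_grid = c(0, 1, 2, 3, 4, 5),
                                 n_seeds = 3, config = network_config(),
                                 network_seed = 1L,
                                 solver = solver_config()) {
  net <- wire_network(config, network_seed)
  rows <- list()
  for (sg in sigma_grid) {
    for (sd in seq_len(n_seeds)) {
      run <- run_motif(net = net, noise = noise_config(sg, seed = sd),
                       solver = solver, record_traces = FALSE)
      rep <- sequence_metrics(run$result, net)
      rows[[length(rows) + 1]] <- data.frame(
        sigma_pct = sg, noise_seed = sd,
        sequence_complete = rep$sequence_complete)
    }
  }
  tab <- do.call(rbind, rows)
  by_sigma <- tapply(tab$sequence_complete, tab$sigma_pct, all)
  passing <- as.numeric(names(by_sigma))[by_sigma]
  list(largest_passing_sigma = if (length(passing)) max(passing) else NA_real_,
       table = tab)
}
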