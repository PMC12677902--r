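## Per-class neuron parameter sets and the membrane right-hand side.
##
## Class channel sets:
##   RA : L, K, Na, CaL, A, SK            (6 state variables)
##   X  : L, K, Na, CaL, CaT, SK, H       (8 state variables)
##   INT: L, K, Na, CaL, CaT, H           (7 state variables)
## State ordering (must match the compiled integrator):
##   RA : V, h, n, e, z, Ca
##   X  : V, h, n, mT, hT, z, r, Ca
##   INT: V, h, n, mT, hT, r, Ca

.CLASSES <- c("RA", "X", "INT")

.state_names <- function(class) {
  switch(class,
         RA  = c("V", "h", "n", "e", "z", "Ca"),
         X   = c("V", "h", "n", "mT", "hT", "z", "r", "Ca"),
         INT = c("V", "h", "n", "mT", "hT", "r", "Ca"),
         stop("unknown neuron class '", class, "'"))
}

## Fixed per-class parameters. Only the four key conductances
## (g_SK, g_H, g_A, g_CaT) and the synaptic conductances are meant to vary;
## g_Na, g_K, g_CaL and the passive parameters are fixed to values that
## reproduce the class spike morphologies (RA/X spikes riding a plateau,
## INT spikes undershooting rest, X/INT sag and rebound).
.default_conductances <- function(class) {
  switch(class,
         RA = list(C_m = 40, g_L = 2.5, E_L = -80, g_Na = 450, E_Na = 55,
                   g_K = 150, E_K = -90, g_CaL = 20, E_Ca = 120, g_CaT = 0,
                   g_SK = 100, g_A = 5, g_H = 0, E_H = -40),
         X  = list(C_m = 100, g_L = 4,  E_L = -88, g_Na = 450, E_Na = 55,
                   g_K = 200, E_K = -90, g_CaL = 5, E_Ca = 120, g_CaT = 70,
                   g_SK = 7,  g_A = 0, g_H = 6, E_H = -40),
         INT = list(C_m = 75, g_L = 4,  E_L = -58, g_Na = 700, E_Na = 55,
                    g_K = 800, E_K = -90, g_CaL = 2, E_Ca = 120, g_CaT = 3,
                    g_SK = 0,  g_A = 0, g_H = 2, E_H = -20))
}

.default_calcium <- function(class) {
  ## dCa/dt = -alpha*(I_CaL + I_CaT) - (Ca - ca0)/tau ; baseline ca0 keeps
  ## the SK gate nearly closed at rest (z_inf(ca0) ~ 0.015)
  list(alpha = if (class == "RA") 4e-4 else 1e-4,
       tau = if (class == "RA") 40 else 50, ca0 = 0.05)
}

#' Neuron parameter set for one HVC class
#'
#' Assembles the full single-compartment parameter set for an `"RA"`, `"X"`
#' or `"INT"` model neuron: membrane capacitance, the class-specific channel
#' set with default maximal conductances and gating kinetics, and the
#' intracellular calcium balance. Any default can be overridden by name
#' (e.g. `g_SK = 0`, `C_m = 80`).
#'
#' @param class `"RA"`, `"X"` or `"INT"`.
#' @param ... Named overrides of conductances (`g_Na`, `g_K`, `g_CaL`,
#'   `g_CaT`, `g_SK`, `g_A`, `g_H`, `g_L`), reversal potentials (`E_*`),
#'   `C_m`, or calcium parameters (`ca_alpha`, `ca_tau`, `ca0`).
#' @return An object of class `hvc_neuron`.
#' @export
neuron_params <- function(class = c("RA", "X", "INT"), ...) {
  class <- match.arg(class)
  p <- .default_conductances(class)
  ca <- .default_calcium(class)
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% names(p)) p[[nm]] <- ov[[nm]]
    else if (nm == "ca_alpha") ca$alpha <- ov[[nm]]
    else if (nm == "ca_tau") ca$tau <- ov[[nm]]
    else if (nm == "ca0") ca$ca0 <- ov[[nm]]
    else stop("unknown parameter '", nm, "' for class ", class)
  }
  bad <- grep("^g_", names(p), value = TRUE)
  bad <- bad[vapply(p[bad], function(x) x < 0, logical(1))]
  if (length(bad)) stop("negative conductance(s): ", paste(bad, collapse = ", "))
  kin <- .default_kinetics(class)
  ch <- list(L = channel_params("L", p$g_L, p$E_L))
  ch$K <- channel_params("K", p$g_K, p$E_K, list(n = kin$n))
  ch$Na <- channel_params("Na", p$g_Na, p$E_Na, list(m = kin$m, h = kin$h))
  ch$CaL <- channel_params("CaL", p$g_CaL, p$E_Ca, list(s = kin$s))
  if (class %in% c("X", "INT")) {
    ch$CaT <- channel_params("CaT", p$g_CaT, p$E_Ca, list(mT = kin$mT, hT = kin$hT))
    ch$H <- channel_params("H", p$g_H, p$E_H, list(r = kin$r))
  }
  if (class %in% c("RA", "X")) {
    ch$SK <- channel_params("SK", p$g_SK, p$E_K, list(z = kin$z))
  }
  if (class == "RA") {
    ch$A <- channel_params("A", p$g_A, p$E_K, list(a = kin$a, e = kin$e))
  }
  structure(list(neuron_class = class, C_m = p$C_m, pars = p,
                 calcium = ca, kinetics = kin, channels = ch),
            class = "hvc_neuron")
}

#' @export
print.hvc_neuron <- function(x, ...) {
  cat("HVC_", x$neuron_class, " model neuron (", length(.state_names(x$neuron_class)),
      " state variables)\n", sep = "")
  cat("  C_m =", x$C_m, "pF; channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  g <- unlist(x$pars[grep("^g_", names(x$pars))])
  cat("  ", paste(names(g), g, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

## parameter row for the compiled integrator (order fixed by src/sim.cpp)
.par_row <- function(np) {
  p <- np$pars
  ca <- np$calcium
  c(p$C_m, p$g_L, p$E_L, p$g_Na, p$E_Na, p$g_K, p$E_K, p$g_CaL, p$E_Ca,
    p$g_CaT, p$g_SK, p$g_A, p$g_H, p$E_H, ca$alpha, ca$tau, ca$ca0)
}

.class_code <- function(class) match(class, .CLASSES) - 1L

## named state -> flat vector and back
.state_vec <- function(state, class) {
  nm <- .state_names(class)
  stopifnot(all(nm %in% names(state)))
  as.numeric(state[nm])
}

.state_list <- function(vec, class) {
  nm <- .state_names(class)
  stopifnot(length(vec) == length(nm))
  as.list(stats::setNames(as.numeric(vec), nm))
}

## all gates at steady state for voltage V, Ca at baseline
.steady_state_at <- function(np, V) {
  class <- np$neuron_class
  kin <- np$kinetics
  ca0 <- np$calcium$ca0
  s <- list(V = V,
            h = .boltz(V, kin$h$theta, kin$h$sigma),
            n = .boltz(V, kin$n$theta, kin$n$sigma),
            Ca = ca0)
  if (class == "RA") {
    s$e <- .boltz(V, kin$e$theta, kin$e$sigma)
    s$z <- ca0^2 / (ca0^2 + kin$z$ks^2)
  }
  if (class %in% c("X", "INT")) {
    s$mT <- .boltz(V, kin$mT$theta, kin$mT$sigma)
    s$hT <- .boltz(V, kin$hT$theta, kin$hT$sigma)
    s$r <- .boltz(V, kin$r$theta, kin$r$sigma)
  }
  if (class == "X") s$z <- ca0^2 / (ca0^2 + kin$z$ks^2)
  s[c("V", setdiff(.state_names(class), "V"))]
}

#' Membrane right-hand side of one model neuron
#'
#' Reference (pure R) implementation of the single-neuron ODE system:
#' `dV/dt = (-sum(I_ionic) + I_stim + I_noise - I_syn)/C_m`, first-order gate
#' relaxation, and the intracellular calcium balance. The compiled network
#' integrator implements the same equations; this function is the slow,
#' transparent form used for verification and for the adaptive reference
#' integration.
#'
#' @param params An `hvc_neuron` object.
#' @param state Named list (or vector) with the class state variables.
#' @param I_syn,I_stim,I_noise Currents in pA (synaptic currents are
#'   subtracted, stimulus and noise added).
#' @return Named numeric vector of time derivatives, in state order.
#' @export
membrane_rhs <- function(params, state, I_syn = 0, I_stim = 0, I_noise = 0) {
  class <- params$neuron_class
  nm <- .state_names(class)
  state <- as.list(state)
  stopifnot(all(nm %in% names(state)))
  V <- state$V
  kin <- params$kinetics
  st <- list(V = V, Ca = state$Ca, gates = state[setdiff(nm, c("V", "Ca"))])
  Iion <- 0
  ICa <- 0
  for (ch in params$channels) {
    Ic <- ionic_current(ch, st)
    Iion <- Iion + Ic
    if (ch$channel_id %in% c("CaL", "CaT")) ICa <- ICa + Ic
  }
  d <- stats::setNames(numeric(length(nm)), nm)
  d["V"] <- (-Iion + I_stim + I_noise - I_syn) / params$C_m
  relax <- function(gate, x, drive = V) {
    xi <- if (isTRUE(gate$calcium_gated)) {
      drive^2 / (drive^2 + gate$ks^2)
    } else .boltz(drive, gate$theta, gate$sigma)
    ta <- if (isTRUE(gate$calcium_gated)) gate$tau
          else .tau_v(drive, gate$tau0, gate$tau1, gate$theta_t, gate$sigma_t)
    (xi - x) / ta
  }
  d["h"] <- relax(kin$h, state$h)
  d["n"] <- relax(kin$n, state$n)
  if (class == "RA") {
    d["e"] <- relax(kin$e, state$e)
    d["z"] <- relax(kin$z, state$z, drive = state$Ca)
  }
  if (class %in% c("X", "INT")) {
    d["mT"] <- relax(kin$mT, state$mT)
    d["hT"] <- relax(kin$hT, state$hT)
    d["r"] <- relax(kin$r, state$r)
  }
  if (class == "X") d["z"] <- relax(kin$z, state$z, drive = state$Ca)
  ca <- params$calcium
  d["Ca"] <- -ca$alpha * ICa - (state$Ca - ca$ca0) / ca$tau
  d
}

#' Resting state of a model neuron
#'
#' Finds the stable resting fixed point by relaxing the unstimulated neuron
#' from -70 mV (gates at their steady states) for `horizon` ms of model time
#' with the fixed-step integrator, then verifying that the state-derivative
#' norm is below `tol`. The default horizon leaves ample time for the slow
#' H-current and the weakly damped T/H interplay of the X class to settle.
#' A neuron that keeps firing in the second half of the horizon or fails
#' the tolerance raises an error that carries the final trajectory.
#'
#' @param params An `hvc_neuron` object.
#' @param horizon Relaxation horizon (ms); the default leaves ample time for
#'   the slow H-current to settle.
#' @param tol Derivative-norm tolerance defining "at rest".
#' @return Named list of resting state variables (class `hvc_state`).
#' @export
resting_state <- function(params, horizon = 4000, tol = 1e-8) {
  s0 <- .steady_state_at(params, -70)
  res <- simulate_neuron(params, state = s0, duration = horizon, dt = 0.02,
                         record_stride = 50L)
  fin <- .state_list(res$state, params$neuron_class)
  d <- membrane_rhs(params, fin)
  late_spikes <- sum(res$spikes[[1]] > horizon / 2)
  if (sqrt(sum(d^2)) >= tol || late_spikes > 0) {
    err <- simpleError(paste0("HVC_", params$neuron_class,
                              " neuron did not settle to rest (|dstate/dt| = ",
                              format(sqrt(sum(d^2))), ")"))
    err$trajectory <- res
    stop(err)
  }
  structure(fin, class = "hvc_state")
}
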