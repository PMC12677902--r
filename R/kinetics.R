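## Channel gating kinetics for the three HVC neuron classes.
##
## Every voltage-gated gate x has a Boltzmann steady state
##   x_inf(V) = 1 / (1 + exp((V - theta)/sigma))
## (sigma < 0: activation, increasing in V; sigma > 0: inactivation) and,
## when not instantaneous, a first-order relaxation dx/dt = (x_inf - x)/tau_x
## with tau_x(V) = tau0 + tau1 / cosh((V - theta_t)/sigma_t).
## The SK gate is calcium-gated: z_inf(Ca) = Ca^2/(Ca^2 + k_s^2), constant tau.
##
## Units throughout the package: mV, ms, nS, pA, pF, uM.

.boltz <- function(V, theta, sigma) 1 / (1 + exp((V - theta) / sigma))
.tau_v <- function(V, tau0, tau1, theta_t, sigma_t) {
  tau0 + tau1 / cosh((V - theta_t) / sigma_t)
}

.gate <- function(exponent, theta, sigma, tau0 = NA, tau1 = NA,
                  theta_t = NA, sigma_t = NA, instantaneous = is.na(tau0)) {
  structure(list(exponent = exponent, theta = theta, sigma = sigma,
                 tau0 = tau0, tau1 = tau1, theta_t = theta_t,
                 sigma_t = sigma_t, instantaneous = instantaneous),
            class = "hvc_gate")
}

.ca_gate <- function(exponent, ks, tau) {
  structure(list(exponent = exponent, ks = ks, tau = tau,
                 instantaneous = FALSE, calcium_gated = TRUE),
            class = "hvc_gate")
}

#' Channel definition
#'
#' Builds a single ionic-channel description: maximal conductance, reversal
#' potential, and the gate specifications (steady-state and time-constant
#' parameters) used both by the R reference right-hand side and by the
#' compiled network integrator.
#'
#' @param channel_id One of `"Na"`, `"K"`, `"CaL"`, `"CaT"`, `"SK"`, `"A"`,
#'   `"H"`, `"L"`.
#' @param g_max Maximal conductance (nS), must be non-negative.
#' @param E_rev Reversal potential (mV).
#' @param gates Named list of gate specs (see [gating_steady_state()]).
#' @return An object of class `hvc_channel`.
#' @export
channel_params <- function(channel_id, g_max, E_rev, gates = list()) {
  stopifnot(channel_id %in% c("Na", "K", "CaL", "CaT", "SK", "A", "H", "L"))
  if (!is.numeric(g_max) || g_max < 0) {
    stop("g_max for channel ", channel_id, " must be >= 0")
  }
  for (g in gates) {
    stopifnot(inherits(g, "hvc_gate"))
    if (g$exponent <= 0 || g$exponent != round(g$exponent)) {
      stop("gate exponents must be positive integers (channel ", channel_id, ")")
    }
  }
  structure(list(channel_id = channel_id, g_max = g_max, E_rev = E_rev,
                 gates = gates), class = "hvc_channel")
}

#' Steady-state (in)activation of a channel gate
#'
#' Evaluates the steady-state value of a named gate of a channel at membrane
#' potential `V` (or, for the calcium-gated SK gate, at calcium concentration
#' `V` in uM). Values are guaranteed to lie in \[0, 1\] for any finite input.
#'
#' @param channel An `hvc_channel` object.
#' @param gate_id Name of the gate (e.g. `"m"`, `"h"`, `"n"`).
#' @param V Membrane potential (mV), or Ca concentration (uM) for SK's gate.
#' @return Steady-state gate value in \[0, 1\].
#' @export
gating_steady_state <- function(channel, gate_id, V) {
  g <- channel$gates[[gate_id]]
  if (is.null(g)) {
    stop("channel ", channel$channel_id, " has no gate named '", gate_id, "'")
  }
  if (isTRUE(g$calcium_gated)) {
    V^2 / (V^2 + g$ks^2)
  } else {
    .boltz(V, g$theta, g$sigma)
  }
}

#' Voltage-dependent time constant of a channel gate
#'
#' @inheritParams gating_steady_state
#' @return Time constant (ms), strictly positive for finite `V`.
#' @export
gating_time_constant <- function(channel, gate_id, V) {
  g <- channel$gates[[gate_id]]
  if (is.null(g)) {
    stop("channel ", channel$channel_id, " has no gate named '", gate_id, "'")
  }
  if (isTRUE(g$instantaneous)) {
    stop("gate '", gate_id, "' of channel ", channel$channel_id,
         " is instantaneous and has no time constant")
  }
  if (isTRUE(g$calcium_gated)) rep(g$tau, length(V))
  else .tau_v(V, g$tau0, g$tau1, g$theta_t, g$sigma_t)
}

#' Ionic current through one channel
#'
#' Ohmic current `g_max * prod(gates^exponents) * (V - E_rev)` (pA; outward
#' positive, i.e. currents are subtracted in the membrane equation). Gate
#' values are taken from `state$gates`; the SK channel's gate is its
#' calcium-activation variable.
#'
#' @param channel An `hvc_channel`.
#' @param state A list with elements `V` (mV) and `gates` (named list of gate
#'   values); instantaneous gates may be omitted and are evaluated at `V`
#'   (the SK gate, if omitted, is evaluated at `state$Ca`).
#' @return Current in pA.
#' @export
ionic_current <- function(channel, state) {
  gprod <- 1
  for (gid in names(channel$gates)) {
    g <- channel$gates[[gid]]
    val <- state$gates[[gid]]
    if (is.null(val)) {
      val <- if (isTRUE(g$calcium_gated)) {
        gating_steady_state(channel, gid, state$Ca)
      } else if (isTRUE(g$instantaneous)) {
        gating_steady_state(channel, gid, state$V)
      } else {
        stop("state is missing dynamic gate '", gid, "' of channel ",
             channel$channel_id)
      }
    }
    gprod <- gprod * val^g$exponent
  }
  channel$g_max * gprod * (state$V - channel$E_rev)
}

## ---- default kinetics tables -----------------------------------------------
## One list per class; CaT kinetics are identical in X and INT.

.default_kinetics <- function(class) {
  ## shared spike-generating kinetics; the interneuron delayed rectifier is
  ## faster, giving the narrow undershooting spikes of that class
  k <- list(
    m  = .gate(3, -38, -4),
    h  = .gate(1, -45, 4, tau0 = 0.1, tau1 = 0.8, theta_t = -45, sigma_t = 12),
    n  = .gate(4, -40, -4, tau0 = 0.1, tau1 = 0.5, theta_t = -40, sigma_t = 15),
    s  = .gate(2, -10, -5),
    mT = .gate(2, -57, -6.2, tau0 = 0.6, tau1 = 4, theta_t = -57, sigma_t = 12),
    hT = .gate(1, -75, 5, tau0 = 10, tau1 = 25, theta_t = -75, sigma_t = 10),
    a  = .gate(1, -45, -6),
    e  = .gate(1, -75, 6, tau0 = 15, tau1 = 0, theta_t = -75, sigma_t = 10),
    r  = .gate(1, -80, 7, tau0 = 30, tau1 = 70, theta_t = -80, sigma_t = 12),
    z  = .ca_gate(1, ks = 0.4, tau = 5)
  )
  if (class == "RA") {
    ## faster-recovering delayed rectifier (short intra-burst ISIs) and a
    ## slower, higher-affinity SK gate that terminates the burst after
    ## roughly 8 ms of calcium accumulation
    k$n <- .gate(4, -40, -4, tau0 = 0.1, tau1 = 0.7, theta_t = -40, sigma_t = 15)
    k$z <- .ca_gate(4, ks = 0.3, tau = 10)
    ## low-threshold, steep L-type activation: a regenerative plateau that
    ## sustains the burst once ignited, until SK terminates it
    k$s <- .gate(2, -40, -3)
  }
  if (class == "X") {
    ## slightly depolarized Na inactivation: tonic adapted trains without
    ## the accommodation stall seen with the shared midpoint
    k$h <- .gate(1, -43, 4, tau0 = 0.1, tau1 = 0.8, theta_t = -43, sigma_t = 12)
  }
  if (class == "INT") {
    k$n <- .gate(4, -40, -4, tau0 = 0.15, tau1 = 0.6, theta_t = -40, sigma_t = 15)
    k$h <- .gate(1, -45, 4, tau0 = 0.1, tau1 = 0.4, theta_t = -45, sigma_t = 12)
    ## interneurons rest more depolarized than X; their T and H gates sit
    ## higher so these currents remain functionally engaged near rest (an
    ## up-regulation of either drives the cell into dense firing)
    k$hT <- .gate(1, -65, 5, tau0 = 10, tau1 = 25, theta_t = -65, sigma_t = 10)
    k$r <- .gate(1, -58, 7, tau0 = 30, tau1 = 70, theta_t = -58, sigma_t = 12)
  }
  k
}

## flatten a class kinetics list into the row layout the C++ code expects
.kin_row <- function(k) {
  g2 <- function(g) c(g$theta, g$sigma)
  g6 <- function(g) c(g$theta, g$sigma, g$tau0, g$tau1, g$theta_t, g$sigma_t)
  c(g2(k$m), g6(k$h), g6(k$n), g2(k$s), g6(k$mT), g6(k$hT),
    g2(k$a), g6(k$e), g6(k$r), k$z$ks, k$z$tau)
}

## 3 x 44 kinetics matrix (rows: RA, X, INT) from per-class channel specs
.kin_matrix <- function(kin_list) {
  rbind(.kin_row(kin_list$RA), .kin_row(kin_list$X), .kin_row(kin_list$INT))
}
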