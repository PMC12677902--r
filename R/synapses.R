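## AMPA / GABA-A synapse dynamics and the stochastic background current.
##
## Each synapse carries a gating variable s in [0,1] with two-state
## transmitter-driven kinetics: s rises at rate alpha while the presynaptic
## membrane is above the transmitter-release threshold (sigmoidal release
## function T(V_pre)) and decays at rate beta otherwise. The synaptic
## current onto a postsynaptic neuron is sum(g * s * (V_post - E_rev)),
## subtracted in the membrane equation.

.ALLOWED_PAIRS <- data.frame(
  pre  = c("RA", "RA", "X", "INT", "INT"),
  post = c("RA", "INT", "INT", "RA", "X"),
  kind = c("AMPA", "AMPA", "AMPA", "GABA_A", "GABA_A"),
  stringsAsFactors = FALSE
)

#' Default synaptic kinetics
#'
#' Release threshold and sigmoid slope shared by both receptor types, rise
#' and decay rates per receptor, and reversal potentials (AMPA ~0 mV,
#' depolarizing at rest; GABA-A below rest, hyperpolarizing). Decay time
#' constants: AMPA 1/beta = 2 ms, GABA-A 8 ms. Calibrated so the
#' paired-recording motifs reproduce the experimental PSP polarities and
#' shapes.
#'
#' @return Named list of kinetic constants.
#' @export
synapse_kinetics <- function() {
  list(theta_rel = -20, slope_rel = 2,
       alpha_AMPA = 4.0, beta_AMPA = 0.18,
       alpha_GABA = 1.0, beta_GABA = 0.125,
       E_AMPA = 0, E_GABA = -88)
}

## flat vector in the order the compiled integrator expects
.syn_kin_vec <- function(k = synapse_kinetics()) {
  c(k$theta_rel, k$slope_rel, k$alpha_AMPA, k$beta_AMPA,
    k$alpha_GABA, k$beta_GABA, k$E_AMPA, k$E_GABA)
}

#' Default per-pair synaptic conductance ranges (nS)
#'
#' Each directed class pair draws its per-edge maximal conductance uniformly
#' from these ranges when the network is wired. The INT->RA range is kept
#' deliberately low: inhibition onto RA-projecting neurons is the most
#' sensitive coupling in the network, and large values suppress the RA
#' bursts that carry the sequence.
#'
#' @return Named list of `c(lo, hi)` ranges, keyed `"PRE->POST"`.
#' @export
synaptic_ranges <- function() {
  list("RA->RA"  = c(23, 24.5),
       "RA->INT" = c(12, 18),
       "X->INT"  = c(2, 5),
       "INT->RA" = c(2, 5),
       "INT->X"  = c(28, 45))
}

#' Construct a synapse
#'
#' @param pre,post Neuron ids.
#' @param kind `"AMPA"` or `"GABA_A"`.
#' @param g Maximal conductance (nS).
#' @param s Initial gating value in \[0,1\].
#' @param kinetics Kinetics list from [synapse_kinetics()].
#' @return Object of class `hvc_synapse`.
#' @export
synapse <- function(pre, post, kind = c("AMPA", "GABA_A"), g, s = 0,
                    kinetics = synapse_kinetics()) {
  kind <- match.arg(kind)
  stopifnot(g >= 0, s >= 0, s <= 1, pre != post)
  E <- if (kind == "AMPA") kinetics$E_AMPA else kinetics$E_GABA
  structure(list(pre = pre, post = post, kind = kind, g = g, s = s,
                 E_rev = E, kinetics = kinetics), class = "hvc_synapse")
}

#' Total synaptic current onto a neuron
#'
#' @param synapses List of `hvc_synapse` objects sharing the same
#'   postsynaptic neuron.
#' @param V_post Postsynaptic membrane potential (mV).
#' @return Current in pA (`sum(g * s * (V_post - E_rev))`); 0 for an empty
#'   set.
#' @export
synaptic_current <- function(synapses, V_post) {
  if (length(synapses) == 0) return(0)
  post <- unique(vapply(synapses, function(x) x$post, numeric(1)))
  if (length(post) > 1) stop("synapses target different postsynaptic neurons")
  sum(vapply(synapses, function(x) x$g * x$s * (V_post - x$E_rev), numeric(1)))
}

#' Synaptic gate derivative
#'
#' @param syn An `hvc_synapse`.
#' @param V_pre Presynaptic membrane potential (mV).
#' @return ds/dt (1/ms).
#' @export
synapse_gate_rhs <- function(syn, V_pre) {
  k <- syn$kinetics
  Tr <- 1 / (1 + exp(-(V_pre - k$theta_rel) / k$slope_rel))
  a <- if (syn$kind == "AMPA") k$alpha_AMPA else k$alpha_GABA
  b <- if (syn$kind == "AMPA") k$beta_AMPA else k$beta_GABA
  a * Tr * (1 - syn$s) - b * syn$s
}

#' Background-noise configuration
#'
#' The stochastic background current is `I_noise(t) = sigma * xi(t)` with
#' `xi` Gaussian white noise (zero mean, unit variance). `sigma` is given in
#' the configuration as a percentage of the network-wide mean synaptic
#' conductance and converted to a current amplitude at a reference driving
#' force of 60 mV: `sigma_pA = (sigma_pct/100) * mean(g_syn) * 60`. Samples
#' are scaled by 1/sqrt(dt) in the integrator (Euler-Maruyama), so the
#' injected process has dt-independent statistics, and are frozen per
#' (seed, neuron, step).
#'
#' @param sigma_pct Noise amplitude, percent of mean synaptic conductance.
#' @param seed Integer RNG seed for the noise stream.
#' @return Object of class `hvc_noise`.
#' @export
noise_config <- function(sigma_pct = 0, seed = 1L) {
  stopifnot(sigma_pct >= 0)
  structure(list(sigma_pct = sigma_pct, seed = as.integer(seed)),
            class = "hvc_noise")
}

## percent-of-mean-conductance -> pA amplitude for a given network
.noise_sigma_pA <- function(noise, net) {
  if (noise$sigma_pct == 0) return(0)
  gbar <- mean(net$synapses$g)
  noise$sigma_pct / 100 * gbar * 60
}

#' One sample of the background-noise current
#'
#' Draws `sigma * xi / sqrt(dt)` using R's RNG; provided for direct
#' inspection of the noise law (the network integrator uses an internal
#' counter-based generator keyed by (seed, step, neuron) for order-free
#' reproducibility).
#'
#' @param cfg An `hvc_noise` config.
#' @param dt Step size (ms).
#' @param sigma_pA Current amplitude (pA); if missing, `cfg$sigma_pct` is
#'   interpreted directly as pA.
#' @param n Number of samples.
#' @return Current sample(s) in pA.
#' @export
noise_current <- function(cfg, dt, sigma_pA = cfg$sigma_pct, n = 1) {
  stopifnot(dt > 0)
  if (sigma_pA == 0) return(rep(0, n))
  sigma_pA * stats::rnorm(n) / sqrt(dt)
}
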