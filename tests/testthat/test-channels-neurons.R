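test_that("gating steady states saturate, hit 0.5 at half-voltage, stay in [0,1]", {
  x <- neuron_params("X")
  na <- x$channels$Na
  expect_lt(gating_steady_state(na, "m", -200), 0.01)
  expect_equal(gating_steady_state(na, "m", na$gates$m$theta), 0.5)
  expect_equal(gating_steady_state(na, "h", na$gates$h$theta), 0.5)
  cat_ <- x$channels$CaT
  expect_equal(gating_steady_state(cat_, "hT", cat_$gates$hT$theta), 0.5)
  ## frozen value: independent evaluation of 1/(1 + exp((-50 + 75)/5))
  expect_equal(gating_steady_state(cat_, "hT", -50), 0.0066928509, tolerance = 1e-8)
  ## monotonicity: activation increasing, inactivation decreasing
  vv <- seq(-120, 40, by = 5)
  m <- gating_steady_state(na, "m", vv)
  h <- gating_steady_state(na, "h", vv)
  expect_true(all(diff(m) > 0))
  expect_true(all(diff(h) < 0))
  expect_true(all(m >= 0 & m <= 1 & h >= 0 & h <= 1))
  ## time constants strictly positive
  for (g in c("h")) expect_true(all(gating_time_constant(na, g, vv) > 0))
  expect_error(gating_steady_state(na, "zz", -50), "no gate named")
})

test_that("ionic currents obey zero-conductance, reversal and hand arithmetic", {
  x <- neuron_params("X")
  k0 <- channel_params("K", 0, -90, list(n = x$channels$K$gates$n))
  st <- list(V = -40, Ca = 0.1, gates = list(n = 0.7))
  expect_equal(ionic_current(k0, st), 0)
  k <- x$channels$K
  stE <- list(V = k$E_rev, Ca = 0.1, gates = list(n = 0.7))
  expect_equal(ionic_current(k, stE), 0)
  ## I_K = g * n^4 * (V - E_K) with n at its steady state for -40 mV
  ninf <- gating_steady_state(k, "n", -40)
  st2 <- list(V = -40, Ca = 0.1, gates = list(n = ninf))
  expect_equal(ionic_current(k, st2),
               k$g_max * ninf^4 * (-40 - k$E_rev))
})

test_that("membrane_rhs vanishes for current-free and leak-equilibrium states", {
  np0 <- neuron_params("RA", g_L = 0, g_Na = 0, g_K = 0, g_CaL = 0,
                       g_SK = 0, g_A = 0)
  st <- hvcnet:::.steady_state_at(np0, -55)
  d <- membrane_rhs(np0, st)
  expect_equal(unname(d["V"]), 0)
  ## leak-only neuron at E_L: dV/dt = 0 and gates relax toward steady state
  npl <- neuron_params("RA", g_Na = 0, g_K = 0, g_CaL = 0, g_SK = 0, g_A = 0)
  stl <- hvcnet:::.steady_state_at(npl, npl$pars$E_L)
  stl$h <- 0.2  # off-steady gate must relax upward (h_inf(-80) ~ 1)
  dl <- membrane_rhs(npl, stl)
  expect_equal(unname(dl["V"]), 0)
  expect_gt(unname(dl["h"]), 0)
})

test_that("membrane_rhs matches a finite-difference derivative of the reference trajectory", {
  skip_if_not_installed("deSolve")
  np <- neuron_params("RA")
  stim <- stimulus_protocol(1, 0.5, onsets = 5, pulse_width = 30)
  ref <- simulate_reference(np, stim = stim, duration = 18, dt_out = 0.005)
  ## mid-burst sample: central difference of the full state vector
  i <- which.min(abs(ref$time - 15))
  h <- ref$time[i + 1] - ref$time[i - 1]
  fd <- (ref$sol[i + 1, -1] - ref$sol[i - 1, -1]) / h
  st <- hvcnet:::.state_list(as.numeric(ref$sol[i, -1]), "RA")
  d <- membrane_rhs(np, st, I_stim = 500)
  expect_equal(unname(d), unname(fd), tolerance = 1e-3)
})

test_that("state dimension is exactly 6/8/7 for RA/X/INT", {
  dims <- vapply(c("RA", "X", "INT"),
                 function(cl) length(hvcnet:::.state_names(cl)), integer(1))
  expect_equal(unname(dims), c(6L, 8L, 7L))
  ## and the channel sets match the class current lists
  expect_setequal(names(neuron_params("RA")$channels),
                  c("L", "K", "Na", "CaL", "A", "SK"))
  expect_setequal(names(neuron_params("X")$channels),
                  c("L", "K", "Na", "CaL", "CaT", "SK", "H"))
  expect_setequal(names(neuron_params("INT")$channels),
                  c("L", "K", "Na", "CaL", "CaT", "H"))
})

test_that("resting_state finds fixed points and reacts to g_H as expected", {
  npl <- neuron_params("X", g_Na = 0, g_K = 0, g_CaL = 0, g_CaT = 0,
                       g_SK = 0, g_H = 0)
  expect_equal(resting_state(npl)$V, npl$pars$E_L, tolerance = 1e-6)
  st <- resting_state(neuron_params("INT"))
  d <- membrane_rhs(neuron_params("INT"), st)
  expect_lt(sqrt(sum(d^2)), 1e-8)
  ## more H current depolarizes the resting potential. The X cell sits
  ## close to its rebound (oscillatory) bifurcation, so it is probed with
  ## a small increment; the interneuron tolerates a full doubling.
  v1 <- resting_state(neuron_params("X"))$V
  v2 <- resting_state(neuron_params("X", g_H = 1.05 * neuron_params("X")$pars$g_H))$V
  expect_gt(v2, v1)
  w1 <- resting_state(neuron_params("INT"))$V
  w2 <- resting_state(neuron_params("INT", g_H = 2 * neuron_params("INT")$pars$g_H))$V
  expect_gt(w2, w1)
  ## a large H-current increase destabilizes the X resting state entirely
  ## (the runaway regime seen when g_H is strongly up-regulated)
  expect_error(resting_state(neuron_params("X", g_H = 12)), "did not settle")
})

test_that("gate variables stay in [0,1] and Ca stays non-negative along trajectories", {
  skip_if_not_installed("deSolve")
  for (cl in c("RA", "X", "INT")) {
    np <- neuron_params(cl)
    stim <- rbind(stimulus_protocol(1, 0.4, onsets = 20, pulse_width = 40),
                  stimulus_protocol(1, -0.2, onsets = 80, pulse_width = 40))
    ref <- simulate_reference(np, stim = stim, duration = 160, dt_out = 0.1)
    y <- ref$sol[, -1, drop = FALSE]
    nm <- hvcnet:::.state_names(cl)
    gates <- y[, !(nm %in% c("V", "Ca")), drop = FALSE]
    expect_true(all(gates >= -1e-9 & gates <= 1 + 1e-9))
    expect_true(all(y[, nm == "Ca"] >= 0))
  }
})

test_that("class electrophysiological signatures hold under current clamp", {
  clamp <- function(np, amp, width = 400, dur = 600) {
    simulate_neuron(np, stim = stimulus_protocol(1, amp, onsets = 100,
                                                 pulse_width = width),
                    duration = dur)
  }
  ## X and INT: sag (minimum precedes the pre-release level) under
  ## hyperpolarization, rebound depolarization at release
  for (cl in c("X", "INT")) {
    np <- neuron_params(cl)
    rest <- resting_state(np)$V
    s <- clamp(np, -0.2)
    instep <- s$time >= 105 & s$time <= 495
    tmin <- s$time[instep][which.min(s$V[instep, 1])]
    late <- mean(s$V[s$time >= 450 & s$time <= 495, 1])
    expect_lt(tmin, 450)                        # minimum early in the step
    expect_gt(late, min(s$V[instep, 1]) + 1)    # sagging back up by > 1 mV
    post <- s$V[s$time > 500 & s$time < 600, 1]
    expect_gt(max(post), rest + 2)              # rebound depolarization
  }
  ## RA: delayed spike onset under a near-threshold step; delay shrinks
  ## when g_A is reduced
  ra <- neuron_params("RA")
  s1 <- clamp(ra, 0.3, width = 200, dur = 400)
  expect_gt(length(s1$spikes[[1]]), 0)
  delay_full <- s1$spikes[[1]][1] - 100
  expect_gt(delay_full, 2)
  s2 <- clamp(neuron_params("RA", g_A = 1), 0.3, width = 200, dur = 400)
  expect_lt(s2$spikes[[1]][1] - 100, delay_full)
  ## INT spikes undershoot rest; RA spikes ride a depolarized plateau
  int <- neuron_params("INT")
  rest_int <- resting_state(int)$V
  si <- clamp(int, 0.2)
  mid <- si$time > 200 & si$time < 480
  expect_gt(length(si$spikes[[1]]), 10)
  expect_lt(min(si$V[mid, 1]), rest_int)
  rest_ra <- resting_state(ra)$V
  sb <- clamp(ra, 0.5, width = 30, dur = 200)
  spk <- sb$spikes[[1]]
  expect_gte(length(spk), 3)
  inburst <- sb$time >= spk[1] & sb$time <= spk[length(spk)]
  expect_gt(min(sb$V[inburst, 1]), rest_ra + 5)
})

test_that("SK current produces spike-frequency adaptation in X trains", {
  clamp <- function(np) {
    simulate_neuron(np, stim = stimulus_protocol(1, 0.25, onsets = 100,
                                                 pulse_width = 300),
                    duration = 450)
  }
  s <- clamp(neuron_params("X"))
  ## steady train after the initial T-current transient, before any pause
  train <- function(sim) {
    spk <- sim$spikes[[1]]
    spk <- spk[spk > 105 & spk < 390]
    spk <- spk[-(1:2)]                 # drop the initial T-current doublet
    gaps <- which(diff(spk) > 15)
    if (length(gaps)) spk <- spk[seq_len(gaps[1])]
    spk
  }
  spk <- train(s)
  expect_gt(length(spk), 4)
  isis <- diff(spk)
  expect_true(all(diff(isis) > -0.05))   # non-decreasing ISIs
  s0 <- clamp(neuron_params("X", g_SK = 0))
  isis0 <- diff(train(s0))
  ## without SK the late train no longer keeps slowing down
  late0 <- isis0[(length(isis0) - 4):length(isis0)]
  expect_lt(max(late0) - min(late0), 0.2)
  expect_gt(isis[length(isis)] - isis[1], 1)
})
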