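test_that("an unstimulated, noiseless network stays at rest", {
  net <- wire_network(small_config(3L), seed = 4L)
  sim <- simulate(net, solver = solver_config(duration = 500))
  expect_true(all(lengths(sim$spikes) == 0))
  drift <- apply(sim$V, 2, function(v) max(abs(v - v[1])))
  expect_true(all(drift < 1))
})

test_that("simulation is bit-reproducible from (config, seeds)", {
  run1 <- run_motif(config = small_config(), network_seed = 6L,
                    noise = noise_config(2, seed = 5L),
                    solver = solver_config(duration = 150), kick_nA = 0.5,
                    kick_ms = 18)
  run2 <- run_motif(config = small_config(), network_seed = 6L,
                    noise = noise_config(2, seed = 5L),
                    solver = solver_config(duration = 150), kick_nA = 0.5,
                    kick_ms = 18)
  expect_identical(run1$result$spikes, run2$result$spikes)
  expect_identical(run1$result$V, run2$result$V)
})

test_that("an isolated RA neuron answers a brief pulse with a delayed burst", {
  np <- neuron_params("RA")
  stim <- stimulus_protocol(1, 0.5, onsets = 50, pulse_width = 18)
  sim <- simulate_neuron(np, stim = stim, duration = 150)
  spk <- sim$spikes[[1]]
  expect_gte(length(spk), 3)
  expect_lte(length(spk), 6)
  expect_gt(spk[1] - 50, 0.5)     # delayed onset
  rest <- resting_state(np)$V
  inburst <- sim$time >= spk[1] & sim$time <= spk[length(spk)]
  expect_gt(min(sim$V[inburst, 1]), rest + 5)  # plateau
})

test_that("fixed-step engine matches the adaptive reference integrator", {
  skip_if_not_installed("deSolve")
  ## single neuron, 1 s: spike times agree to < 0.5 ms
  np <- neuron_params("X")
  stim <- stimulus_protocol(1, 0.2, onsets = 100, pulse_width = 800)
  fx <- simulate_neuron(np, stim = stim, duration = 1000, dt = 0.01)
  ref <- simulate_reference(np, stim = stim, duration = 1000, dt_out = 0.02)
  ref_spk <- detect_spikes(ref$V[, 1], ref$time)
  expect_equal(length(fx$spikes[[1]]), length(ref_spk))
  expect_lt(max(abs(fx$spikes[[1]]- ref_spk)), 0.5)
  ## two-neuron RA->RA motif: first-spike times agree to < 0.5 ms
  ra <- neuron_params("RA")
  syn <- data.frame(pre = 1, post = 2, kind = "AMPA", g = 23)
  st2 <- stimulus_protocol(1, 0.5, onsets = 20, pulse_width = 18)
  fx2 <- simulate_neuron(list(ra, ra), syn, st2, duration = 80, dt = 0.01)
  ref2 <- simulate_reference(list(ra, ra), syn, st2, duration = 80,
                             dt_out = 0.02)
  for (i in 1:2) {
    rs <- detect_spikes(ref2$V[, i], ref2$time)
    expect_lt(abs(fx2$spikes[[i]][1] - rs[1]), 0.5)
  }
})

test_that("halving the step changes first-spike times by < 0.1 ms", {
  net <- wire_network(small_config(3L), seed = 9L)
  first_ra <- net$circuits[[1]]$ra_ids[1]
  stim <- stimulus_protocol(first_ra, 0.5, onsets = 10, pulse_width = 18)
  s1 <- simulate(net, stim, solver_config(dt = 0.01, duration = 150),
                 record_traces = FALSE)
  s2 <- simulate(net, stim, solver_config(dt = 0.005, duration = 150),
                 record_traces = FALSE)
  ra_ids <- net$neurons$id[net$neurons$class == "RA"]
  for (i in ra_ids) {
    a <- s1$spikes[[i]]; b <- s2$spikes[[i]]
    if (length(a) && length(b)) expect_lt(abs(a[1] - b[1]), 0.1)
    expect_equal(length(a) > 0, length(b) > 0)
  }
})

test_that("no state blows up across seeded builds within default ranges", {
  for (sd in 1:8) {
    run <- run_motif(config = small_config(4L), network_seed = sd,
                     solver = solver_config(duration = 150), kick_nA = 0.5,
                     kick_ms = 18)
    expect_true(all(is.finite(run$result$V)))
    expect_true(all(is.finite(run$result$state)))
  }
})

test_that("severing one chain AMPA edge silences everything downstream", {
  run0 <- small_motif(1L)
  net <- run0$net
  ord <- chain_order(net)
  ## cut the chain at the link leaving neuron 8 of the chain
  cut_pre <- ord[8]; cut_post <- ord[9]
  sel <- net$synapses$pre == cut_pre & net$synapses$post == cut_post &
    net$synapses$kind == "AMPA"
  expect_equal(sum(sel), 1)
  net$synapses$g[sel] <- 0
  res <- run_motif(net = net, solver = solver_config(duration = 220),
                   kick_nA = 0.5, kick_ms = 18)
  down <- ord[9:length(ord)]
  expect_true(all(lengths(res$result$spikes[down]) == 0))
  rep <- sequence_metrics(res$result, net)
  expect_false(rep$sequence_complete)
  expect_equal(rep$break_point, cut_post)
})

test_that("simulate rejects invalid networks and unknown stimulus targets", {
  net <- wire_network(small_config(3L), seed = 4L)
  bad <- net
  bad$synapses <- rbind(bad$synapses, data.frame(
    pre = bad$neurons$id[1], post = bad$neurons$id[1], kind = "AMPA", g = 1))
  expect_error(simulate(bad), "invalid network")
  expect_error(simulate(net, stim = stimulus_protocol(9999, 0.5, 10, 10)),
               "unknown neuron")
})
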