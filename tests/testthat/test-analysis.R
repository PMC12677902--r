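test_that("detect_spikes localizes planted spikes and ignores flat traces", {
  tt <- seq(0, 100, by = 0.1)
  expect_length(detect_spikes(rep(-65, length(tt)), tt), 0)
  V <- rep(-65, length(tt))
  at <- c(10, 25, 40, 71, 90)
  for (a in at) {
    i <- which.min(abs(tt - a))
    V[(i - 3):(i + 3)] <- c(-40, 0, 30, 40, 30, 0, -40)
  }
  got <- detect_spikes(V, tt, threshold = -20)
  expect_length(got, 5)
  expect_true(all(abs(got - at) <= 0.1))
  ## the result is stable over a threshold sweep across the spike flank
  for (th in c(-30, -20, -10)) {
    expect_length(detect_spikes(V, tt, threshold = th), 5)
  }
})

test_that("group_bursts splits trains at the ISI threshold", {
  spk <- cumsum(c(10, 2, 2, 2, 50, 2, 2))
  g <- group_bursts(spk, isi_threshold = 15)
  expect_equal(g$bursts$n_spikes, c(4L, 3L))
  expect_equal(g$bursts$duration, c(6, 4))
  expect_length(g$isolated, 0)
  ## tonic train: every ISI above threshold -> no bursts, all isolated
  tonic <- seq(0, 200, by = 25)
  g2 <- group_bursts(tonic, isi_threshold = 15)
  expect_equal(nrow(g2$bursts), 0)
  expect_equal(g2$isolated, tonic)
  expect_error(group_bursts(c(5, 3, 8)), "sorted")
})

test_that("group_bursts agrees with a brute-force O(n^2) clustering", {
  brute <- function(spk, thr, min_spikes = 2) {
    if (!length(spk)) return(integer(0))
    lab <- integer(length(spk))
    lab[1] <- 1
    for (i in seq_along(spk)[-1]) {
      lab[i] <- if (any(abs(spk[i] - spk[lab == lab[i - 1]]) <= thr &
                        spk[i] - spk[i - 1] <= thr)) lab[i - 1] else lab[i - 1] + 1
    }
    sizes <- tabulate(lab)
    sort(sizes[sizes >= min_spikes])
  }
  set.seed(314)
  for (i in 1:300) {
    spk <- sort(runif(sample(0:25, 1), 0, 200))
    g <- group_bursts(spk, isi_threshold = 10)
    expect_equal(sort(g$bursts$n_spikes), as.integer(brute(spk, 10)))
  }
})

test_that("inter_burst_delay returns first-peak latency and flags absences", {
  expect_equal(inter_burst_delay(c(5, 7), c(5, 7)), 0)
  expect_equal(inter_burst_delay(10, 14), 4)
  miss <- inter_burst_delay(numeric(0), c(3))
  expect_true(is.na(miss))
  expect_true(attr(miss, "missing")[["pre"]])
})

test_that("psp_metrics reports polarity and amplitude from baseline", {
  tt <- seq(0, 100, by = 0.1)
  flat <- rep(-70, length(tt))
  m <- psp_metrics(flat, tt, c(0, 20), c(30, 60))
  expect_equal(m$amplitude, 0)
  expect_equal(m$polarity, "none")
  dip <- flat; dip[tt > 40 & tt < 45] <- -73
  m2 <- psp_metrics(dip, tt, c(0, 20), c(30, 60))
  expect_equal(m2$polarity, "hyperpolarizing")
  expect_equal(m2$amplitude, 3)
  expect_error(psp_metrics(flat, tt, c(0, 20), c(150, 160)), "window")
})

test_that("sequence_metrics reproduces hand-computed statistics on a fixture", {
  ## 2-circuit toy net with prescribed spike trains
  cfg <- network_config()
  cfg$n_circuits <- 2L
  cfg$pools <- c(RA = 6L, INT = 2L, X = 2L)
  cfg$ra_per_circuit <- c(3L, 3L)
  cfg$int_per_circuit <- c(1L, 1L)
  cfg$x_per_circuit <- c(1L, 1L)
  cfg$ra_to_int_in <- c(3L, 3L)
  cfg$int_to_ra_out <- c(2L, 2L)
  cfg$x_to_int_out <- c(1L, 1L)
  cfg$int_to_x_out <- c(1L, 1L)
  net <- wire_network(cfg, seed = 3L)
  ord <- chain_order(net)
  spikes <- vector("list", 10)
  ## RA bursts: 4 spikes over 6 ms, onsets 10 ms apart in chain order
  for (k in seq_along(ord)) spikes[[ord[k]]] <- 10 * k + c(0, 2, 4, 6)
  int_ids <- net$neurons$id[net$neurons$class == "INT"]
  x_ids <- net$neurons$id[net$neurons$class == "X"]
  for (j in int_ids) spikes[[j]] <- seq(10, 70, by = 4)
  for (x in x_ids) spikes[[x]] <- c(20, 21.5, 23, 24.5, 50, 51.5, 53, 54.5)
  sim <- fake_sim(spikes, net$neurons$class, duration = 100)
  rep <- sequence_metrics(sim, net)
  expect_true(rep$sequence_complete)
  expect_true(is.na(rep$break_point))
  expect_equal(rep$summary$ra_burst_duration_mean, 6)
  expect_equal(rep$summary$ra_burst_spikes_mean, 4)
  expect_equal(rep$summary$x_bursts_mean, 2)
  expect_true(all(rep$x$ok))
  ## deleting the burst of RA k flips completeness and names the neuron
  for (k in seq_along(ord)) {
    broken <- spikes
    broken[[ord[k]]] <- numeric(0)
    repk <- sequence_metrics(fake_sim(broken, net$neurons$class), net)
    expect_false(repk$sequence_complete)
    expect_equal(repk$break_point, ord[k])
  }
  ## out-of-order onsets break completeness without a break point
  swapped <- spikes
  swapped[[ord[2]]] <- spikes[[ord[3]]]
  swapped[[ord[3]]] <- spikes[[ord[2]]]
  reps <- sequence_metrics(fake_sim(swapped, net$neurons$class), net)
  expect_false(reps$sequence_complete)
})

test_that("validator output is a pure function of the simulation result", {
  run <- small_motif(1L)
  r1 <- sequence_metrics(run$result, run$net)
  r2 <- sequence_metrics(run$result, run$net)
  expect_identical(r1[setdiff(names(r1), "span")], r2[setdiff(names(r2), "span")])
})
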