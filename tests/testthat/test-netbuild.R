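test_that("partition_pool respects bounds, sums, and infeasibility", {
  p <- hvcnet:::.with_seed(1, partition_pool(120, 20, c(6, 6)))
  expect_equal(p, rep(6L, 20))
  p2 <- hvcnet:::.with_seed(2, partition_pool(120, 20, c(3, 10)))
  expect_length(p2, 20)
  expect_true(all(p2 >= 3 & p2 <= 10))
  expect_equal(sum(p2), 120)
  expect_error(partition_pool(100, 20, c(6, 6)), "no valid partition")
})

test_that("partition_pool samples valid partitions uniformly (enumeration oracle)", {
  ## all compositions of 7 into 3 parts within [1,4], enumerated brute-force
  grid <- expand.grid(a = 1:4, b = 1:4, c = 1:4)
  valid <- grid[rowSums(grid) == 7, ]
  n_valid <- nrow(valid)
  draws <- hvcnet:::.with_seed(99, replicate(6000, paste(
    partition_pool(7, 3, c(1, 4)), collapse = "-")))
  tab <- table(draws)
  expect_equal(length(tab), n_valid)
  chi <- chisq.test(as.vector(tab), p = rep(1 / n_valid, n_valid))
  expect_gt(chi$p.value, 1e-4)
})

test_that("build_ra_chain is a uniform permutation with m-1 internal edges", {
  expect_equal(build_ra_chain(7L), 7L)
  ids <- c(11L, 12L, 13L, 14L)
  draws <- hvcnet:::.with_seed(7, replicate(7200, paste(build_ra_chain(ids),
                                                        collapse = "-")))
  tab <- table(draws)
  expect_equal(length(tab), factorial(4))
  chi <- chisq.test(as.vector(tab), p = rep(1 / 24, 24))
  expect_gt(chi$p.value, 1e-4)
  ## edge count: a chain over m neurons carries m-1 within-circuit synapses
  net <- wire_network(small_config(4L), seed = 5L)
  for (cc in net$circuits) {
    ch <- cc$ra_ids
    edges <- paste(net$synapses$pre, net$synapses$post)
    internal <- paste(ch[-length(ch)], ch[-1])
    expect_true(all(internal %in% edges))
  }
})

test_that("wire_network builds legal graphs at default and minimal scale", {
  net <- wire_network(network_config(), seed = 1L)
  expect_s3_class(net, "hvc_network")
  expect_length(validate_graph(net), 0)
  expect_equal(nrow(net$neurons), 220)
  ## minimal legal instance: 2 circuits, ranges collapsed
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
  mini <- wire_network(cfg, seed = 3L)
  expect_length(validate_graph(mini), 0)
  expect_equal(nrow(mini$neurons), 10)
})

test_that("wiring rules hold under an independent brute-force edge scan", {
  for (sd in 1:25) {
    net <- wire_network(small_config(), seed = sd)
    syn <- net$synapses
    cls <- setNames(net$neurons$class, net$neurons$id)
    circ <- setNames(net$neurons$circuit, net$neurons$id)
    pre_c <- cls[as.character(syn$pre)]
    post_c <- cls[as.character(syn$post)]
    ## no INT->RA edge inside the interneuron's own circuit
    ira <- pre_c == "INT" & post_c == "RA"
    expect_equal(sum(circ[as.character(syn$pre[ira])] ==
                     circ[as.character(syn$post[ira])]), 0)
    ## INT<->X edges stay within one circuit
    loc <- (pre_c == "INT" & post_c == "X") | (pre_c == "X" & post_c == "INT")
    expect_true(all(circ[as.character(syn$pre[loc])] ==
                    circ[as.character(syn$post[loc])]))
    ## kinds match the allowed class pairs
    expect_true(all(syn$kind[pre_c == "INT"] == "GABA_A"))
    expect_true(all(syn$kind[pre_c != "INT"] == "AMPA"))
    ## degree bounds, counted from scratch
    cfg <- net$config
    for (j in net$neurons$id[net$neurons$class == "INT"]) {
      indeg <- sum(syn$post == j & cls[as.character(syn$pre)] == "RA")
      expect_true(indeg >= cfg$ra_to_int_in[1] && indeg <= cfg$ra_to_int_in[2])
      out_ra <- sum(syn$pre == j & cls[as.character(syn$post)] == "RA")
      expect_true(out_ra >= cfg$int_to_ra_out[1] &&
                  out_ra <= cfg$int_to_ra_out[2])
    }
    ## every X neuron receives at least one inhibitory afferent
    for (xid in net$neurons$id[net$neurons$class == "X"]) {
      expect_gte(sum(syn$post == xid & syn$kind == "GABA_A"), 1)
    }
    ## partition conservation
    mem <- unlist(lapply(net$circuits, function(cc)
      c(cc$ra_ids, cc$int_ids, cc$x_ids)))
    expect_setequal(mem, net$neurons$id)
    expect_equal(anyDuplicated(mem), 0L)
  }
})

test_that("network construction is deterministic given (config, seed)", {
  n1 <- wire_network(small_config(), seed = 11L)
  n2 <- wire_network(small_config(), seed = 11L)
  expect_identical(n1$synapses, n2$synapses)
  expect_identical(n1$circuits, n2$circuits)
  f1 <- tempfile(fileext = ".csv"); s1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".csv"); s2 <- tempfile(fileext = ".json")
  write_network(n1, f1, s1)
  write_network(n2, f2, s2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  n3 <- wire_network(small_config(), seed = 12L)
  expect_false(identical(n1$synapses, n3$synapses))
})

test_that("validate_graph reports planted faults precisely", {
  net <- wire_network(small_config(), seed = 2L)
  expect_length(validate_graph(net), 0)
  ## plant an INT->RA edge inside the interneuron's own circuit
  int1 <- net$neurons$id[net$neurons$class == "INT"][1]
  circ1 <- net$neurons$circuit[int1]
  ra_same <- net$neurons$id[net$neurons$class == "RA" &
                            net$neurons$circuit == circ1][1]
  bad <- net
  bad$synapses <- rbind(bad$synapses,
                        data.frame(pre = int1, post = ra_same,
                                   kind = "GABA_A", g = 1))
  v <- validate_graph(bad)
  expect_length(grep("own circuit", v), 1)
  expect_match(v[grep("own circuit", v)], paste0(int1, "->", ra_same))
  ## break an inter-circuit chain link
  bad2 <- net
  a <- net$circuits[[1]]$ra_ids
  b <- net$circuits[[2]]$ra_ids
  drop <- with(bad2$synapses, !(pre == a[length(a)] & post == b[1]))
  bad2$synapses <- bad2$synapses[drop, ]
  v2 <- validate_graph(bad2)
  expect_true(any(grepl("chain break between circuits 1, 2", v2)))
})

test_that("network serialization round-trips losslessly", {
  net <- wire_network(small_config(), seed = 8L)
  net <- apply_perturbation(net, "X", "population", "g_SK", "set", 3.5)
  ef <- tempfile(fileext = ".csv"); sf <- tempfile(fileext = ".json")
  write_network(net, ef, sf)
  back <- read_network(ef, sf)
  expect_equal(back$synapses, net$synapses)
  expect_identical(lapply(back$circuits, unclass),
                   lapply(net$circuits, unclass))
  expect_equal(back$neurons, net$neurons)
  expect_equal(back$cells[[net$neurons$id[net$neurons$class == "X"][1]]]$pars,
               net$cells[[net$neurons$id[net$neurons$class == "X"][1]]]$pars)
  expect_length(validate_graph(back), 0)
})
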