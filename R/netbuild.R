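## Randomized chain-of-microcircuits network construction.
##
## The network is a chain of microcircuits, each holding a few RA-projecting
## neurons wired in a feedforward AMPA chain, plus interneurons and
## X-projecting neurons. Rules of engagement:
##   * RA -> RA        AMPA, chain within a circuit; circuits linked
##                     last-RA(i) -> first-RA(i+1)
##   * RA -> INT       AMPA, donors drawn from the full RA pool
##   * INT -> RA       GABA-A, targets never in the interneuron's own circuit
##   * X  -> INT       AMPA, within one circuit only
##   * INT -> X        GABA-A, within one circuit only

## evaluate `expr` under a private RNG stream, restoring the caller's seed
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Random partition of a neuron pool over microcircuits
#'
#' Splits `pool_size` neurons into `n_circuits` parts, each within
#' `per_circuit_range`, summing exactly to `pool_size`. Sampling is by
#' rejection over iid discrete uniforms conditioned on the sum, so all valid
#' partitions are approximately equally likely.
#'
#' @param pool_size Total number of neurons of the class.
#' @param n_circuits Number of microcircuits.
#' @param per_circuit_range `c(lo, hi)` bounds per circuit.
#' @param max_tries Rejection-sampling cap before giving up.
#' @return Integer vector of length `n_circuits`.
#' @export
partition_pool <- function(pool_size, n_circuits, per_circuit_range,
                           max_tries = 1e5) {
  lo <- per_circuit_range[1]; hi <- per_circuit_range[2]
  if (pool_size < n_circuits * lo || pool_size > n_circuits * hi) {
    stop("no valid partition: pool of ", pool_size, " cannot be split into ",
         n_circuits, " circuits of [", lo, ", ", hi, "] neurons")
  }
  if (lo == hi) return(rep(as.integer(lo), n_circuits))
  for (i in seq_len(max_tries)) {
    parts <- lo + sample.int(hi - lo + 1, n_circuits, replace = TRUE) - 1L
    if (sum(parts) == pool_size) return(as.integer(parts))
  }
  stop("partition rejection sampling failed after ", max_tries, " tries")
}

#' Random feedforward chain order for a circuit's RA neurons
#'
#' Selects the circuit's RA neurons one at a time, uniformly at random, into
#' a chain order; consecutive pairs receive AMPA synapses when the network
#' is wired. The first and last elements are the circuit's entry and exit
#' points for inter-circuit links.
#'
#' @param ra_ids RA neuron ids assigned to the circuit.
#' @return `ra_ids` in chain order.
#' @export
build_ra_chain <- function(ra_ids) {
  if (length(ra_ids) <= 1) return(ra_ids)
  sample(ra_ids)
}

## draw `k` in count_range capped by availability; error if even the lower
## bound is unsatisfiable
.draw_count <- function(count_range, available, what) {
  lo <- count_range[1]; hi <- count_range[2]
  if (available < lo) {
    stop("cannot draw ", lo, " ", what, " from only ", available, " candidates")
  }
  hi <- min(hi, available)
  if (lo == hi) lo else sample(lo:hi, 1)
}

.sample_ids <- function(ids, k) if (length(ids) == 1) rep(ids, k) else sample(ids, k)

#' Default network configuration
#'
#' Pool sizes (2:1:1 RA:INT:X), microcircuit count, per-circuit membership
#' ranges, per-neuron connection-count ranges, and per-pair synaptic
#' conductance ranges.
#'
#' @return Named list of network construction parameters.
#' @export
network_config <- function() {
  list(pools = c(RA = 120L, INT = 50L, X = 50L),
       n_circuits = 20L,
       ra_per_circuit = c(3L, 10L),
       int_per_circuit = c(1L, 4L),
       x_per_circuit = c(1L, 4L),
       ra_to_int_in = c(3L, 8L),
       int_to_ra_out = c(2L, 4L),
       x_to_int_out = c(1L, 3L),
       int_to_x_out = c(1L, 2L),
       g_ranges = synaptic_ranges())
}

#' Build the randomized microcircuit-chain network
#'
#' Partitions the three pools over the microcircuits, wires the RA chains
#' and inter-circuit links, then adds RA->INT, INT->RA (never same-circuit),
#' X->INT and INT->X (same-circuit only) synapses with per-edge conductances
#' drawn uniformly from the configured ranges. Fully deterministic given
#' `(config, seed)`.
#'
#' @param config Network configuration, see [network_config()].
#' @param seed Integer construction seed.
#' @return An object of class `hvc_network` with elements `neurons`
#'   (data.frame: id, class, circuit, chain_pos), `circuits` (per-circuit id
#'   lists, RA in chain order), `synapses` (data.frame: pre, post, kind, g),
#'   `cells` (per-neuron `hvc_neuron` parameter sets), `pools`, and `seed`.
#' @export
wire_network <- function(config = network_config(), seed = 1L) {
  .with_seed(seed, {
    pools <- config$pools
    nc <- config$n_circuits
    n_ra <- pools[["RA"]]; n_int <- pools[["INT"]]; n_x <- pools[["X"]]
    ra_ids <- seq_len(n_ra)
    int_ids <- n_ra + seq_len(n_int)
    x_ids <- n_ra + n_int + seq_len(n_x)

    parts_ra <- partition_pool(n_ra, nc, config$ra_per_circuit)
    ## joint INT/X partition: each circuit must have enough interneuron
    ## GABA capacity (int_to_x_out[2] per INT) to inhibit all of its X
    ## neurons, so that every X neuron can fire rebound bursts
    cap <- config$int_to_x_out[2]
    repeat {
      parts_int <- partition_pool(n_int, nc, config$int_per_circuit)
      parts_x <- partition_pool(n_x, nc, config$x_per_circuit)
      if (all(parts_x <= cap * parts_int)) break
    }

    ## recruit members randomly, one neuron at a time, from each pool
    ra_pool <- sample(ra_ids); int_pool <- sample(int_ids); x_pool <- sample(x_ids)
    circuits <- vector("list", nc)
    o1 <- o2 <- o3 <- 0L
    for (i in seq_len(nc)) {
      mem_ra <- ra_pool[o1 + seq_len(parts_ra[i])]; o1 <- o1 + parts_ra[i]
      mem_int <- int_pool[o2 + seq_len(parts_int[i])]; o2 <- o2 + parts_int[i]
      mem_x <- x_pool[o3 + seq_len(parts_x[i])]; o3 <- o3 + parts_x[i]
      circuits[[i]] <- list(index = i, ra_ids = build_ra_chain(mem_ra),
                            int_ids = sort(mem_int), x_ids = sort(mem_x))
    }

    circ_of <- integer(n_ra + n_int + n_x)
    chain_pos <- rep(NA_integer_, n_ra + n_int + n_x)
    for (i in seq_len(nc)) {
      cc <- circuits[[i]]
      circ_of[c(cc$ra_ids, cc$int_ids, cc$x_ids)] <- i
      chain_pos[cc$ra_ids] <- seq_along(cc$ra_ids)
    }

    gr <- config$g_ranges
    draw_g <- function(pair, k) stats::runif(k, gr[[pair]][1], gr[[pair]][2])
    pre <- post <- integer(0); kind <- character(0); g <- numeric(0)
    add <- function(p, q, kd, gs) {
      pre <<- c(pre, p); post <<- c(post, q)
      kind <<- c(kind, rep(kd, length(p))); g <<- c(g, gs)
    }

    ## RA chains and inter-circuit links
    for (i in seq_len(nc)) {
      ch <- circuits[[i]]$ra_ids
      if (length(ch) > 1) {
        add(ch[-length(ch)], ch[-1], "AMPA", draw_g("RA->RA", length(ch) - 1))
      }
      if (i < nc) {
        add(ch[length(ch)], circuits[[i + 1]]$ra_ids[1], "AMPA",
            draw_g("RA->RA", 1))
      }
    }
    ## RA -> INT: per-INT in-degree drawn from the configured range; donors
    ## are drawn without replacement, stratified along the chain (one donor
    ## per chain segment) so every interneuron receives excitation spread
    ## across the whole motif, as required for its dense, song-long firing
    ra_chain <- unlist(lapply(circuits, function(cc) cc$ra_ids))
    for (j in int_ids) {
      k <- .draw_count(config$ra_to_int_in, n_ra, "RA donors")
      seg <- split(ra_chain, cut(seq_len(n_ra), k, labels = FALSE))
      donors <- vapply(seg, function(s) .sample_ids(s, 1), numeric(1))
      add(donors, rep(j, k), "AMPA", draw_g("RA->INT", k))
    }
    ## INT -> RA: targets from any circuit except the interneuron's own
    for (j in int_ids) {
      eligible <- ra_ids[circ_of[ra_ids] != circ_of[j]]
      k <- .draw_count(config$int_to_ra_out, length(eligible), "RA targets")
      add(rep(j, k), .sample_ids(eligible, k), "GABA_A", draw_g("INT->RA", k))
    }
    ## X -> INT and INT -> X: same circuit only
    for (i in seq_len(nc)) {
      cc <- circuits[[i]]
      for (x in cc$x_ids) {
        k <- .draw_count(config$x_to_int_out, length(cc$int_ids), "INT targets")
        add(rep(x, k), .sample_ids(cc$int_ids, k), "AMPA", draw_g("X->INT", k))
      }
      ## INT -> X with full coverage: every X neuron must receive at least
      ## one inhibitory afferent (rebound bursts require inhibition), with
      ## per-INT out-degrees still inside the configured range
      nx <- length(cc$x_ids)
      repeat {
        ks <- vapply(cc$int_ids, function(j)
          as.integer(.draw_count(config$int_to_x_out, nx, "X targets")),
          integer(1))
        if (sum(ks) >= nx) break
      }
      slots <- rep(cc$int_ids, ks)
      slots <- slots[sample.int(length(slots))]
      tgt <- rep(NA_integer_, length(slots))
      tgt[seq_len(nx)] <- .sample_ids(cc$x_ids, nx)
      for (sl in which(is.na(tgt))) {
        taken <- tgt[slots == slots[sl] & !is.na(tgt)]
        free <- setdiff(cc$x_ids, taken)
        tgt[sl] <- if (length(free)) .sample_ids(free, 1) else NA_integer_
      }
      keep <- !is.na(tgt)
      add(slots[keep], tgt[keep], "GABA_A", draw_g("INT->X", sum(keep)))
    }

    neurons <- data.frame(
      id = c(ra_ids, int_ids, x_ids),
      class = c(rep("RA", n_ra), rep("INT", n_int), rep("X", n_x)),
      circuit = circ_of, chain_pos = chain_pos,
      stringsAsFactors = FALSE
    )
    cells <- c(replicate(n_ra, neuron_params("RA"), simplify = FALSE),
               replicate(n_int, neuron_params("INT"), simplify = FALSE),
               replicate(n_x, neuron_params("X"), simplify = FALSE))
    net <- structure(
      list(neurons = neurons, circuits = circuits,
           synapses = data.frame(pre = pre, post = post, kind = kind, g = g,
                                 stringsAsFactors = FALSE),
           cells = cells, pools = pools, config = config, seed = seed),
      class = "hvc_network")
    viol <- validate_graph(net)
    if (length(viol)) {
      stop("wired network violates its own invariants:\n  ",
           paste(viol, collapse = "\n  "))
    }
    net
  })
}

#' @export
print.hvc_network <- function(x, ...) {
  cat("HVC microcircuit-chain network: ",
      sum(x$pools), " neurons (", paste(names(x$pools), x$pools, sep = ":",
                                        collapse = ", "),
      "), ", length(x$circuits), " microcircuits, ",
      nrow(x$synapses), " synapses, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Validate a network against the wiring rules
#'
#' Independent brute-force scan of the membership tables and edge list.
#' Returns a character vector of violations (empty when the graph is legal),
#' each naming the broken rule and the offending neuron/edge ids.
#'
#' @param net An `hvc_network`.
#' @return Character vector of violation messages.
#' @export
validate_graph <- function(net) {
  v <- character(0)
  nn <- net$neurons
  syn <- net$synapses
  cfg <- net$config
  circ <- stats::setNames(nn$circuit, nn$id)
  cls <- stats::setNames(nn$class, nn$id)

  ## membership: every neuron in exactly one circuit, counts within bounds
  all_mem <- unlist(lapply(net$circuits, function(cc)
    c(cc$ra_ids, cc$int_ids, cc$x_ids)))
  if (anyDuplicated(all_mem)) {
    v <- c(v, paste("neuron(s) in more than one microcircuit:",
                    paste(unique(all_mem[duplicated(all_mem)]), collapse = ",")))
  }
  if (!setequal(all_mem, nn$id)) {
    v <- c(v, "microcircuit membership does not cover the neuron pool exactly")
  }
  for (cc in net$circuits) {
    chk <- function(ids, rng, what) {
      if (length(ids) < rng[1] || length(ids) > rng[2]) {
        sprintf("circuit %d has %d %s neurons (allowed %d-%d)",
                cc$index, length(ids), what, rng[1], rng[2])
      } else character(0)
    }
    v <- c(v, chk(cc$ra_ids, cfg$ra_per_circuit, "RA"),
           chk(cc$int_ids, cfg$int_per_circuit, "INT"),
           chk(cc$x_ids, cfg$x_per_circuit, "X"))
  }

  ## edge-level rules
  if (any(syn$pre == syn$post)) {
    v <- c(v, paste("self-synapse on neuron(s):",
                    paste(syn$pre[syn$pre == syn$post], collapse = ",")))
  }
  key <- paste(syn$pre, syn$post, syn$kind)
  if (anyDuplicated(key)) {
    v <- c(v, paste("duplicate edge(s):", paste(unique(key[duplicated(key)]),
                                                collapse = "; ")))
  }
  pairkey <- paste0(cls[as.character(syn$pre)], "->", cls[as.character(syn$post)])
  expected <- stats::setNames(.ALLOWED_PAIRS$kind,
                              paste0(.ALLOWED_PAIRS$pre, "->", .ALLOWED_PAIRS$post))
  bad <- is.na(expected[pairkey]) | expected[pairkey] != syn$kind
  if (any(bad)) {
    v <- c(v, paste("disallowed class/kind edge(s):",
                    paste(sprintf("%d->%d (%s %s)", syn$pre[bad], syn$post[bad],
                                  pairkey[bad], syn$kind[bad]), collapse = "; ")))
  }
  ## INT->RA never same circuit; INT->X and X->INT same circuit only
  ira <- pairkey == "INT->RA" & !bad
  same <- circ[as.character(syn$pre)] == circ[as.character(syn$post)]
  if (any(ira & same)) {
    v <- c(v, paste("INT->RA edge(s) inside the interneuron's own circuit:",
                    paste(sprintf("%d->%d", syn$pre[ira & same],
                                  syn$post[ira & same]), collapse = "; ")))
  }
  loc <- (pairkey %in% c("INT->X", "X->INT")) & !bad
  if (any(loc & !same)) {
    v <- c(v, paste("cross-circuit INT/X edge(s):",
                    paste(sprintf("%d->%d", syn$pre[loc & !same],
                                  syn$post[loc & !same]), collapse = "; ")))
  }

  ## RA chain integrity: consecutive chain edges and inter-circuit links
  ed <- paste(syn$pre, syn$post)[syn$kind == "AMPA"]
  for (cc in net$circuits) {
    ch <- cc$ra_ids
    if (length(ch) > 1) {
      need <- paste(ch[-length(ch)], ch[-1])
      miss <- need[!(need %in% ed)]
      if (length(miss)) {
        v <- c(v, sprintf("broken RA chain in circuit %d (missing edge %s)",
                          cc$index, paste(miss, collapse = "; ")))
      }
    }
  }
  for (i in seq_len(length(net$circuits) - 1)) {
    a <- net$circuits[[i]]$ra_ids
    b <- net$circuits[[i + 1]]$ra_ids
    if (!(paste(a[length(a)], b[1]) %in% ed)) {
      v <- c(v, sprintf("chain break between circuits %d, %d", i, i + 1))
    }
  }

  ## degree bounds (brute-force counts)
  int_ids <- nn$id[nn$class == "INT"]
  deg <- function(ids, sel, by) {
    tab <- table(factor(by[sel], levels = ids))
    as.integer(tab)
  }
  in_ra_int <- deg(int_ids, pairkey == "RA->INT", syn$post)
  bad_deg <- int_ids[in_ra_int < cfg$ra_to_int_in[1] |
                     in_ra_int > cfg$ra_to_int_in[2]]
  if (length(bad_deg)) {
    v <- c(v, paste("INT neuron(s) with RA->INT in-degree out of range:",
                    paste(bad_deg, collapse = ",")))
  }
  out_int_ra <- deg(int_ids, pairkey == "INT->RA", syn$pre)
  bad_deg <- int_ids[out_int_ra < cfg$int_to_ra_out[1] |
                     out_int_ra > cfg$int_to_ra_out[2]]
  if (length(bad_deg)) {
    v <- c(v, paste("INT neuron(s) with INT->RA out-degree out of range:",
                    paste(bad_deg, collapse = ",")))
  }
  x_ids <- nn$id[nn$class == "X"]
  out_x_int <- deg(x_ids, pairkey == "X->INT", syn$pre)
  bad_deg <- x_ids[out_x_int < cfg$x_to_int_out[1] |
                   out_x_int > cfg$x_to_int_out[2]]
  if (length(bad_deg)) {
    v <- c(v, paste("X neuron(s) with X->INT out-degree out of range:",
                    paste(bad_deg, collapse = ",")))
  }
  out_int_x <- deg(int_ids, pairkey == "INT->X", syn$pre)
  bad_deg <- int_ids[out_int_x < cfg$int_to_x_out[1] |
                     out_int_x > cfg$int_to_x_out[2]]
  if (length(bad_deg)) {
    v <- c(v, paste("INT neuron(s) with INT->X out-degree out of range:",
                    paste(bad_deg, collapse = ",")))
  }
  v
}

#' Serialize a network to an edge-list CSV plus a JSON sidecar
#'
#' @param net An `hvc_network`.
#' @param edge_file Path for the edge-list CSV (pre, post, kind, g).
#' @param sidecar_file Path for the JSON sidecar (pools, seed, circuit
#'   membership with RA chain order, per-neuron conductance overrides).
#' @return Invisibly, the two paths.
#' @export
write_network <- function(net, edge_file, sidecar_file) {
  utils::write.csv(net$synapses, edge_file, row.names = FALSE, quote = FALSE)
  defaults <- lapply(c(RA = "RA", INT = "INT", X = "X"),
                     function(cl) neuron_params(cl)$pars)
  ov <- list()
  for (i in seq_along(net$cells)) {
    p <- net$cells[[i]]$pars
    d <- defaults[[net$neurons$class[i]]]
    diffs <- p[vapply(names(p), function(n) !identical(p[[n]], d[[n]]), logical(1))]
    if (length(diffs)) ov[[as.character(net$neurons$id[i])]] <- diffs
  }
  side <- list(pools = as.list(net$pools), seed = net$seed,
               config = net$config[setdiff(names(net$config), "pools")],
               circuits = lapply(net$circuits, function(cc)
                 list(index = cc$index, ra_ids = cc$ra_ids,
                      int_ids = cc$int_ids, x_ids = cc$x_ids)),
               cell_overrides = ov)
  jsonlite::write_json(side, sidecar_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(edge_file, sidecar_file))
}

#' Read a network back from its CSV + JSON serialization
#'
#' @param edge_file,sidecar_file Paths written by [write_network()].
#' @return An `hvc_network`, equal to the one serialized.
#' @export
read_network <- function(edge_file, sidecar_file) {
  syn <- utils::read.csv(edge_file, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(sidecar_file, simplifyVector = TRUE)
  pools <- unlist(side$pools)
  circuits <- lapply(seq_len(nrow(side$circuits)), function(i) {
    list(index = side$circuits$index[i],
         ra_ids = as.integer(unlist(side$circuits$ra_ids[i])),
         int_ids = as.integer(unlist(side$circuits$int_ids[i])),
         x_ids = as.integer(unlist(side$circuits$x_ids[i])))
  })
  n_ra <- pools[["RA"]]; n_int <- pools[["INT"]]; n_x <- pools[["X"]]
  circ_of <- integer(sum(pools)); chain_pos <- rep(NA_integer_, sum(pools))
  for (cc in circuits) {
    circ_of[c(cc$ra_ids, cc$int_ids, cc$x_ids)] <- cc$index
    chain_pos[cc$ra_ids] <- seq_along(cc$ra_ids)
  }
  neurons <- data.frame(
    id = seq_len(sum(pools)),
    class = c(rep("RA", n_ra), rep("INT", n_int), rep("X", n_x)),
    circuit = circ_of, chain_pos = chain_pos, stringsAsFactors = FALSE)
  cells <- lapply(seq_len(sum(pools)), function(i) {
    ov <- side$cell_overrides[[as.character(i)]]
    if (is.null(ov)) neuron_params(neurons$class[i])
    else do.call(neuron_params, c(list(neurons$class[i]), ov))
  })
  config <- network_config()
  for (nm in names(side$config)) {
    cfgv <- side$config[[nm]]
    config[[nm]] <- if (nm == "g_ranges") lapply(cfgv, as.numeric)
                    else if (is.numeric(config[[nm]])) as.integer(unlist(cfgv))
                    else cfgv
  }
  config$pools <- pools
  structure(list(neurons = neurons, circuits = circuits, synapses = syn,
                 cells = cells, pools = pools, config = config,
                 seed = side$seed),
            class = "hvc_network")
}

#' RA neuron ids in chain order
#'
#' The global order in which the sequence is expected to travel: circuits in
#' chain order, RA neurons in within-circuit chain order.
#'
#' @param net An `hvc_network`.
#' @return Integer vector of RA ids.
#' @export
chain_order <- function(net) {
  unlist(lapply(net$circuits, function(cc) cc$ra_ids))
}
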