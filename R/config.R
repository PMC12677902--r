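## Configuration loading and result serialization (cli_io).

#' Full default run configuration
#'
#' All tunable settings in one nested list: `network` (pool sizes, circuit
#' count, degree and conductance ranges), `cells` (per-class parameter
#' overrides), `solver`, `noise`, `experiment` and `seeds`. This is the
#' schema against which configuration files are validated.
#'
#' @return Nested named list.
#' @export
hvc_config <- function() {
  list(network = network_config(),
       cells = list(RA = list(), X = list(), INT = list()),
       solver = list(method = "fixed_rk4_em", dt = 0.01, duration = 1000,
                     record_stride = 10L, rel_tol = 1e-6, abs_tol = 1e-8),
       noise = list(sigma_pct = 0, seed = 1L),
       experiment = list(kick_nA = 0.5, kick_ms = 18, fold_up = 20,
                         n_sims = 100),
       seeds = list(network = 1L, noise = 1L))
}

## recursive merge of `over` into `base`, rejecting unknown keys
.merge_config <- function(base, over, path = "") {
  for (nm in names(over)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      stop("unknown configuration key '", here, "'", call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      ## cells.* and g_ranges accept arbitrary-but-known inner keys
      if (nm %in% c("RA", "X", "INT", "g_ranges")) base[[nm]] <- over[[nm]]
      else base[[nm]] <- .merge_config(base[[nm]], over[[nm]], here)
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

.check_config <- function(cfg) {
  errs <- character(0)
  if (!is.numeric(cfg$solver$dt) || cfg$solver$dt <= 0) {
    errs <- c(errs, "solver.dt must be > 0")
  }
  if (!is.numeric(cfg$solver$duration) || cfg$solver$duration <= 0) {
    errs <- c(errs, "solver.duration must be > 0")
  }
  if (!is.numeric(cfg$noise$sigma_pct) || cfg$noise$sigma_pct < 0) {
    errs <- c(errs, "noise.sigma_pct must be >= 0")
  }
  nw <- cfg$network
  for (nm in c("ra_per_circuit", "int_per_circuit", "x_per_circuit",
               "ra_to_int_in", "int_to_ra_out", "x_to_int_out",
               "int_to_x_out")) {
    r <- nw[[nm]]
    if (length(r) != 2 || any(r < 0) || r[1] > r[2]) {
      errs <- c(errs, paste0("network.", nm, " must be a valid [lo, hi] range"))
    }
  }
  if (length(errs)) {
    stop("configuration error(s):\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, merges it over the defaults of
#' [hvc_config()], rejects unknown keys (listing every offending key path),
#' and validates value ranges. An empty file yields all defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Validated configuration list with attribute `"resolved"` set.
#' @export
load_config <- function(path = NULL) {
  cfg <- hvc_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    over <- yaml::read_yaml(path)
    if (!is.null(over)) cfg <- .merge_config(cfg, over)
  }
  cfg$network$pools <- unlist(cfg$network$pools)
  for (nm in grep("_per_circuit$|_in$|_out$", names(cfg$network), value = TRUE)) {
    cfg$network[[nm]] <- as.integer(unlist(cfg$network[[nm]]))
  }
  cfg$network$g_ranges <- lapply(cfg$network$g_ranges, as.numeric)
  cfg <- .check_config(cfg)
  attr(cfg, "resolved") <- TRUE
  cfg
}

#' Apply per-class cell parameter overrides to a network
#'
#' Replaces the parameter set of every neuron of a class with defaults
#' modified by the named overrides (as accepted by [neuron_params()]);
#' used by the CLI to honor the `cells` section of a configuration file.
#'
#' @param net An `hvc_network`.
#' @param cells Named list (`RA`, `X`, `INT`) of override lists.
#' @return The modified network.
#' @export
apply_cell_overrides <- function(net, cells) {
  for (cl in intersect(names(cells), c("RA", "X", "INT"))) {
    ov <- cells[[cl]]
    if (!length(ov)) next
    ids <- net$neurons$id[net$neurons$class == cl]
    for (id in ids) {
      net$cells[[id]] <- do.call(neuron_params, c(list(cl), ov))
    }
  }
  net
}

#' Write spike trains to CSV
#'
#' Plain tool-agnostic format: one row per spike with neuron id, class,
#' microcircuit and spike time.
#'
#' @param result An `hvc_sim`.
#' @param net The matching `hvc_network` (or `NULL` for motif-free sims).
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_spikes <- function(result, net = NULL, path) {
  circ <- if (is.null(net)) rep(NA_integer_, length(result$spikes))
          else net$neurons$circuit
  rows <- do.call(rbind, lapply(seq_along(result$spikes), function(i) {
    s <- result$spikes[[i]]
    if (!length(s)) return(NULL)
    data.frame(neuron_id = result$neuron_ids[i], class = result$classes[i],
               circuit = circ[i], time_ms = s)
  }))
  if (is.null(rows)) {
    rows <- data.frame(neuron_id = integer(0), class = character(0),
                       circuit = integer(0), time_ms = numeric(0))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike trains written by [write_spikes()]
#'
#' @param path CSV path.
#' @param n_neurons Total neuron count (to restore empty trains).
#' @return List of per-neuron spike-time vectors.
#' @export
read_spikes <- function(path, n_neurons) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(n_neurons), function(i)
    as.numeric(d$time_ms[d$neuron_id == i]))
}

#' Write voltage traces to CSV
#'
#' Long columns: time plus one column per neuron (`V<id>`), strided as
#' recorded.
#'
#' @param result An `hvc_sim` with recorded traces.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_traces <- function(result, path) {
  if (!length(result$time)) stop("simulation has no recorded traces")
  d <- data.frame(time = result$time, result$V)
  names(d) <- c("time_ms", paste0("V", result$neuron_ids))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a validation report to JSON
#'
#' @param report An `hvc_validation`.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_validation <- function(report, path) {
  jsonlite::write_json(
    list(sequence_complete = report$sequence_complete,
         break_point = report$break_point,
         all_ra_ok = report$all_ra_ok, all_x_ok = report$all_x_ok,
         all_int_tonic = report$all_int_tonic,
         summary = report$summary, ra = report$ra, x = report$x,
         int = report$int),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
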