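## Spike detection, burst grouping, per-class firing statistics, and the
## desired-network-activity validator.

#' Detect spikes in a sampled voltage trace
#'
#' Upward threshold crossings separated by at least the refractory period;
#' each spike time is localized at the local voltage maximum following the
#' crossing.
#'
#' @param V Uniformly sampled voltage trace (mV).
#' @param time Sample times (ms), same length as `V`.
#' @param threshold Detection threshold (mV).
#' @param refractory Minimum separation between spikes (ms).
#' @return Numeric vector of spike (peak) times.
#' @export
detect_spikes <- function(V, time, threshold = -20, refractory = 1) {
  stopifnot(length(V) == length(time))
  above <- V >= threshold
  ups <- which(!above[-length(above)] & above[-1]) + 1
  if (!length(ups)) return(numeric(0))
  downs <- which(above[-length(above)] & !above[-1])
  peaks <- vapply(ups, function(u) {
    d <- downs[downs >= u]
    end <- if (length(d)) d[1] else length(V)
    seg <- u:end
    time[seg[which.max(V[seg])]]
  }, numeric(1))
  keep <- c(TRUE, diff(peaks) >= refractory)
  ## enforce refractory sequentially (a run of close peaks keeps the first)
  out <- numeric(0)
  last <- -Inf
  for (p in peaks) {
    if (p - last >= refractory) { out <- c(out, p); last <- p }
  }
  out
}

#' Group a spike train into bursts
#'
#' Maximal runs of spikes whose consecutive inter-spike intervals are all
#' `<= isi_threshold`. Runs shorter than `min_spikes` are reported as
#' isolated spikes, not bursts.
#'
#' @param spike_times Sorted spike times (ms).
#' @param isi_threshold Maximum within-burst ISI (ms).
#' @param min_spikes Minimum spikes for a run to count as a burst.
#' @return List with `bursts` (data.frame: onset, offset, n_spikes,
#'   duration) and `isolated` (times of spikes outside any burst).
#' @export
group_bursts <- function(spike_times, isi_threshold = 15, min_spikes = 2) {
  if (is.unsorted(spike_times)) stop("spike times must be sorted")
  n <- length(spike_times)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      n_spikes = integer(0), duration = numeric(0))
  if (n == 0) return(list(bursts = empty, isolated = numeric(0)))
  grp <- cumsum(c(1, diff(spike_times) > isi_threshold))
  sizes <- tabulate(grp)
  onset <- tapply(spike_times, grp, min)
  offset <- tapply(spike_times, grp, max)
  isb <- sizes >= min_spikes
  list(bursts = data.frame(onset = as.numeric(onset[isb]),
                           offset = as.numeric(offset[isb]),
                           n_spikes = as.integer(sizes[isb]),
                           duration = as.numeric(offset[isb] - onset[isb])),
       isolated = spike_times[grp %in% which(!isb)])
}

#' First-peak-to-first-peak latency between two neurons' bursts
#'
#' @param pre_spikes,post_spikes Spike (peak) time vectors.
#' @return Latency in ms, or `NA` (with attribute `missing`) if either
#'   neuron has no spikes.
#' @export
inter_burst_delay <- function(pre_spikes, post_spikes) {
  if (!length(pre_spikes) || !length(post_spikes)) {
    return(structure(NA_real_,
                     missing = c(pre = !length(pre_spikes),
                                 post = !length(post_spikes))))
  }
  post_spikes[1] - pre_spikes[1]
}

#' Postsynaptic-potential polarity and amplitude
#'
#' Compares a response window to a baseline window of the same trace: the
#' polarity is the sign of the extremal deflection from the baseline mean,
#' the amplitude its absolute size.
#'
#' @param V Voltage trace (mV).
#' @param time Sample times (ms).
#' @param baseline_window,response_window `c(t0, t1)` in ms, inside `time`.
#' @return List with `polarity` (`"depolarizing"`, `"hyperpolarizing"` or
#'   `"none"`) and `amplitude` (mV).
#' @export
psp_metrics <- function(V, time, baseline_window, response_window) {
  inw <- function(w) time >= w[1] & time <= w[2]
  if (!any(inw(baseline_window)) || !any(inw(response_window))) {
    stop("baseline/response window outside the trace")
  }
  base <- mean(V[inw(baseline_window)])
  dev <- V[inw(response_window)] - base
  ext <- dev[which.max(abs(dev))]
  list(polarity = if (abs(ext) < 1e-9) "none"
                  else if (ext > 0) "depolarizing" else "hyperpolarizing",
       amplitude = abs(ext))
}

#' Sequence-propagation metrics and desired-activity validation
#'
#' Computes per-class burst statistics from a simulation and checks them
#' against the desired-network-activity criteria: every RA-projecting
#' neuron fires exactly one burst of 3-6 spikes lasting at most 10 ms, with
#' burst onsets ordered along the chain; X-projecting neurons fire 1-4
#' bursts of 4-9 spikes; interneurons fire densely throughout the motif
#' (at least one spike in every `tonic_window` ms of the active span, with
#' at least two bursts overall).
#'
#' @param result An `hvc_sim` from [simulate()] or [run_motif()].
#' @param net The `hvc_network` the simulation was run on.
#' @param isi_threshold Burst-grouping ISI threshold (ms).
#' @param ra_min_burst Minimum spikes for an RA spike run to count as a
#'   burst in the sequence tally (sub-burst doublets do not carry the
#'   sequence).
#' @param ra_spikes,ra_max_duration,x_bursts,x_spikes Acceptance bounds.
#' @param tonic_window Window (ms) for the interneuron tonicity criterion.
#' @return An object of class `hvc_validation`: per-class tables, summary
#'   statistics, `sequence_complete`, and `break_point` (first chain-order
#'   RA id without a burst, or `NA`).
#' @export
sequence_metrics <- function(result, net, isi_threshold = 15,
                             ra_spikes = c(3, 6), ra_max_duration = 10,
                             ra_min_burst = 3, x_bursts = c(1, 4),
                             x_spikes = c(4, 9), tonic_window = 100) {
  nn <- net$neurons
  spk <- result$spikes
  ord <- chain_order(net)

  ## an RA burst proper has at least `ra_min_burst` spikes (the lower end
  ## of the realistic range); smaller runs are sub-burst doublets, so a
  ## neuron reduced to one is counted as having lost its burst
  ra <- do.call(rbind, lapply(seq_along(ord), function(k) {
    id <- ord[k]
    b <- group_bursts(spk[[id]], isi_threshold, min_spikes = ra_min_burst)$bursts
    data.frame(id = id, chain_rank = k, n_bursts = nrow(b),
               onset = if (nrow(b)) b$onset[1] else NA_real_,
               n_spikes = if (nrow(b)) b$n_spikes[1] else 0L,
               duration = if (nrow(b)) b$duration[1] else NA_real_)
  }))
  ra$ok <- ra$n_bursts == 1 & ra$n_spikes >= ra_spikes[1] &
    ra$n_spikes <= ra_spikes[2] &
    !is.na(ra$duration) & ra$duration <= ra_max_duration

  no_burst <- ra$chain_rank[ra$n_bursts == 0]
  onsets <- ra$onset
  ordered <- all(ra$n_bursts >= 1) && !is.unsorted(onsets, strictly = FALSE)
  sequence_complete <- all(ra$n_bursts == 1) && ordered
  break_point <- if (length(no_burst)) ra$id[ra$chain_rank == min(no_burst)]
                 else NA_integer_

  x_ids <- nn$id[nn$class == "X"]
  xt <- do.call(rbind, lapply(x_ids, function(id) {
    b <- group_bursts(spk[[id]], isi_threshold)$bursts
    data.frame(id = id, n_bursts = nrow(b),
               min_spikes = if (nrow(b)) min(b$n_spikes) else NA_integer_,
               max_spikes = if (nrow(b)) max(b$n_spikes) else NA_integer_)
  }))
  xt$ok <- xt$n_bursts >= x_bursts[1] & xt$n_bursts <= x_bursts[2] &
    !is.na(xt$min_spikes) & xt$min_spikes >= x_spikes[1] &
    xt$max_spikes <= x_spikes[2]

  ## interneuron tonicity over the active span of the motif
  act <- range(c(ra$onset, unlist(spk[ord])), na.rm = TRUE)
  span <- c(min(ra$onset, na.rm = TRUE),
            max(ra$onset + ra$duration, na.rm = TRUE))
  if (!all(is.finite(span))) span <- c(0, max(result$time))
  int_ids <- nn$id[nn$class == "INT"]
  it <- do.call(rbind, lapply(int_ids, function(id) {
    s <- spk[[id]]
    b <- group_bursts(s, isi_threshold)$bursts
    wins <- if (span[2] - span[1] <= tonic_window) numeric(0)
            else seq(span[1], span[2] - tonic_window, by = tonic_window)
    covered <- if (length(wins) < 1) length(s) > 0 else
      all(vapply(wins, function(w)
        any(s >= w & s < w + tonic_window), logical(1)))
    data.frame(id = id, n_spikes = length(s), n_bursts = nrow(b),
               tonic = covered && nrow(b) >= 2)
  }))

  summary <- list(
    ra_burst_duration_mean = mean(ra$duration, na.rm = TRUE),
    ra_burst_duration_sd = stats::sd(ra$duration, na.rm = TRUE),
    ra_burst_spikes_mean = mean(ra$n_spikes[ra$n_bursts >= 1]),
    ra_burst_spikes_sd = stats::sd(ra$n_spikes[ra$n_bursts >= 1]),
    x_bursts_mean = mean(xt$n_bursts),
    x_bursts_range = range(xt$n_bursts),
    int_rate_mean = mean(it$n_spikes) / (diff(span) / 1000)
  )
  structure(list(ra = ra, x = xt, int = it, summary = summary,
                 sequence_complete = sequence_complete,
                 break_point = break_point,
                 all_ra_ok = all(ra$ok), all_x_ok = all(xt$ok),
                 all_int_tonic = all(it$tonic), span = span),
            class = "hvc_validation")
}

#' @export
print.hvc_validation <- function(x, ...) {
  cat("Desired-network-activity report\n")
  cat("  sequence_complete:", x$sequence_complete,
      if (!is.na(x$break_point)) paste0("(break at RA ", x$break_point, ")")
      else "", "\n")
  s <- x$summary
  cat(sprintf("  RA bursts: %.2f +/- %.2f ms, %.2f +/- %.2f spikes (%d/%d ok)\n",
              s$ra_burst_duration_mean, s$ra_burst_duration_sd,
              s$ra_burst_spikes_mean, s$ra_burst_spikes_sd,
              sum(x$ra$ok), nrow(x$ra)))
  cat(sprintf("  X bursts/neuron: %.2f (range %d-%d, %d/%d ok)\n",
              s$x_bursts_mean, s$x_bursts_range[1], s$x_bursts_range[2],
              sum(x$x$ok), nrow(x$x)))
  cat(sprintf("  INT mean rate: %.1f Hz over active span (%d/%d tonic)\n",
              s$int_rate_mean, sum(x$int$tonic), nrow(x$int)))
  invisible(x)
}
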