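#' Simulate a spiking network
#'
#' Clock-driven simulation of the recurrent network under Poisson external
#' drive, with exact integration of the subthreshold dynamics, per-synapse
#' transmission delays (ring buffer), threshold/reset and an absolute
#' refractory period during which synaptic input is shunted.
#'
#' @param net an [build_network()] object.
#' @param drive an [build_drive()] object (per-neuron feedforward plus
#'   shared background intensity).
#' @param neuron an [neuron_params()] object.
#' @param duration simulated time, ms.
#' @param seed integer seed; identical seeds give identical output.
#' @param v_init optional initial potentials (mV). Default: uniform on
#'   \[v_reset, v_th) to suppress startup synchrony (drawn from `seed`).
#' @param record_v integer vector of neuron ids whose membrane potential
#'   is sampled every step (keep small; memory is `n_steps x length`).
#' @param transient initial window (ms) excluded from the rate and
#'   membrane-potential summaries.
#' @return `osnet_spikes` object: list with `events` (data.frame
#'   `id`, `time_ms`, sorted by time), `n_neurons`, `duration`, `dt`,
#'   `rates` (spikes/s per neuron over the post-transient window),
#'   `v_mean` (mean potential per neuron over non-refractory,
#'   post-transient samples), `shunt_rate` (mean rate of synaptic charge
#'   discarded during refractoriness, mV/ms, over the same window),
#'   `vtrace` (matrix, if requested), `window`.
#' @export
simulate_network <- function(net, drive, neuron, duration, seed = 1L,
                             v_init = NULL, record_v = integer(0),
                             transient = 200) {
  stopifnot(inherits(net, "osnet_network"), inherits(drive, "osnet_drive"),
            inherits(neuron, "osnet_neuron"))
  if (duration <= 0) stop("duration must be positive")
  dt <- net$dt
  n <- net$n
  n_steps <- as.integer(round(duration / dt))
  if (length(drive$ffw_rate) != n)
    stop("drive length does not match network size")

  set.seed(as.integer(seed))
  if (is.null(v_init)) {
    v_init <- suppressWarnings(runif(n, neuron$v_reset, neuron$v_th))
    if (!all(is.finite(v_init))) v_init <- rep(neuron$v_reset, n)
  }
  W <- net$weights$W
  res <- sim_core(
    n = n, Wp = W@p, Wi = W@i, Wx = W@x,
    dsteps = net$delay_steps, pif = neuron$model == "PIF",
    decay = if (neuron$model == "LIF") exp(-dt / neuron$tau_m) else 1.0,
    v_rest = neuron$v_rest, v_th = neuron$v_th, v_reset = neuron$v_reset,
    ref_steps = as.integer(round(neuron$tau_ref / dt)),
    lam_ffw = drive$ffw_rate * dt / 1000, j_ffw = drive$j_ffw,
    lam_bkg = drive$bkg_rate * dt / 1000, j_bkg = drive$j_bkg,
    n_steps = n_steps, dt = dt, v0 = v_init,
    rec_ids = as.integer(record_v) - 1L,
    vstat_start = as.integer(round(transient / dt)))

  window <- c(transient, duration)
  keep <- res$time > transient
  counts <- tabulate(res$id[keep], nbins = n)
  structure(list(
    events = data.frame(id = res$id, time_ms = res$time),
    n_neurons = n, duration = duration, dt = dt,
    counts = counts,
    rates = counts / (diff(window) / 1000),
    v_mean = ifelse(res$vcnt > 0, res$vsum / res$vcnt, NA_real_),
    shunt_rate = res$shunt / diff(window),
    vtrace = if (length(record_v)) res$vtrace else NULL,
    record_v = record_v, window = window, seed = as.integer(seed)),
    class = "osnet_spikes")
}

#' @export
print.osnet_spikes <- function(x, ...) {
  cat("osnet spike data:", nrow(x$events), "spikes from", x$n_neurons,
      "neurons over", x$duration, "ms\n")
  cat("  mean rate (post-transient):",
      format(mean(x$rates), digits = 4), "spikes/s\n")
  invisible(x)
}

#' Population peri-stimulus time histogram
#'
#' Binned population rates (spikes/s per neuron), separately per group.
#'
#' @param spikes an `osnet_spikes` object.
#' @param bin bin size, ms.
#' @param groups named list of neuron-id vectors (e.g. excitatory and
#'   inhibitory blocks); defaults to one group with all neurons.
#' @return data.frame with `time_ms` (bin centres) and one rate column per
#'   group.
#' @export
population_psth <- function(spikes, bin, groups = NULL) {
  if (bin <= 0) stop("bin must be positive")
  if (is.null(groups)) groups <- list(all = seq_len(spikes$n_neurons))
  breaks <- seq(0, spikes$duration + bin, by = bin)
  centres <- head(breaks, -1L) + bin / 2
  out <- data.frame(time_ms = centres)
  for (gname in names(groups)) {
    ids <- groups[[gname]]
    ev <- spikes$events$time_ms[spikes$events$id %in% ids]
    cnt <- tabulate(findInterval(ev, breaks, left.open = TRUE),
                    nbins = length(centres))
    out[[gname]] <- cnt / (bin / 1000) / length(ids)
  }
  out
}

#' Write spikes in two-column gdf-style text format
#'
#' `neuron_id time_ms`, whitespace-delimited, sorted by time, no header.
#' @param spikes an `osnet_spikes` object.
#' @param path output file.
#' @export
write_gdf <- function(spikes, path) {
  ev <- spikes$events[order(spikes$events$time_ms, spikes$events$id), ]
  utils::write.table(format(ev, scientific = FALSE, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gdf-style spike file
#' @param path file written by [write_gdf()].
#' @param n_neurons,duration metadata not stored in the text format.
#' @return `osnet_spikes`-like list (events only plus metadata).
#' @export
read_gdf <- function(path, n_neurons = NA_integer_, duration = NA_real_) {
  df <- utils::read.table(path, col.names = c("id", "time_ms"))
  structure(list(events = df, n_neurons = n_neurons, duration = duration),
            class = "osnet_spikes")
}
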