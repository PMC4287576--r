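# Tuning curves and circular selectivity statistics.  Orientation is a
# 180-degree-periodic variable, so all circular statistics work on the
# doubled angle 2*theta.

#' Extract tuning curves from per-orientation spike data
#'
#' @param spikes_by_theta named list of `osnet_spikes`, one per stimulus
#'   orientation; names are orientations in degrees.
#' @param window `(t_start, t_end)` ms; spikes before `t_start` (onset
#'   transient) are discarded.
#' @return matrix `n_neurons x n_theta` of rates (spikes/s), with
#'   orientations (degrees) as column names.
#' @export
extract_tuning_curves <- function(spikes_by_theta, window = NULL) {
  thetas <- as.numeric(names(spikes_by_theta))
  if (any(is.na(thetas)))
    stop("spikes_by_theta must be named by orientation (degrees)")
  n <- spikes_by_theta[[1]]$n_neurons
  curves <- vapply(spikes_by_theta, function(sp) {
    if (sp$n_neurons != n) stop("mismatched network sizes across orientations")
    win <- if (is.null(window)) sp$window else window
    if (win[2] > sp$duration) stop("window exceeds simulation duration")
    ev <- sp$events
    keep <- ev$time_ms > win[1] & ev$time_ms <= win[2]
    tabulate(ev$id[keep], nbins = n) / (diff(win) / 1000)
  }, numeric(n))
  colnames(curves) <- names(spikes_by_theta)
  curves
}

#' Orientation selectivity index and preferred orientation
#'
#' Circular-resultant statistics of a tuning curve at doubled angles:
#' `OSI = |sum_k r_k exp(2 i theta_k)| / sum_k r_k`, and the PO is half
#' the resultant angle, mapped to \[0, 180).
#'
#' @param rates rates per orientation (one curve), or a matrix with one
#'   row per neuron.
#' @param theta orientation grid, degrees.
#' @return data.frame with columns `osi` and `po` (degrees); `NA` for
#'   all-zero curves.
#' @export
osi_po <- function(rates, theta) {
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
  if (ncol(rates) != length(theta))
    stop("rates and theta grid have different lengths")
  z <- rates %*% exp(2i * theta * pi / 180)
  tot <- rowSums(rates)
  osi <- ifelse(tot > 0, Mod(z) / tot, NA_real_)
  po <- ifelse(tot > 0, (Arg(z) * 180 / pi / 2) %% 180, NA_real_)
  po[!is.na(po) & po > 180 - 1e-9] <- 0
  data.frame(osi = as.numeric(osi), po = as.numeric(po))
}

#' Baseline (F0) and modulation (F2) components
#'
#' `F0` is the mean rate; `F2` is the amplitude of the second Fourier
#' harmonic over orientation, with the convention that a curve
#' `r = F0 + F2 cos(2 (theta - phi))` is recovered exactly, so
#' `OSI = F2 / (2 F0)` holds identically for positive curves.
#'
#' @inheritParams osi_po
#' @return data.frame with columns `f0` and `f2` (spikes/s).
#' @export
f0_f2 <- function(rates, theta) {
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
  if (ncol(rates) != length(theta))
    stop("rates and theta grid have different lengths")
  f0 <- rowMeans(rates)
  z <- rates %*% exp(2i * theta * pi / 180)
  f2 <- (2 / ncol(rates)) * Mod(z)
  data.frame(f0 = as.numeric(f0), f2 = as.numeric(f2))
}

#' Circular difference of preferred orientations
#'
#' 180-degree-periodic difference `po_out - po_in`, mapped to
#' \[-90, 90) (the +/-90 ambiguity maps to -90).
#'
#' @param po_out,po_in orientations in degrees.
#' @return difference in degrees.
#' @export
dpo <- function(po_out, po_in) {
  ((po_out - po_in + 90) %% 180) - 90
}

#' Sharpening coefficient
#'
#' Ratio of output to input tuning width; values below 1 indicate
#' sharpening of the output tuning curve relative to its input.
#'
#' @param tw_out,tw_in tuning widths in degrees; `tw_in` must be > 0.
#' @return dimensionless ratio.
#' @export
sharpening_coefficient <- function(tw_out, tw_in) {
  if (any(tw_in <= 0)) stop("tw_in must be positive")
  tw_out / tw_in
}

#' Coefficient of variation of inter-spike intervals
#'
#' @param spikes an `osnet_spikes` object.
#' @param min_spikes neurons with fewer spikes (in the post-transient
#'   window) are excluded.
#' @param window optional `(t_start, t_end)` ms; defaults to the spike
#'   object's post-transient window.
#' @return named numeric vector of CV values, one per qualifying neuron.
#' @export
cv_isi <- function(spikes, min_spikes = 10L, window = NULL) {
  if (min_spikes < 2) stop("min_spikes must be at least 2")
  win <- if (is.null(window)) spikes$window else window
  ev <- spikes$events
  ev <- ev[ev$time_ms > win[1] & ev$time_ms <= win[2], ]
  out <- vapply(split(ev$time_ms, ev$id), function(tt) {
    if (length(tt) < min_spikes) return(NA_real_)
    isi <- diff(sort(tt))
    sd(isi) / mean(isi)
  }, numeric(1))
  out[!is.na(out)]
}

#' Normalize tuning curves
#'
#' Per-curve division by the mean or the maximum, optionally after
#' subtracting each neuron's spontaneous rate (clipped at zero).
#'
#' @param curves matrix `n_neurons x n_theta`.
#' @param mode `"mean"` or `"max"`.
#' @param subtract_spont subtract `spont` before normalizing.
#' @param spont per-neuron spontaneous rates (spikes/s).
#' @return normalized matrix; curves with a non-positive denominator are
#'   set to `NA` (flagged missing).
#' @export
normalize_tuning <- function(curves, mode = c("mean", "max"),
                             subtract_spont = FALSE, spont = NULL) {
  mode <- match.arg(mode)
  if (subtract_spont) {
    if (is.null(spont)) stop("spont rates required for subtraction")
    curves <- pmax(curves - spont, 0)
  }
  denom <- if (mode == "mean") rowMeans(curves) else
    apply(curves, 1, max)
  bad <- !(denom > 0)
  out <- curves / denom
  out[bad, ] <- NA_real_
  out
}

#' Population-average tuning curve aligned to preferred orientations
#'
#' Circularly shifts each neuron's tuning curve so that the grid point
#' nearest its preferred orientation moves to the first column, then
#' averages across neurons. Optionally subtracts each neuron's
#' spontaneous rate (clipped at zero) first — the standard procedure
#' before comparing tuning-curve shapes across contrasts.
#'
#' @param curves matrix `n_neurons x n_theta` (uniform grid over 180
#'   degrees, ascending, starting at 0).
#' @param po per-neuron preferred orientations (degrees) to align on,
#'   e.g. the input POs.
#' @param subtract_spont,spont optional spontaneous-rate subtraction.
#' @return numeric vector of length `n_theta`: the mean aligned curve
#'   (first entry = preferred orientation).
#' @export
aligned_population_curve <- function(curves, po, subtract_spont = FALSE,
                                     spont = NULL) {
  if (subtract_spont) {
    if (is.null(spont)) stop("spont rates required for subtraction")
    curves <- pmax(curves - spont, 0)
  }
  n_th <- ncol(curves)
  shift <- round(po / (180 / n_th)) %% n_th
  aligned <- vapply(seq_len(nrow(curves)), function(i) {
    idx <- ((seq_len(n_th) - 1 + shift[i]) %% n_th) + 1
    curves[i, idx]
  }, numeric(n_th))
  rowMeans(aligned)
}

#' Reset-corrected (free) membrane potential
#'
#' Corrects a measured mean membrane potential for the net
#' hyperpolarization caused by the post-spike reset. Averaging the
#' subthreshold dynamics over non-refractory times and balancing the
#' reset flux gives
#' `v_free = v_rest + (1 - x)(v_meas - v_rest) + tau_m ((v_th - v_reset) * r + L)`
#' with `r` the rate (per ms), `x = r * tau_ref` the refractory time
#' fraction, and `L` the mean rate of synaptic charge shunted away during
#' refractory periods (mV/ms, reported as `shunt_rate` by
#' [simulate_network()]). For `tau_ref = 0` (or `shunted = 0` and low
#' rates) this reduces to the plain correction
#' `v_meas + tau_m * (v_th - v_reset) * rate`.
#'
#' @param v_mean_measured measured time-averaged potential (mV), taken
#'   over non-refractory times (`v_mean` of [simulate_network()]).
#' @param rate firing rate(s), spikes/s.
#' @param neuron an [neuron_params()] object (LIF).
#' @param shunted mean shunted-charge rate (mV/ms); 0 if not accounted.
#' @return free membrane potential estimate (mV).
#' @export
free_membrane_potential <- function(v_mean_measured, rate, neuron,
                                    shunted = 0) {
  r_ms <- rate / 1000
  x <- r_ms * neuron$tau_ref
  neuron$v_rest + (1 - x) * (v_mean_measured - neuron$v_rest) +
    neuron$tau_m * ((neuron$v_th - neuron$v_reset) * r_ms + shunted)
}

#' Reconstruct the free membrane potential from the net input
#'
#' The mean free potential implied by the input moments:
#' `v_rec = v_rest + tau_m (j_bkg s_bkg + j_ffw s_i + sum_j W_ij r_j)` —
#' identical to the `mu` component of [input_moments()].
#'
#' @inheritParams input_moments
#' @return per-neuron potential (mV).
#' @export
reconstruct_free_potential <- function(net, rates, drive, neuron) {
  input_moments(net, rates, drive, neuron)$mu
}
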