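#' Stimulus configuration
#'
#' The external drive to every neuron has two parts: a stimulus-independent
#' background Poisson process (total rate `s_bkg`, efficacy `j_bkg`) and a
#' stimulus-driven feedforward Poisson process whose intensity depends on
#' contrast and on the angle between the stimulus orientation and the
#' neuron's input preferred orientation (PO).
#'
#' @param m input modulation ratio in \[0, 1\]: the fraction of the
#'   feedforward input that is tuned.
#' @param s_max maximal total feedforward baseline rate (spikes/s), reached
#'   at contrast 1.
#' @param s_bkg total background rate (spikes/s).
#' @param j_ffw,j_bkg feedforward / background PSP efficacies (mV).
#' @param contrasts strictly increasing contrast values in (0, 1].
#' @param n_theta number of stimulus orientations on the uniform grid over
#'   \[0, 180) degrees.
#' @return `osnet_stimulus` object.
#' @export
stimulus_config <- function(m = 0.1, s_max = 30000, s_bkg = 15000,
                            j_ffw = 0.1, j_bkg = 0.1,
                            contrasts = c(1 / 3, 2 / 3, 1),
                            n_theta = 12L) {
  if (m < 0 || m > 1) stop("modulation ratio m must lie in [0, 1]")
  if (s_max <= 0) stop("s_max must be positive")
  if (s_bkg < 0) stop("s_bkg must be non-negative")
  if (any(contrasts <= 0) || any(contrasts > 1) ||
      is.unsorted(contrasts, strictly = TRUE))
    stop("contrasts must be strictly increasing values in (0, 1]")
  if (n_theta < 2) stop("need at least 2 stimulus orientations")
  structure(list(m = m, s_max = s_max, s_bkg = s_bkg,
                 j_ffw = j_ffw, j_bkg = j_bkg,
                 contrasts = contrasts, n_theta = as.integer(n_theta)),
            class = "osnet_stimulus")
}

#' Orientation grid of a stimulus configuration
#' @param stim an `osnet_stimulus`.
#' @return orientations in degrees, uniform on \[0, 180).
#' @export
theta_grid <- function(stim) {
  n <- if (inherits(stim, "osnet_stimulus")) stim$n_theta else as.integer(stim)
  seq(0, 180, length.out = n + 1L)[seq_len(n)]
}

#' Contrast-dependent feedforward baseline
#'
#' Linear map `s_b = s_max * C`; the default contrasts `{1/3, 2/3, 1}`
#' span a three-fold range of baseline intensity.
#'
#' @param C contrast in \[0, 1\].
#' @param s_max maximal baseline rate (spikes/s).
#' @return baseline rate in spikes/s.
#' @export
contrast_baseline <- function(C, s_max) {
  if (any(C < 0) || any(C > 1)) stop("contrast must lie in [0, 1]")
  s_max * C
}

#' Orientation-tuned feedforward intensity
#'
#' `s = s_b * (1 + m * cos(2 * (theta - po)))`, 180-degree periodic in
#' both angles and non-negative for `m <= 1`.
#'
#' @param po input preferred orientation(s), degrees.
#' @param theta stimulus orientation, degrees.
#' @param s_b baseline rate (spikes/s).
#' @param m modulation ratio in \[0, 1\].
#' @return feedforward rate(s), spikes/s.
#' @export
feedforward_rate <- function(po, theta, s_b, m) {
  if (m < 0 || m > 1)
    stop("modulation ratio m outside [0, 1] would produce negative rates")
  s_b * (1 + m * cos(2 * (theta - po) * pi / 180))
}

#' Per-neuron external drive for one stimulus condition
#'
#' @param pos per-neuron input POs (degrees).
#' @param theta stimulus orientation (degrees); ignored when
#'   `evoked = FALSE`.
#' @param C contrast; ignored when `evoked = FALSE`.
#' @param stim an [stimulus_config()] object.
#' @param evoked if `FALSE`, the spontaneous condition: feedforward
#'   intensities are identically zero and only the background remains.
#' @return `osnet_drive`: list with `ffw_rate` (per neuron, spikes/s),
#'   `bkg_rate` (shared scalar), efficacies, `theta`, `contrast`.
#' @export
build_drive <- function(pos, theta = 0, C = 1, stim = stimulus_config(),
                        evoked = TRUE) {
  ffw <- if (evoked) {
    s_b <- contrast_baseline(C, stim$s_max)
    feedforward_rate(pos, theta, s_b, stim$m)
  } else {
    rep(0, length(pos))
  }
  structure(list(ffw_rate = ffw, bkg_rate = stim$s_bkg,
                 j_ffw = stim$j_ffw, j_bkg = stim$j_bkg,
                 theta = if (evoked) theta else NA_real_,
                 contrast = if (evoked) C else NA_real_,
                 evoked = evoked),
            class = "osnet_drive")
}

#' Input tuning curves implied by a stimulus configuration
#'
#' The feedforward intensity of each neuron across the orientation grid:
#' the reference against which output sharpening is measured.
#'
#' @inheritParams build_drive
#' @return matrix `length(pos) x n_theta` of rates (spikes/s).
#' @export
input_tuning_curves <- function(pos, C = 1, stim = stimulus_config()) {
  thetas <- theta_grid(stim)
  s_b <- contrast_baseline(C, stim$s_max)
  vapply(thetas, function(th) feedforward_rate(pos, th, s_b, stim$m),
         numeric(length(pos)))
}
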