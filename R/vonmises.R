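# Von Mises tuning-curve fits and the tuning-width statistic.

#' Von Mises tuning function
#'
#' `A * exp(kappa * cos(2 * (theta - phi)))` with orientation in degrees.
#'
#' @param theta orientations (degrees).
#' @param A amplitude (spikes/s), `kappa` concentration, `phi` preferred
#'   orientation (degrees).
#' @export
von_mises <- function(theta, A, kappa, phi) {
  A * exp(kappa * cos(2 * (theta - phi) * pi / 180))
}

#' Fit a von Mises function to a tuning curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of the 3-parameter
#' von Mises model, multi-started over the preferred orientation around
#' the circular-resultant PO. The error index is the RMS residual as a
#' percentage of the curve's mean rate. Deterministic given the curve.
#'
#' @param rates rates per orientation (one curve).
#' @param theta orientation grid, degrees (>= 4 points).
#' @return list with `A`, `kappa`, `phi` (degrees in \[0, 180)),
#'   `error_index` (percent) and `flag` (`"ok"`, `"zero"` for all-zero
#'   curves, `"flat"` for unidentifiable phi, `"failed"` when the
#'   optimizer did not converge from any start).
#' @export
fit_von_mises <- function(rates, theta) {
  if (length(theta) < 4) stop("need at least 4 grid points")
  if (length(rates) != length(theta))
    stop("rates and theta grid have different lengths")
  if (all(rates == 0))
    return(list(A = NA_real_, kappa = NA_real_, phi = NA_real_,
                error_index = NA_real_, flag = "zero"))
  st <- osi_po(rates, theta)
  if (!is.na(st$osi) && st$osi < 1e-10) {
    # flat curve: A is the mean, phi unidentifiable
    return(list(A = mean(rates), kappa = 0, phi = NA_real_,
                error_index = 100 * sqrt(mean((rates - mean(rates))^2)) /
                  mean(rates), flag = "flat"))
  }
  kappa0 <- max(2 * st$osi, 1e-3)
  best <- NULL
  for (phi0 in st$po + c(0, -30, 30)) {
    A0 <- mean(rates) / besselI(kappa0, 0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ A * exp(kappa * cos(2 * (th - phi) * pi / 180)),
        data = data.frame(r = rates, th = theta),
        start = list(A = A0, kappa = kappa0, phi = phi0),
        lower = c(A = 0, kappa = 0, phi = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(list(A = NA_real_, kappa = NA_real_, phi = NA_real_,
                error_index = NA_real_, flag = "failed"))
  p <- stats::coef(best$fit)
  list(A = unname(p["A"]), kappa = unname(p["kappa"]),
       phi = unname(p["phi"]) %% 180,
       error_index = 100 * sqrt(best$rss / length(rates)) / mean(rates),
       flag = "ok")
}

#' Tuning width of a fitted von Mises curve
#'
#' Half width at half height between the fitted curve's minimum and
#' maximum: `tw = (1/2) * acos(ln(cosh kappa) / kappa)` in degrees,
#' defined by continuity as 45 degrees at `kappa = 0` (the unrectified
#' cosine limit). Strictly decreasing in `kappa`, with range (0, 45\].
#'
#' @param kappa von Mises concentration (>= 0); vectorized.
#' @return tuning width, degrees.
#' @export
tuning_width <- function(kappa) {
  if (any(kappa < 0, na.rm = TRUE)) stop("kappa must be non-negative")
  # log(cosh(k)) = k - log(2) + log1p(exp(-2k)), stable for large k
  lch <- ifelse(kappa > 20, kappa - log(2) + log1p(exp(-2 * kappa)),
                log(cosh(kappa)))
  ratio <- ifelse(kappa == 0, 0, lch / kappa)
  0.5 * acos(pmin(1, pmax(-1, ratio))) * 180 / pi
}

#' Selectivity statistics for a set of tuning curves
#'
#' Per-neuron OSI, PO, von Mises fit, tuning width, F0/F2 and (when input
#' POs are supplied) dPO and the sharpening coefficient relative to the
#' input tuning width.
#'
#' @param curves matrix `n_neurons x n_theta` of rates (spikes/s).
#' @param theta orientation grid, degrees.
#' @param po_in optional per-neuron input POs (degrees).
#' @param tw_in optional input tuning width (degrees) for the sharpening
#'   coefficient; scalar or per-neuron.
#' @param max_error_index fits with a larger error index (percent) are
#'   flagged `"excluded"` and their fit-derived statistics set to `NA`.
#' @return data.frame, one row per neuron.
#' @export
tuning_stats <- function(curves, theta, po_in = NULL, tw_in = NULL,
                         max_error_index = 5) {
  st <- osi_po(curves, theta)
  ff <- f0_f2(curves, theta)
  fits <- lapply(seq_len(nrow(curves)), function(i)
    fit_von_mises(curves[i, ], theta))
  out <- data.frame(
    neuron = seq_len(nrow(curves)),
    osi = st$osi, po = st$po, f0 = ff$f0, f2 = ff$f2,
    A = vapply(fits, `[[`, numeric(1), "A"),
    kappa = vapply(fits, `[[`, numeric(1), "kappa"),
    phi = vapply(fits, `[[`, numeric(1), "phi"),
    error_index = vapply(fits, `[[`, numeric(1), "error_index"),
    flag = vapply(fits, `[[`, character(1), "flag"))
  excl <- !is.na(out$error_index) & out$error_index > max_error_index &
    out$flag == "ok"
  out$flag[excl] <- "excluded"
  out$tw <- ifelse(out$flag %in% c("ok"), tuning_width(pmax(out$kappa, 0)),
                   NA_real_)
  if (!is.null(po_in)) out$dpo <- dpo(out$po, po_in)
  if (!is.null(tw_in)) out$sc <- out$tw / tw_in
  out
}
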