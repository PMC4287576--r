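# Mean-field prediction of per-neuron stationary rates.
#
# Under stationarity, a PIF neuron's mean drift must balance the reset
# flux: (v_th - v_reset) * r_i = sum_j W_ij r_j + h_i, with h_i the
# external drive in mV/s.  The linear layer solves this exactly; the
# rectified layer solves the same equation with negative rates clamped to
# zero (silent neurons stop contributing to the recurrent field); the LIF
# layer replaces the threshold-linear transfer by the Siegert
# first-passage function of the input moments.

# External drive field in mV/s per neuron.
drive_field <- function(drive) {
  drive$j_ffw * drive$ffw_rate + drive$j_bkg * drive$bkg_rate
}

#' Refractory-period rate correction
#'
#' Converts the rate of the refractoriness-free model into the rate with
#' an absolute refractory period during which input is shunted:
#' `r' = r / (1 + r * tau_ref)`, bounded above by `1/tau_ref`.
#' Non-positive rates are returned unchanged.
#'
#' @param r rate(s), spikes/s.
#' @param tau_ref refractory period, ms.
#' @return corrected rate(s), spikes/s.
#' @export
refractory_correction <- function(r, tau_ref) {
  if (tau_ref < 0) stop("tau_ref must be non-negative")
  ifelse(r > 0, r / (1 + r * tau_ref / 1000), r)
}

# Power-iteration estimate of the spectral radius of W / (v_th - v_reset).
spectral_radius <- function(W, dv, iter = 100L, seed = 1L) {
  n <- nrow(W)
  set.seed(as.integer(seed))
  v <- rnorm(n)
  v <- v / sqrt(sum(v^2))
  rho <- 0
  for (k in seq_len(iter)) {
    w <- as.numeric(W %*% v) / dv
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    rho <- nw
    v <- w / nw
  }
  rho
}

#' Linear stationary rates
#'
#' Solves `(v_th - v_reset) r = W r + h` for the full rate vector, then
#' applies the refractory correction. Negative solutions are allowed and
#' reported as such: this layer does not rectify (the raw solution is
#' attached as `attr(, "raw")`, in spikes/s, uncorrected).
#'
#' @param net an [build_network()] object.
#' @param drive an [build_drive()] object.
#' @param neuron an [neuron_params()] object.
#' @param check_stability estimate the spectral radius of
#'   `W / (v_th - v_reset)` by power iteration and error if >= 1.
#' @return per-neuron rates, spikes/s.
#' @export
linear_rates <- function(net, drive, neuron, check_stability = TRUE) {
  dv <- neuron$v_th - neuron$v_reset
  W <- net$weights$W
  if (check_stability && spectral_radius(W, dv) >= 1)
    stop("spectral radius of W/(v_th - v_reset) >= 1: ",
         "no stable stationary solution")
  h <- drive_field(drive)
  r <- as.numeric(Matrix::solve(dv * Diagonal(net$n) - W, h))
  out <- refractory_correction(r, neuron$tau_ref)
  attr(out, "raw") <- r
  out
}

new_solver_trace <- function(residual, converged, tol) {
  structure(list(iterations = length(residual), residual = residual,
                 converged = converged, tol = tol),
            class = "osnet_solver_trace")
}

#' @export
print.osnet_solver_trace <- function(x, ...) {
  cat("solver trace:", x$iterations, "iterations; final residual",
      format(x$residual[length(x$residual)], digits = 4),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' Rectified (threshold-linear) fixed point
#'
#' Damped Picard iteration for `r = max(0, (W r + h) / (v_th - v_reset))`:
#' silent neurons are removed from the recurrent field self-consistently.
#' After convergence the active set is polished by one exact linear solve
#' on its support, and the refractory correction is applied.
#'
#' @inheritParams linear_rates
#' @param tol convergence tolerance: RMS of successive iterates, spikes/s.
#' @param max_iter iteration cap; exceeding it raises an error carrying
#'   the residual trace.
#' @param damping Picard damping `alpha` in (0, 1]:
#'   `r <- (1 - alpha) r + alpha G(r)`. Must satisfy
#'   `alpha < 2 / (1 + |lambda_min|)` for the common-mode eigenvalue of
#'   `W/(v_th - v_reset)` in inhibition-dominated networks.
#' @param polish solve the linear system restricted to the converged
#'   active set (exact rates, residual at machine precision).
#' @return list with `rates` (spikes/s, refractory-corrected), `raw`
#'   (uncorrected fixed point), and `trace` (an `osnet_solver_trace`).
#' @export
rectified_fixed_point <- function(net, drive, neuron, tol = 1e-6,
                                  max_iter = 10000L, damping = 0.5,
                                  polish = TRUE) {
  if (tol <= 0) stop("tol must be positive")
  if (damping <= 0 || damping > 1) stop("damping must lie in (0, 1]")
  dv <- neuron$v_th - neuron$v_reset
  W <- net$weights$W
  h <- drive_field(drive)
  r <- numeric(net$n)
  res <- numeric(0)
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    g <- pmax(0, (as.numeric(W %*% r) + h) / dv)
    r_new <- (1 - damping) * r + damping * g
    rms <- sqrt(mean((r_new - r)^2))
    res <- c(res, rms)
    r <- r_new
    if (rms <= tol) { converged <- TRUE; break }
  }
  trace <- new_solver_trace(res, converged, tol)
  if (!converged) {
    cond <- structure(
      class = c("osnet_nonconvergence", "error", "condition"),
      list(message = paste0("rectified fixed point did not reach tol = ",
                            tol, " within ", max_iter, " iterations"),
           call = sys.call(), trace = trace))
    stop(cond)
  }
  if (polish) {
    act <- (as.numeric(W %*% r) + h) > 0
    if (any(act)) {
      A <- dv * Diagonal(sum(act)) - W[act, act, drop = FALSE]
      rp <- as.numeric(Matrix::solve(A, h[act]))
      if (all(rp >= 0)) {
        r <- numeric(net$n)
        r[act] <- rp
      }
    }
  }
  list(rates = refractory_correction(r, neuron$tau_ref), raw = r,
       trace = trace)
}

#' First two moments of the free membrane potential
#'
#' Under the diffusion approximation with uncorrelated Poissonian input
#' spike trains and instantaneous PSPs:
#' `mu_i = v_rest + tau_m (sum_j W_ij r_j + j_ffw s_i + j_bkg s_bkg)` and
#' `sigma_i^2 = (tau_m / 2)(sum_j W_ij^2 r_j + j_ffw^2 s_i + j_bkg^2 s_bkg)`
#' with rates in per-ms units consistent with `tau_m` in ms.
#'
#' @inheritParams linear_rates
#' @param rates per-neuron rates, spikes/s.
#' @return list with components `mu` and `sigma` (mV).
#' @export
input_moments <- function(net, rates, drive, neuron) {
  if (any(rates < 0)) stop("rates must be non-negative")
  r_ms <- rates / 1000
  sf <- drive$ffw_rate / 1000
  sb <- drive$bkg_rate / 1000
  mu <- neuron$v_rest + neuron$tau_m *
    (as.numeric(net$weights$W %*% r_ms) + drive$j_ffw * sf +
       drive$j_bkg * sb)
  s2 <- (neuron$tau_m / 2) *
    (as.numeric(net$weights$W2 %*% r_ms) + drive$j_ffw^2 * sf +
       drive$j_bkg^2 * sb)
  list(mu = mu, sigma = sqrt(s2))
}

#' LIF transfer-function fixed point
#'
#' Damped Picard iteration for `r_i = F(mu_i(r), sigma_i(r))`, where `F`
#' is the Siegert first-passage rate ([siegert_rate()], which carries the
#' refractory period natively) and the moments follow [input_moments()].
#'
#' @inheritParams rectified_fixed_point
#' @param lookup optional [siegert_table()] for interpolated transfer
#'   evaluation (must bracket all (mu, sigma) encountered), or `"auto"`:
#'   after a short direct-evaluation warm-up the solver builds a table
#'   spanning the observed moment ranges (padded) and switches to it.
#' @param lookup_fallback if `TRUE`, values outside the lookup grid fall
#'   back to direct evaluation instead of raising an error.
#' @return list with `rates` (spikes/s), `moments` (at the fixed point),
#'   `trace`, and `lookup` (the table, when one was supplied or built).
#' @export
lif_fixed_point <- function(net, drive, neuron, tol = 1e-6,
                            max_iter = 10000L, damping = 0.5,
                            lookup = NULL, lookup_fallback = FALSE) {
  if (neuron$model != "LIF")
    stop("lif_fixed_point requires an LIF neuron model")
  if (tol <= 0) stop("tol must be positive")
  if (damping <= 0 || damping > 1) stop("damping must lie in (0, 1]")
  auto <- identical(lookup, "auto")
  if (auto) lookup <- NULL
  warmup <- if (auto) 25L else 0L
  mu_rng <- c(Inf, -Inf)
  sg_rng <- c(Inf, -Inf)
  Fx <- function(mom) {
    if (is.null(lookup)) siegert_rate(mom$mu, mom$sigma, neuron)
    else siegert_interp(lookup, mom$mu, mom$sigma, fallback = lookup_fallback)
  }
  r <- numeric(net$n)
  res <- numeric(0)
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    mom <- input_moments(net, r, drive, neuron)
    if (auto && is.null(lookup)) {
      mu_rng <- c(min(mu_rng[1], mom$mu), max(mu_rng[2], mom$mu))
      sg_rng <- c(min(sg_rng[1], mom$sigma), max(sg_rng[2], mom$sigma))
      if (k >= warmup) {
        lookup <- siegert_table(
          neuron,
          mu_range = mu_rng + c(-15, 15),
          sigma_range = c(max(1e-3, 0.3 * sg_rng[1]), 2 * sg_rng[2] + 1e-3),
          n_mu = 240L, n_sigma = 120L)
        lookup_fallback <- TRUE
      }
    }
    r_new <- (1 - damping) * r + damping * Fx(mom)
    rms <- sqrt(mean((r_new - r)^2))
    res <- c(res, rms)
    r <- r_new
    if (rms <= tol) { converged <- TRUE; break }
  }
  trace <- new_solver_trace(res, converged, tol)
  if (!converged) {
    cond <- structure(
      class = c("osnet_nonconvergence", "error", "condition"),
      list(message = paste0("LIF fixed point did not reach tol = ", tol,
                            " within ", max_iter, " iterations"),
           call = sys.call(), trace = trace))
    stop(cond)
  }
  list(rates = r, moments = input_moments(net, r, drive, neuron),
       trace = trace, lookup = lookup)
}
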