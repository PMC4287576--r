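# Shared builders for small test networks and drives.

tiny_net <- function(n_exc = 40, n_inh = 10, k_exc = 8, k_inh = 2,
                     j_epsp = 0.2, g = 4, seed = 11L, dt = 0.1,
                     delays = delay_spec("uniform", d_min = 0.5, d_max = 3)) {
  build_network(n_exc, n_inh, k_exc, k_inh, j_epsp = j_epsp, g = g,
                delays = delays, dt = dt,
                seed_topology = seed, seed_po = seed + 1L,
                seed_delays = seed + 2L)
}

# one isolated neuron with signed two-channel Poisson drive realising
# prescribed membrane-potential moments (mu, sigma) for an LIF neuron
moment_drive <- function(mu, sigma, neuron, j = 0.1) {
  stopifnot(neuron$model == "LIF")
  s_diff <- (mu - neuron$v_rest) / (neuron$tau_m * j)       # per ms
  s_sum <- 2 * sigma^2 / (neuron$tau_m * j^2)               # per ms
  s_plus <- (s_sum + s_diff) / 2
  s_minus <- (s_sum - s_diff) / 2
  stopifnot(s_plus >= 0, s_minus >= 0)
  structure(list(ffw_rate = s_plus * 1000, bkg_rate = s_minus * 1000,
                 j_ffw = j, j_bkg = -j, theta = NA, contrast = NA,
                 evoked = TRUE),
            class = "osnet_drive")
}

flat_drive <- function(n, rate_ffw = 0, rate_bkg = 0, j_ffw = 0.1,
                       j_bkg = 0.1) {
  structure(list(ffw_rate = rep(rate_ffw, n), bkg_rate = rate_bkg,
                 j_ffw = j_ffw, j_bkg = j_bkg, theta = NA, contrast = NA,
                 evoked = TRUE),
            class = "osnet_drive")
}

# brute-force oracle for the rectified fixed point: enumerate all 2^N
# active sets, solve the linear system on each support, keep the
# feasible solution (positive rates on the support, non-positive net
# input off it)
rectified_oracle <- function(W, h, dv) {
  n <- length(h)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    act <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    r <- numeric(n)
    if (any(act)) {
      A <- dv * diag(sum(act)) - W[act, act, drop = FALSE]
      sol <- tryCatch(solve(A, h[act]), error = function(e) NULL)
      if (is.null(sol) || any(sol < 0)) next
      r[act] <- sol
    }
    resid <- as.numeric(W %*% r) + h
    if (all(resid[!act] <= 1e-9) && all(r[act] > -1e-12)) {
      best <- r
      break
    }
  }
  best
}
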