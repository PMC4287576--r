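# Siegert first-passage-time transfer function for the LIF neuron under
# Gaussian white-noise input with mean mu and stationary free-potential
# standard deviation sigma:
#
#   1 / r = tau_ref + tau_m * sqrt(pi) *
#           integral_{y(v_reset)}^{y(v_th)} exp(u^2) (1 + erf u) du,
#   y(V) = (V - mu) / (sqrt(2) * sigma)
#
# (sqrt(2)*sigma is the diffusion scale of the underlying OU process,
# whose stationary variance is sigma^2 under the tau_m/2 prefactor of
# the input moments; validated against single-neuron Monte Carlo.)
#
# The integrand equals erfcx(-u) (scaled complementary error function),
# which is evaluated without overflow for u < 0; for u > 0 the identity
# erfcx(-u) = 2 exp(u^2) - erfcx(u) splits off the exactly integrable
# exp(u^2) part (via erfi), leaving only smooth, bounded integrands for
# the fixed-order Gauss-Legendre rule.

.osnet_env <- new.env(parent = emptyenv())

gl_nodes <- function(k = 40L) {
  key <- paste0("gl", k)
  if (is.null(.osnet_env[[key]]))
    .osnet_env[[key]] <- pracma::gaussLegendre(k, -1, 1)
  .osnet_env[[key]]
}

# erfcx(x) = exp(x^2) erfc(x) for x >= 0.  pracma's implementation
# overflows beyond x ~ 26.6; switch to the asymptotic expansion
# 1/(x sqrt(pi)) * (1 - 1/(2x^2) + 3/(4x^4) - 15/(8x^6) + 105/(16x^8))
# there (relative error < 1e-11 at the switch point).
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  big <- x > 25
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    z <- 1 / x[big]^2
    out[big] <- 1 / (x[big] * sqrt(pi)) *
      (1 + z * (-1 / 2 + z * (3 / 4 + z * (-15 / 8 + z * 105 / 16))))
  }
  out
}

# Vectorised integral of erfcx(t) over [lo_i, hi_i], lo, hi >= 0.
# Gauss-Legendre panel on [lo, min(hi, 2)] (curvature ~ O(1) near 0);
# the slowly decaying ~ 1/(t sqrt(pi)) tail is integrated in log space,
# where the transformed integrand is nearly constant, so a fixed-order
# rule stays accurate over arbitrarily wide ranges.
int_erfcx <- function(lo, hi, k = 40L) {
  gl <- gl_nodes(k)
  panel <- function(a, b, f) {
    h <- (b - a) / 2
    mid <- (b + a) / 2
    tt <- outer(h, gl$x) + mid            # n x k
    fv <- matrix(f(as.numeric(tt)), nrow = length(a))
    drop(fv %*% gl$w) * h
  }
  m <- pmax(pmin(hi, 2), lo)
  out <- panel(lo, m, erfcx_safe)
  tail <- hi > m
  if (any(tail)) {
    out[tail] <- out[tail] +
      panel(log(m[tail]), log(hi[tail]),
            function(s) erfcx_safe(exp(s)) * exp(s))
  }
  out
}

#' Stationary LIF firing rate under Gaussian white-noise input
#'
#' Mean first-passage rate of the LIF diffusion with input mean `mu` and
#' fluctuation scale `sigma` (both mV), including the absolute refractory
#' period. Continuous in `(mu, sigma)`; the `sigma = 0` limit is the
#' deterministic LIF rate (zero below threshold).
#'
#' @param mu,sigma input mean and standard deviation of the free membrane
#'   potential (mV); vectors are recycled to a common length.
#' @param neuron an [neuron_params()] object with `model = "LIF"`.
#' @return firing rate(s) in spikes/s.
#' @export
siegert_rate <- function(mu, sigma, neuron) {
  if (neuron$tau_m <= 0) stop("siegert_rate requires tau_m > 0")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  nn <- max(length(mu), length(sigma))
  mu <- rep_len(mu, nn)
  sigma <- rep_len(sigma, nn)
  r <- numeric(nn)

  det_rate <- function(m) {
    out <- numeric(length(m))
    sup <- m > neuron$v_th
    out[sup] <- 1000 / (neuron$tau_ref + neuron$tau_m *
                          log((m[sup] - neuron$v_reset) /
                                (m[sup] - neuron$v_th)))
    out
  }

  zero <- sigma == 0
  r[zero] <- det_rate(mu[zero])

  if (any(!zero)) {
    # sigma is the stationary SD of the free potential; the first-passage
    # integral is written in units of the OU diffusion scale sqrt(2)*sigma
    a <- (neuron$v_reset - mu[!zero]) / (sigma[!zero] * sqrt(2))
    b <- (neuron$v_th - mu[!zero]) / (sigma[!zero] * sqrt(2))
    # G(x) = int_0^x erfcx(-u) du; for x > 0 the exp(u^2) part integrates
    # to sqrt(pi) * erfi(x) exactly
    G <- function(x) {
      out <- numeric(length(x))
      pos <- x > 0
      if (any(pos))
        out[pos] <- sqrt(pi) * pracma::erfi(x[pos]) -
          int_erfcx(rep(0, sum(pos)), x[pos])
      if (any(!pos))
        out[!pos] <- -int_erfcx(rep(0, sum(!pos)), -x[!pos])
      out
    }
    # rate is < 1e-40 spikes/s beyond b ~ 10; treat as silent
    live <- b <= 10
    ri <- numeric(length(a))
    if (any(live)) {
      I <- G(b[live]) - G(a[live])
      ri[live] <- 1000 / (neuron$tau_ref +
                            neuron$tau_m * sqrt(pi) * I)
    }
    r[!zero] <- ri
  }
  r
}

#' Precompute a Siegert lookup table
#'
#' Rates on a (mu, sigma) grid (linear in mu, log-spaced in sigma) for
#' bilinear interpolation inside [lif_fixed_point()].
#'
#' @param neuron an [neuron_params()] object.
#' @param mu_range,sigma_range ranges (mV) that must bracket all values
#'   encountered during the iteration; `sigma_range` must be positive.
#' @param n_mu,n_sigma grid sizes.
#' @return `osnet_siegert_table` object.
#' @export
siegert_table <- function(neuron, mu_range, sigma_range,
                          n_mu = 200L, n_sigma = 100L) {
  stopifnot(sigma_range[1] > 0, diff(mu_range) > 0, diff(sigma_range) > 0)
  mu <- seq(mu_range[1], mu_range[2], length.out = n_mu)
  sg <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                length.out = n_sigma))
  rates <- vapply(sg, function(s) siegert_rate(mu, s, neuron), numeric(n_mu))
  structure(list(mu = mu, sigma = sg, rates = rates, neuron = neuron),
            class = "osnet_siegert_table")
}

# Bilinear interpolation on a siegert_table; errors outside the grid
# unless fallback = TRUE (then evaluates the integral directly).
siegert_interp <- function(tab, mu, sigma, fallback = FALSE) {
  out_mu <- mu < tab$mu[1] | mu > tab$mu[length(tab$mu)]
  out_sg <- sigma < tab$sigma[1] | sigma > tab$sigma[length(tab$sigma)]
  out <- out_mu | out_sg
  if (any(out) && !fallback)
    stop("(mu, sigma) outside the lookup grid; enlarge the table or ",
         "enable direct-evaluation fallback")
  r <- numeric(length(mu))
  if (any(!out)) {
    i <- findInterval(mu[!out], tab$mu, all.inside = TRUE)
    j <- findInterval(sigma[!out], tab$sigma, all.inside = TRUE)
    fx <- (mu[!out] - tab$mu[i]) / (tab$mu[i + 1] - tab$mu[i])
    fy <- (sigma[!out] - tab$sigma[j]) / (tab$sigma[j + 1] - tab$sigma[j])
    r[!out] <- (1 - fx) * (1 - fy) * tab$rates[cbind(i, j)] +
      fx * (1 - fy) * tab$rates[cbind(i + 1, j)] +
      (1 - fx) * fy * tab$rates[cbind(i, j + 1)] +
      fx * fy * tab$rates[cbind(i + 1, j + 1)]
  }
  if (any(out)) r[out] <- siegert_rate(mu[out], sigma[out], tab$neuron)
  r
}
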