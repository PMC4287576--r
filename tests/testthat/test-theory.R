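test_that("refractory correction has the stated closed forms", {
  expect_equal(refractory_correction(0, 2), 0)
  expect_equal(refractory_correction(123, 0), 123)
  expect_equal(refractory_correction(100, 2), 100 / 1.2)
  # monotone and bounded by 1/tau_ref
  r <- seq(0, 2000, by = 10)
  rc <- refractory_correction(r, 2)
  expect_true(all(diff(rc) > 0))
  expect_true(all(rc < 500))
})

test_that("linear rates solve the uncoupled and self-coupled closed forms", {
  neuron <- neuron_params("PIF", v_th = 20, tau_ref = 2)
  # W = 0: r = h / dV, refractory-corrected
  net <- build_network(3, 1, 0, 0, delays = delay_spec("fixed", value = 1))
  drv <- flat_drive(4, rate_ffw = 20000, j_ffw = 0.1, j_bkg = 0)
  r <- linear_rates(net, drv, neuron)
  expect_equal(as.vector(r), rep(refractory_correction(100, 2), 4))
  expect_equal(attr(r, "raw"), rep(100, 4))
  # zero input gives zero rates
  r0 <- linear_rates(net, flat_drive(4), neuron)
  expect_equal(as.vector(r0), rep(0, 4))
  # scalar self-coupling w < dV: r = h / (dV - w)
  net1 <- build_network(1, 0, 0, 0, delays = delay_spec("fixed", value = 1))
  net1$weights$W[1, 1] <- 5
  drv1 <- flat_drive(1, rate_ffw = 20000, j_ffw = 0.1, j_bkg = 0)
  r1 <- attr(linear_rates(net1, drv1, neuron, check_stability = FALSE),
             "raw")
  expect_equal(r1, 2000 / (20 - 5))
})

test_that("unstable recurrence is rejected by the spectral-radius guard", {
  net1 <- build_network(1, 0, 0, 0, delays = delay_spec("fixed", value = 1))
  net1$weights$W[1, 1] <- 25    # exceeds v_th - v_reset
  neuron <- neuron_params("PIF")
  expect_error(linear_rates(net1, flat_drive(1, 1000), neuron),
               "spectral radius")
})

test_that("rectified fixed point clamps, matches linear rates when positive", {
  neuron <- neuron_params("PIF", v_th = 20, tau_ref = 2)
  net <- tiny_net(n_exc = 40, n_inh = 10, k_exc = 8, k_inh = 2, g = 4)
  drv <- flat_drive(net$n, rate_ffw = 20000, rate_bkg = 1000)
  lin <- linear_rates(net, drv, neuron)
  fp <- rectified_fixed_point(net, drv, neuron)
  expect_true(fp$trace$converged)
  if (all(attr(lin, "raw") > 0))
    expect_equal(fp$rates, as.vector(lin), tolerance = 1e-6)
  # fixed-point identity of the uncorrected solution
  g <- pmax(0, (as.numeric(net$weights$W %*% fp$raw) +
                  osnet:::drive_field(drv)) / 20)
  expect_lt(max(abs(g - fp$raw)), 1e-6)
})

test_that("scalar negative self-coupling has the known fixed point", {
  # w = -dV/2 and h = dV * 1/s: r = h' / (1 - w') = 2/3 spikes/s
  neuron <- neuron_params("PIF", v_th = 20, tau_ref = 0)
  net1 <- build_network(1, 0, 0, 0, delays = delay_spec("fixed", value = 1))
  net1$weights$W[1, 1] <- -10
  drv1 <- flat_drive(1, rate_ffw = 200, j_ffw = 0.1, j_bkg = 0)
  fp <- rectified_fixed_point(net1, drv1, neuron)
  expect_equal(fp$rates, 2 / 3, tolerance = 1e-6)
})

test_that("rectified fixed point matches the exhaustive active-set oracle", {
  neuron <- neuron_params("PIF", v_th = 20, tau_ref = 0)
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    W <- matrix(rnorm(n * n, sd = 4), n, n)
    diag(W) <- 0
    # keep dV I - W strictly diagonally dominant: unique rectified
    # solution, so the enumeration oracle is well-defined
    s <- max(rowSums(abs(W)))
    if (s >= 18) W <- W * 17 / s
    h <- rnorm(n, mean = 20, sd = 60)
    net <- build_network(n, 0, 0, 0,
                         delays = delay_spec("fixed", value = 1))
    net$weights$W <- methods::as(W, "CsparseMatrix")
    drv <- flat_drive(n, j_ffw = 1, j_bkg = 0)
    drv$ffw_rate <- h
    fp <- rectified_fixed_point(net, drv, neuron, tol = 1e-9,
                                damping = 0.3)
    oracle <- rectified_oracle(W, h, 20)
    expect_false(is.null(oracle))
    expect_identical(fp$raw > 1e-9, oracle > 1e-9)
    expect_lt(max(abs(fp$raw - oracle)), 1e-8)
  }
})

test_that("non-convergence raises an error carrying the solver trace", {
  neuron <- neuron_params("PIF", v_th = 20, tau_ref = 0)
  net <- tiny_net(n_exc = 20, n_inh = 5, k_exc = 4, k_inh = 1)
  drv <- flat_drive(net$n, rate_ffw = 20000, rate_bkg = 500)
  err <- tryCatch(
    rectified_fixed_point(net, drv, neuron, tol = 1e-14, max_iter = 5L),
    osnet_nonconvergence = function(e) e)
  expect_s3_class(err, "osnet_nonconvergence")
  expect_equal(err$trace$iterations, 5L)
  expect_false(err$trace$converged)
})

test_that("input moments have the stated zero-input and scaling behaviour", {
  neuron <- neuron_params("LIF", tau_m = 20, v_rest = -70)
  net <- tiny_net(n_exc = 20, n_inh = 5, k_exc = 4, k_inh = 1)
  mom0 <- input_moments(net, rep(0, 25), flat_drive(25), neuron)
  expect_equal(mom0$mu, rep(-70, 25))
  expect_equal(mom0$sigma, rep(0, 25))
  # doubling one source weight doubles its mu term, quadruples sigma^2
  net1 <- build_network(2, 0, 0, 0, delays = delay_spec("fixed", value = 1))
  rates <- c(0, 1000)
  for (w in c(0.2, 0.4)) {
    net1$weights$W[1, 2] <- w
    net1$weights$W2 <- net1$weights$W
    net1$weights$W2@x <- net1$weights$W2@x^2
    mom <- input_moments(net1, rates, flat_drive(2, j_ffw = 0, j_bkg = 0),
                         neuron)
    assign(paste0("mu_", w * 10), mom$mu[1] - neuron$v_rest)
    assign(paste0("s2_", w * 10), mom$sigma[1]^2)
  }
  expect_equal(mu_4, 2 * mu_2)
  expect_equal(s2_4, 4 * s2_2)
})

test_that("simulated free-potential variance matches the diffusion sigma^2", {
  # disconnected LIF with threshold disabled: stationary variance of the
  # membrane potential equals (tau_m/2) * sum j^2 s
  neuron <- neuron_params("LIF", v_th = Inf, tau_ref = 0)
  net <- build_network(1, 0, 0, 0, delays = delay_spec("fixed", value = 1))
  drv <- flat_drive(1, rate_ffw = 8000, rate_bkg = 8000, j_ffw = 0.1,
                    j_bkg = -0.1)
  sp <- simulate_network(net, drv, neuron, duration = 60000, seed = 5,
                         record_v = 1)
  v <- sp$vtrace[-(1:5000), 1]
  s2_pred <- 10 * (0.1^2 * 8 + 0.1^2 * 8)
  expect_lt(abs(var(v) - s2_pred) / s2_pred, 0.1)
})

test_that("LIF fixed point reduces to the siegert rate without recurrence", {
  neuron <- neuron_params("LIF")
  net <- build_network(5, 1, 0, 0, delays = delay_spec("fixed", value = 1))
  drv <- flat_drive(6, rate_ffw = 22000, rate_bkg = 4000)
  fp <- lif_fixed_point(net, drv, neuron)
  mom <- input_moments(net, rep(0, 6), drv, neuron)
  expect_equal(fp$rates, siegert_rate(mom$mu, mom$sigma, neuron),
               tolerance = 1e-6)
  # converged output satisfies the self-consistency residual
  mom2 <- fp$moments
  expect_lt(max(abs(fp$rates - siegert_rate(mom2$mu, mom2$sigma, neuron))),
            1e-4)
})

test_that("small LIF network rates match a long spiking simulation", {
  neuron <- neuron_params("LIF")
  net <- tiny_net(n_exc = 40, n_inh = 10, k_exc = 6, k_inh = 2,
                  j_epsp = 0.15, g = 4)
  drv <- flat_drive(net$n, rate_ffw = 25000, rate_bkg = 5000)
  fp <- lif_fixed_point(net, drv, neuron, damping = 0.4)
  sp <- simulate_network(net, drv, neuron, duration = 20000, seed = 19)
  se <- sqrt(pmax(sp$counts, 1)) / (diff(sp$window) / 1000)
  z <- abs(sp$rates - fp$rates) / se
  expect_lt(mean(z > 3), 0.1)
  expect_lt(abs(mean(sp$rates) - mean(fp$rates)) / mean(fp$rates), 0.1)
})

test_that("PIF linear theory equals the clamped-mean-potential identity", {
  # a PIF network is the leak-free limit: linear rates are invariant to
  # tau_m and solve dV r = W r + h exactly
  neuron <- neuron_params("PIF", v_th = 20, tau_ref = 0)
  net <- tiny_net()
  drv <- flat_drive(net$n, rate_ffw = 22000, rate_bkg = 3000)
  r <- attr(linear_rates(net, drv, neuron), "raw")
  resid <- 20 * r - as.numeric(net$weights$W %*% r) -
    osnet:::drive_field(drv)
  expect_lt(max(abs(resid)), 1e-9)
})
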