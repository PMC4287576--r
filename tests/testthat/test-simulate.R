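test_that("subthreshold propagation matches the closed forms", {
  lif <- neuron_params("LIF", tau_m = 20, v_rest = 0)
  pif <- neuron_params("PIF")
  expect_equal(propagate_subthreshold(0, lif, 5), 0)    # fixed point
  expect_equal(propagate_subthreshold(10, lif, 20), 10 * exp(-1))
  expect_equal(propagate_subthreshold(13.7, pif, 50), 13.7)
  expect_error(propagate_subthreshold(1, lif, 0), "dt")
})

test_that("zero drive and zero weights produce no spikes", {
  net <- tiny_net()
  neuron <- neuron_params("LIF")
  sp <- simulate_network(net, flat_drive(net$n), neuron, duration = 200,
                         seed = 1, v_init = rep(0, net$n))
  expect_equal(nrow(sp$events), 0L)
})

test_that("input-silenced LIF trajectory is the analytic exponential", {
  net <- build_network(1, 0, 0, 0, delays = delay_spec("fixed", value = 1))
  neuron <- neuron_params("LIF", tau_m = 17.3, v_rest = 2)
  sp <- simulate_network(net, flat_drive(1), neuron, duration = 100,
                         seed = 1, v_init = 15, record_v = 1)
  k <- seq_len(1000)
  analytic <- 2 + (15 - 2) * exp(-k * 0.1 / 17.3)
  expect_lt(max(abs(sp$vtrace[, 1] - analytic)), 1e-12)
})

test_that("PIF potential equals the cumulative delayed PSP sum exactly", {
  # inhibitory neuron 2 drives neuron 1 through a single synapse; neuron
  # 1 receives no external input and stays below threshold, so its
  # potential must be the running (delayed) spike count of neuron 2
  # times the synaptic weight, exactly
  topo <- structure(list(n_exc = 1L, n_inh = 1L, k_exc = 0L, k_inh = 1L,
                         sources = list(2L, integer(0)), seed = 1L),
                    class = "osnet_topology")
  wt <- build_weight_matrix(topo, j_epsp = 0.25, g = 2)
  net <- structure(list(topology = topo, weights = wt,
                        delays = delay_spec("fixed", value = 2),
                        delay_steps = rep(20L, length(wt$W@x)), dt = 0.1,
                        po = c(0, 0), n = 2L, n_exc = 1L, n_inh = 1L),
                   class = "osnet_network")
  neuron <- neuron_params("PIF", v_th = 20, tau_ref = 2)
  drv <- flat_drive(2, j_ffw = 0.1, j_bkg = 0)
  drv$ffw_rate <- c(0, 30000)
  sp <- simulate_network(net, drv, neuron, duration = 500, seed = 4,
                         v_init = c(0, 0), record_v = 1)
  t2 <- sp$events$time_ms[sp$events$id == 2]
  steps <- seq_len(5000) * 0.1
  expected <- -0.5 * vapply(steps, function(t)
    sum(t2 + 2 <= t + 1e-9), numeric(1))
  expect_identical(sp$vtrace[, 1], expected)
})

test_that("no inter-spike interval is shorter than the refractory period", {
  net <- tiny_net(n_exc = 20, n_inh = 5, k_exc = 4, k_inh = 1)
  neuron <- neuron_params("LIF", tau_ref = 2)
  drv <- flat_drive(net$n, rate_ffw = 30000, rate_bkg = 5000)
  sp <- simulate_network(net, drv, neuron, duration = 1000, seed = 6)
  isi <- unlist(lapply(split(sp$events$time_ms, sp$events$id),
                       function(tt) diff(sort(tt))))
  expect_gte(min(isi), 2 + 0.1 - 1e-9)
})

test_that("identical seeds reproduce spike data exactly", {
  net <- tiny_net()
  neuron <- neuron_params("LIF")
  drv <- flat_drive(net$n, rate_ffw = 25000, rate_bkg = 2000)
  s1 <- simulate_network(net, drv, neuron, duration = 500, seed = 12)
  s2 <- simulate_network(net, drv, neuron, duration = 500, seed = 12)
  s3 <- simulate_network(net, drv, neuron, duration = 500, seed = 13)
  expect_identical(s1$events, s2$events)
  expect_false(identical(s1$events, s3$events))
})

test_that("disconnected PIF neuron matches the mean-drift rate oracle", {
  # drift j*s = 2000 mV/s over a 20 mV threshold distance: free rate
  # 100/s, refractory-corrected to 100/1.2
  net <- build_network(1, 0, 0, 0, delays = delay_spec("fixed", value = 1))
  neuron <- neuron_params("PIF", v_th = 20, tau_ref = 2)
  drv <- flat_drive(1, rate_ffw = 20000, j_ffw = 0.1, j_bkg = 0)
  sp <- simulate_network(net, drv, neuron, duration = 60000, seed = 31)
  expected <- 100 / (1 + 100 * 0.002)
  se <- sqrt(sp$counts[1]) / (diff(sp$window) / 1000)
  expect_lt(abs(sp$rates[1] - expected), 3 * se)
})

test_that("halving dt leaves stationary rates within Monte-Carlo error", {
  neuron <- neuron_params("LIF")
  rates <- vapply(c(0.1, 0.05), function(dt) {
    net <- tiny_net(n_exc = 40, n_inh = 10, k_exc = 8, k_inh = 2, dt = dt)
    drv <- flat_drive(net$n, rate_ffw = 30000, rate_bkg = 5000)
    sp <- simulate_network(net, drv, neuron, duration = 3000, seed = 17)
    c(mean(sp$rates), sum(sp$counts))
  }, numeric(2))
  # population-mean rate: SE from total counts
  se <- sqrt(sum(rates[2, ])) / (50 * 2.8)
  expect_lt(abs(rates[1, 1] - rates[1, 2]), 3 * se)
})

test_that("population PSTH conserves spike counts and is flat for Poisson input", {
  net <- tiny_net(n_exc = 20, n_inh = 5, k_exc = 0, k_inh = 0)
  neuron <- neuron_params("LIF")
  drv <- flat_drive(net$n, rate_ffw = 30000, rate_bkg = 0)
  sp <- simulate_network(net, drv, neuron, duration = 2000, seed = 9)
  groups <- list(exc = 1:20, inh = 21:25)
  psth <- population_psth(sp, bin = 10, groups = groups)
  for (g in names(groups)) {
    total <- sum(psth[[g]]) * (10 / 1000) * length(groups[[g]])
    expect_equal(total, sum(sp$events$id %in% groups[[g]]))
  }
  # empty input gives an all-zero trace
  sp0 <- simulate_network(net, flat_drive(net$n), neuron, duration = 100,
                          seed = 2, v_init = rep(0, net$n))
  expect_true(all(population_psth(sp0, bin = 5)$all == 0))
  # rates in a disconnected drive regime are flat across bins
  expect_lt(sd(psth$exc) / mean(psth$exc), 0.2)
})

test_that("gdf round trip preserves events", {
  net <- tiny_net(n_exc = 10, n_inh = 2, k_exc = 2, k_inh = 1)
  neuron <- neuron_params("LIF")
  drv <- flat_drive(net$n, rate_ffw = 30000, rate_bkg = 1000)
  sp <- simulate_network(net, drv, neuron, duration = 300, seed = 5)
  path <- withr::local_tempfile(fileext = ".gdf")
  write_gdf(sp, path)
  back <- read_gdf(path)
  ord <- order(sp$events$time_ms, sp$events$id)
  expect_equal(back$events$id, sp$events$id[ord])
  expect_equal(back$events$time_ms, sp$events$time_ms[ord],
               tolerance = 1e-8)
})
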