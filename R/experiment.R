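# Config-driven orchestration: presets, orientation x contrast sweeps,
# simulation-vs-theory comparison, result bundles.

#' Shipped experiment presets
#'
#' Four study regimes, shipped at a reduced "desk" scale (N = 1250) that
#' keeps a full orientation-by-contrast sweep tractable on one CPU while
#' preserving the qualitative operating point of the corresponding
#' full-scale balanced random network:
#' \describe{
#'   \item{pif_linear}{PIF network with exactly balanced recurrence
#'     (`g * k_inh = k_exc`): the linear rate theory applies without
#'     rectification.}
#'   \item{pif_rectified}{PIF network with dominant inhibition: a
#'     sizeable fraction of linear rates is negative, so the rectified
#'     fixed point is required.}
#'   \item{lif}{Same inhibition-dominated network with leaky neurons
#'     operating in the fluctuation-driven regime (Siegert fixed point).}
#'   \item{lif_synchronous}{The `lif` network with identical (rather than
#'     distributed) recurrent delays, which puts it in a synchronous
#'     dynamical state.}
#' }
#'
#' @param preset preset name.
#' @param master_seed integer master seed; per-condition seeds are derived
#'   deterministically from it.
#' @return `osnet_config` object (a validated nested list with sections
#'   `network`, `stimulus`, `neuron`, `solver`, `simulation`).
#' @export
preset_config <- function(preset = c("pif_linear", "pif_rectified", "lif",
                                     "lif_synchronous"),
                          master_seed = 1L) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    master_seed = as.integer(master_seed),
    network = list(n_exc = 1000L, n_inh = 250L, k_exc = 40L, k_inh = 10L,
                   j_epsp = 0.2, g = 4,
                   delay = list(mode = "uniform", d_min = 0.5, d_max = 3.0),
                   seed_topology = 101L, seed_po = 202L, seed_delays = 303L),
    stimulus = list(m = 0.5, s_max = 5000, s_bkg = 400,
                    j_ffw = 0.1, j_bkg = 0.1,
                    contrasts = c(1 / 3, 2 / 3, 1), n_theta = 12L),
    neuron = list(model = "PIF", tau_m = 20, v_rest = 0, v_th = 20,
                  v_reset = 0, tau_ref = 2),
    solver = list(tol = 1e-6, max_iter = 10000L, damping = 0.5,
                  use_lookup = FALSE),
    simulation = list(duration = 5000, dt = 0.1, transient = 200))
  if (preset %in% c("pif_rectified", "lif", "lif_synchronous")) {
    base$network$k_exc <- 320L
    base$network$k_inh <- 80L
    base$network$j_epsp <- 0.25
    base$network$g <- 8
    base$stimulus$m <- 0.4
    base$stimulus$s_max <- 14000
    base$stimulus$s_bkg <- 1000
    base$solver$damping <- 0.25
  }
  if (preset %in% c("lif", "lif_synchronous")) {
    base$neuron$model <- "LIF"
    base$solver$use_lookup <- TRUE
    # stronger drive than the PIF presets: the leaky neuron needs the
    # mean input within a few sigma of threshold at the lowest contrast,
    # and enough background to sustain spontaneous activity
    base$stimulus$s_max <- 24000
    base$stimulus$s_bkg <- 10000
  }
  if (preset == "lif_synchronous")
    base$network$delay <- list(mode = "fixed", value = 1.5)
  validate_config(structure(base, class = "osnet_config"))
}

#' Validate an experiment configuration
#'
#' Checks every section by constructing the corresponding domain objects;
#' errors name the offending field.
#'
#' @param config an `osnet_config` (or plain nested list).
#' @return the config, invisibly classed `osnet_config`.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  for (sec in c("network", "stimulus", "neuron", "solver", "simulation"))
    if (is.null(config[[sec]])) stop("config section missing: ", sec)
  nw <- config$network
  d <- nw$delay
  if (d$mode == "fixed") delay_spec("fixed", value = d$value)
  else delay_spec("uniform", d_min = d$d_min, d_max = d$d_max)
  do.call(stimulus_config, config$stimulus)
  do.call(neuron_params, config$neuron)
  if (config$simulation$duration <= config$simulation$transient)
    stop("simulation duration must exceed the transient window")
  if (config$simulation$dt <= 0) stop("dt must be positive")
  invisible(structure(config, class = "osnet_config"))
}

#' Read / write experiment configurations
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), decided by file extension.
#' @param path config file.
#' @return an `osnet_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param config config to write.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  else yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Scale a preset down to a test fixture
#'
#' Population sizes scale with `scale`; in-degrees with `sqrt(scale)`
#' (roughly preserving input statistics); the simulated duration with
#' `sqrt(scale)` (floored at 500 ms).
#'
#' @param preset preset name or an `osnet_config` to scale.
#' @param scale ratio in (0, 1].
#' @return scaled `osnet_config`.
#' @export
generate_fixture <- function(preset, scale = 1) {
  if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]")
  cfg <- if (inherits(preset, "osnet_config")) preset else
    preset_config(preset)
  if (scale < 1) {
    cfg$network$n_exc <- max(2L, as.integer(round(cfg$network$n_exc * scale)))
    cfg$network$n_inh <- max(1L, as.integer(round(cfg$network$n_inh * scale)))
    cfg$network$k_exc <- min(cfg$network$n_exc - 1L,
                             as.integer(round(cfg$network$k_exc *
                                                sqrt(scale))))
    cfg$network$k_inh <- min(cfg$network$n_inh - 1L,
                             as.integer(round(cfg$network$k_inh *
                                                sqrt(scale))))
    cfg$simulation$duration <-
      max(500, round(cfg$simulation$duration * sqrt(scale)))
  }
  validate_config(cfg)
}

# Deterministic per-condition seed derivation (stable, < 2^31).
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 104729) %% 2147483647L) + 1L
}

config_network <- function(config) {
  nw <- config$network
  d <- nw$delay
  dl <- if (d$mode == "fixed") delay_spec("fixed", value = d$value)
  else delay_spec("uniform", d_min = d$d_min, d_max = d$d_max)
  build_network(nw$n_exc, nw$n_inh, nw$k_exc, nw$k_inh,
                j_epsp = nw$j_epsp, g = nw$g, delays = dl,
                dt = config$simulation$dt,
                seed_topology = nw$seed_topology, seed_po = nw$seed_po,
                seed_delays = nw$seed_delays)
}

config_theories <- function(config) {
  if (config$neuron$model == "PIF") c("linear", "rectified") else "lif"
}

theory_rates <- function(theory, net, drv, neuron, solver, lookup = NULL) {
  switch(theory,
         linear = list(rates = linear_rates(net, drv, neuron,
                                            check_stability = FALSE)),
         rectified = rectified_fixed_point(net, drv, neuron,
                                           tol = solver$tol,
                                           max_iter = solver$max_iter,
                                           damping = solver$damping),
         lif = lif_fixed_point(net, drv, neuron, tol = solver$tol,
                               max_iter = solver$max_iter,
                               damping = solver$damping,
                               lookup = lookup, lookup_fallback = TRUE),
         stop("unknown theory layer: ", theory))
}

#' Run a full orientation-by-contrast sweep
#'
#' One simulation per configured (contrast, orientation) condition plus
#' one spontaneous run (background only), with the rate theory evaluated
#' on the same network and drives. Fully deterministic given the master
#' seed: per-condition simulation seeds are derived by stable hashing.
#'
#' @param config an `osnet_config`.
#' @param theories theory layers to evaluate (default: the ones natural
#'   for the neuron model — linear and rectified for PIF, the Siegert
#'   fixed point for LIF).
#' @param contrasts,thetas optional subsets of the configured grid.
#' @param keep_spikes store the full spike objects (memory!).
#' @param outdir if non-NULL, write per-condition gdf spike files, rate
#'   CSVs and a JSON manifest into this directory.
#' @return `osnet_bundle`: list with `conditions` (data.frame), matrices
#'   `sim_rates` and one per theory layer (`n_neurons x n_conditions`,
#'   spontaneous condition last), `v_mean`, the network's input POs, the
#'   config, and any solver errors (`errors`; bundle marked `partial`).
#' @export
run_orientation_sweep <- function(config, theories = NULL,
                                  contrasts = NULL, thetas = NULL,
                                  keep_spikes = FALSE, outdir = NULL) {
  config <- validate_config(config)
  if (is.null(theories)) theories <- config_theories(config)
  stim <- do.call(stimulus_config, config$stimulus)
  neuron <- do.call(neuron_params, config$neuron)
  net <- config_network(config)
  if (is.null(contrasts)) contrasts <- stim$contrasts
  if (is.null(thetas)) thetas <- theta_grid(stim)

  cond <- expand.grid(theta = thetas, contrast = contrasts,
                      KEEP.OUT.ATTRS = FALSE)
  cond$evoked <- TRUE
  cond <- rbind(cond, data.frame(theta = NA, contrast = NA, evoked = FALSE))
  cond$index <- seq_len(nrow(cond))
  cond$seed <- derive_seed(config$master_seed, cond$index)

  n <- net$n
  sim_rates <- matrix(NA_real_, n, nrow(cond))
  v_mean <- matrix(NA_real_, n, nrow(cond))
  th_rates <- lapply(theories, function(.) matrix(NA_real_, n, nrow(cond)))
  names(th_rates) <- theories
  spikes <- if (keep_spikes) vector("list", nrow(cond)) else NULL
  errors <- list()
  lookup_tab <- NULL

  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  for (i in cond$index) {
    drv <- build_drive(net$po, theta = cond$theta[i], C = cond$contrast[i],
                       stim = stim, evoked = cond$evoked[i])
    sp <- simulate_network(net, drv, neuron,
                           duration = config$simulation$duration,
                           seed = cond$seed[i],
                           transient = config$simulation$transient)
    sim_rates[, i] <- sp$rates
    v_mean[, i] <- sp$v_mean
    if (keep_spikes) spikes[[i]] <- sp
    if (!is.null(outdir))
      write_gdf(sp, file.path(outdir, sprintf("spikes_%03d.gdf", i)))
    for (th in theories) {
      lk <- if (th == "lif") {
        if (!is.null(lookup_tab)) lookup_tab
        else if (isTRUE(config$solver$use_lookup)) "auto" else NULL
      } else NULL
      res <- tryCatch(theory_rates(th, net, drv, neuron, config$solver,
                                   lookup = lk),
                      error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(th, i, sep = "_")]] <- conditionMessage(res)
      } else {
        th_rates[[th]][, i] <- res$rates
        if (th == "lif" && is.null(lookup_tab) && !is.null(res$lookup))
          lookup_tab <- res$lookup
      }
    }
  }

  bundle <- structure(list(
    config = config, net = net, conditions = cond, po = net$po,
    sim_rates = sim_rates, theory = th_rates, v_mean = v_mean,
    spikes = spikes, errors = errors, partial = length(errors) > 0),
    class = "osnet_bundle")
  if (!is.null(outdir)) write_bundle_tables(bundle, outdir)
  bundle
}

# Rates, conditions and manifest as plain-text files.
write_bundle_tables <- function(bundle, outdir) {
  utils::write.csv(data.frame(neuron_id = seq_len(nrow(bundle$sim_rates)),
                              bundle$sim_rates),
                   file.path(outdir, "sim_rates.csv"), row.names = FALSE)
  for (th in names(bundle$theory))
    utils::write.csv(data.frame(neuron_id = seq_len(nrow(bundle$sim_rates)),
                                bundle$theory[[th]]),
                     file.path(outdir, paste0("theory_", th, ".csv")),
                     row.names = FALSE)
  utils::write.csv(bundle$conditions, file.path(outdir, "conditions.csv"),
                   row.names = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("osnet")),
                   master_seed = bundle$config$master_seed,
                   condition_seeds = bundle$conditions$seed,
                   config = unclass(bundle$config),
                   partial = bundle$partial)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.osnet_bundle <- function(x, ...) {
  ne <- sum(x$conditions$evoked)
  cat("osnet result bundle:", ne, "evoked conditions + 1 spontaneous;",
      "preset", x$config$preset %||% "(custom)", "\n")
  cat("  theory layers:", paste(names(x$theory), collapse = ", "), "\n")
  if (x$partial) cat("  PARTIAL: ", length(x$errors), "solver errors\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare simulated and theoretical rates
#'
#' Per condition: distribution of per-neuron rate differences
#' (simulation minus theory), Pearson correlation and RMS difference.
#'
#' @param bundle an `osnet_bundle`.
#' @param theory which theory layer (must be present in the bundle).
#' @return data.frame, one row per condition.
#' @export
compare_sim_theory <- function(bundle, theory = names(bundle$theory)[1]) {
  if (!theory %in% names(bundle$theory))
    stop("theory layer not present in bundle: ", theory)
  th <- bundle$theory[[theory]]
  out <- lapply(bundle$conditions$index, function(i) {
    d <- bundle$sim_rates[, i] - th[, i]
    data.frame(index = i, theta = bundle$conditions$theta[i],
               contrast = bundle$conditions$contrast[i],
               mean_diff = mean(d), sd_diff = sd(d),
               q05 = quantile(d, 0.05, names = FALSE),
               q95 = quantile(d, 0.95, names = FALSE),
               pearson = cor(bundle$sim_rates[, i], th[, i]),
               rms_diff = sqrt(mean(d^2)),
               mean_rate_sim = mean(bundle$sim_rates[, i]))
  })
  do.call(rbind, out)
}

#' Tuning curves of a bundle at one contrast
#'
#' @param bundle an `osnet_bundle`.
#' @param contrast one of the configured contrasts.
#' @param source `"sim"` or a theory layer name.
#' @return matrix `n_neurons x n_theta` with orientations as column names.
#' @export
bundle_tuning_curves <- function(bundle, contrast, source = "sim") {
  sel <- bundle$conditions$evoked &
    abs(bundle$conditions$contrast - contrast) < 1e-9
  if (!any(sel)) stop("contrast not present in bundle: ", contrast)
  m <- if (source == "sim") bundle$sim_rates[, sel, drop = FALSE]
  else bundle$theory[[source]][, sel, drop = FALSE]
  colnames(m) <- bundle$conditions$theta[sel]
  ord <- order(as.numeric(colnames(m)))
  m[, ord, drop = FALSE]
}

#' Tuning width of the (cosine) input tuning curve
#'
#' Fits the same von Mises model to the feedforward input curve, giving
#' the reference width for the sharpening coefficient.
#'
#' @param stim an [stimulus_config()] object.
#' @param C contrast.
#' @return width in degrees.
#' @export
input_tuning_width <- function(stim, C = 1) {
  th <- theta_grid(stim)
  curve <- feedforward_rate(0, th, contrast_baseline(C, stim$s_max), stim$m)
  fit <- fit_von_mises(curve, th)
  tuning_width(fit$kappa)
}
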