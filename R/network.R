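#' Build a fixed-in-degree random network topology
#'
#' Every neuron (excitatory or inhibitory target alike) receives exactly
#' `k_exc` excitatory and `k_inh` inhibitory inputs, drawn uniformly at
#' random without replacement from the respective population, excluding
#' self-connections and multiple contacts. Excitatory neurons occupy
#' indices `1..n_exc`, inhibitory neurons `n_exc+1 .. n_exc+n_inh`.
#'
#' @param n_exc,n_inh population sizes.
#' @param k_exc,k_inh excitatory / inhibitory in-degree (identical for
#'   every target).
#' @param seed integer seed; the topology is a pure function of the
#'   arguments.
#' @return An object of class `osnet_topology`: a list with `n_exc`,
#'   `n_inh`, `k_exc`, `k_inh` and `sources`, a list of integer vectors
#'   (presynaptic indices per target, excitatory sources first).
#' @export
build_topology <- function(n_exc, n_inh, k_exc, k_inh, seed = 1L) {
  stopifnot(n_exc >= 0, n_inh >= 0, k_exc >= 0, k_inh >= 0)
  n <- n_exc + n_inh
  if (n < 1L) stop("network must contain at least one neuron")
  # an excitatory target can draw from n_exc - 1 distinct excitatory sources
  if (n_exc > 0 && k_exc > n_exc - 1L)
    stop("excitatory in-degree k_exc = ", k_exc,
         " exceeds the ", n_exc - 1L,
         " admissible distinct excitatory sources (excitatory population)")
  if (n_inh > 0 && k_inh > n_inh - 1L)
    stop("inhibitory in-degree k_inh = ", k_inh,
         " exceeds the ", n_inh - 1L,
         " admissible distinct inhibitory sources (inhibitory population)")
  if (n_exc == 0 && k_exc > 0) stop("k_exc > 0 but no excitatory neurons")
  if (n_inh == 0 && k_inh > 0) stop("k_inh > 0 but no inhibitory neurons")

  set.seed(as.integer(seed))
  exc_pool <- seq_len(n_exc)
  inh_pool <- n_exc + seq_len(n_inh)
  # sample() would misbehave on length-1 pools; index explicitly
  draw <- function(pool, k)
    if (k > 0) pool[sample.int(length(pool), k)] else integer(0)
  sources <- vector("list", n)
  for (i in seq_len(n)) {
    epool <- if (i <= n_exc) exc_pool[-i] else exc_pool
    ipool <- if (i > n_exc) inh_pool[inh_pool != i] else inh_pool
    sources[[i]] <- c(draw(epool, k_exc), draw(ipool, k_inh))
  }
  structure(list(n_exc = n_exc, n_inh = n_inh,
                 k_exc = k_exc, k_inh = k_inh,
                 sources = sources, seed = as.integer(seed)),
            class = "osnet_topology")
}

#' Dale-compliant weight matrix from a topology
#'
#' Synapses from excitatory sources all have PSP amplitude `j_epsp` (mV);
#' synapses from inhibitory sources all have amplitude `-g * j_epsp`.
#' The matrix is stored sparsely with `W[i, j]` the PSP that a spike of
#' neuron `j` evokes in neuron `i`, so each row holds one target's inputs.
#'
#' @param topology an `osnet_topology`.
#' @param j_epsp excitatory PSP amplitude in mV (> 0).
#' @param g inhibition-dominance ratio (>= 0); IPSP = `-g * j_epsp`.
#' @return `osnet_weights` object: list with the sparse matrix `W` (mV),
#'   `W2` (entrywise square, used by the diffusion moments), `j_epsp`, `g`.
#' @export
build_weight_matrix <- function(topology, j_epsp, g) {
  stopifnot(inherits(topology, "osnet_topology"))
  if (!is.numeric(j_epsp) || j_epsp <= 0) stop("j_epsp must be positive")
  if (!is.numeric(g) || g < 0) stop("g must be non-negative")
  n <- topology$n_exc + topology$n_inh
  deg <- lengths(topology$sources)
  ii <- rep.int(seq_len(n), deg)
  jj <- unlist(topology$sources, use.names = FALSE)
  w <- as.numeric(ifelse(jj <= topology$n_exc, j_epsp, -g * j_epsp))
  W <- sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  W2 <- W
  W2@x <- W2@x^2
  structure(list(W = W, W2 = W2, j_epsp = j_epsp, g = g,
                 n_exc = topology$n_exc, n_inh = topology$n_inh),
            class = "osnet_weights")
}

#' Transmission-delay specification
#'
#' @param mode `"fixed"` (all recurrent delays identical) or `"uniform"`
#'   (per-synapse delays drawn uniformly on `[d_min, d_max]`). Distributed
#'   delays desynchronise the network (asynchronous-irregular state);
#'   identical delays favour the synchronous state.
#' @param value delay in ms (fixed mode).
#' @param d_min,d_max range in ms (uniform mode).
#' @return `osnet_delays` object.
#' @export
delay_spec <- function(mode = c("uniform", "fixed"), value = 1.5,
                       d_min = 0.5, d_max = 3.0) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (value <= 0) stop("delay must be positive")
  } else {
    if (d_min <= 0 || d_max <= d_min)
      stop("uniform delays require 0 < d_min < d_max")
  }
  structure(list(mode = mode, value = value, d_min = d_min, d_max = d_max),
            class = "osnet_delays")
}

# Per-edge delays in integer steps, aligned with the nonzero slots of the
# column-compressed weight matrix (the order the simulator consumes).
draw_edge_delays <- function(weights, delays, dt, seed) {
  n_edges <- length(weights$W@x)
  if (delays$mode == "fixed") {
    steps <- rep.int(as.integer(round(delays$value / dt)), n_edges)
  } else {
    set.seed(as.integer(seed))
    d <- runif(n_edges, delays$d_min, delays$d_max)
    steps <- as.integer(round(d / dt))
  }
  if (any(steps < 1L))
    stop("delays shorter than one simulation step after rounding")
  steps
}

#' Assign input preferred orientations
#'
#' Input POs are drawn independently and uniformly on \[0, 180) degrees.
#'
#' @param n number of neurons (>= 1).
#' @param seed integer seed.
#' @return numeric vector of length `n`, degrees in \[0, 180).
#' @export
assign_input_pos <- function(n, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be at least 1")
  set.seed(as.integer(seed))
  runif(n, 0, 180)
}

#' Write a network as a coordinate-list text table
#'
#' One line per synapse: `source target weight_mV delay_ms`, with a
#' one-line header.
#'
#' @param net an `osnet_network` (see [build_network()]).
#' @param path output file.
#' @export
write_network_table <- function(net, path) {
  W <- net$weights$W
  Wt <- as(W, "TsparseMatrix")
  df <- data.frame(source = Wt@j + 1L, target = Wt@i + 1L,
                   weight_mV = Wt@x)
  # delay steps are stored in @x (column) order; map to triplet order
  Wc <- as(W, "CsparseMatrix")
  key_c <- paste(Wc@i + 1L, rep(seq_len(ncol(Wc)), diff(Wc@p)))
  key_t <- paste(df$target, df$source)
  df$delay_ms <- net$delay_steps[match(key_t, key_c)] * net$dt
  df <- df[order(df$source, df$target), ]
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a complete network model
#'
#' Convenience constructor combining topology, Dale-compliant weights,
#' per-synapse delays and input preferred orientations, as consumed by
#' both the simulator and the rate theory.
#'
#' @param n_exc,n_inh,k_exc,k_inh network sizes and in-degrees.
#' @param j_epsp,g synaptic efficacy (mV) and inhibition ratio.
#' @param delays an [delay_spec()] object.
#' @param dt simulation step (ms) used to discretise delays.
#' @param seed_topology,seed_po,seed_delays integer seeds.
#' @return `osnet_network` object.
#' @export
build_network <- function(n_exc, n_inh, k_exc, k_inh, j_epsp = 0.2, g = 4,
                          delays = delay_spec("uniform"), dt = 0.1,
                          seed_topology = 1L, seed_po = 2L,
                          seed_delays = 3L) {
  topo <- build_topology(n_exc, n_inh, k_exc, k_inh, seed = seed_topology)
  weights <- build_weight_matrix(topo, j_epsp, g)
  dsteps <- draw_edge_delays(weights, delays, dt, seed = seed_delays)
  po <- assign_input_pos(n_exc + n_inh, seed = seed_po)
  structure(list(topology = topo, weights = weights, delays = delays,
                 delay_steps = dsteps, dt = dt, po = po,
                 n = n_exc + n_inh, n_exc = n_exc, n_inh = n_inh),
            class = "osnet_network")
}

#' @export
print.osnet_network <- function(x, ...) {
  cat("osnet network:", x$n_exc, "excitatory +", x$n_inh,
      "inhibitory neurons\n")
  cat("  in-degrees:", x$topology$k_exc, "exc /", x$topology$k_inh,
      "inh; J =", x$weights$j_epsp, "mV; g =", x$weights$g, "\n")
  cat("  delays:", x$delays$mode, "\n")
  invisible(x)
}
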