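#' Ground-truth structural networks
#'
#' A `structural_network` holds the directed Synaptic Weight Matrix (SWM;
#' entry `(i, j)` is the weight of the link i -> j, positive for excitatory
#' sources and negative for inhibitory ones), the per-link conduction delays
#' in milliseconds, and the neuron type labels. The excitatory:inhibitory
#' count ratio is 4:1; autapses are not allowed; inhibitory links carry a
#' fixed 1 ms delay while excitatory delays are uniform on {1, ..., 20} ms;
#' weights are drawn from N(6, 1) (excitatory) and N(-5, 1) (inhibitory) at
#' initialization.
#'
#' @name structural_network
#' @keywords internal
NULL

new_structural_network <- function(swm, delays, types, wiring, seed) {
  structure(list(n_neurons = nrow(swm), swm = swm, delays_ms = delays,
                 types = types, wiring = wiring, seed = seed),
            class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  cat(sprintf("structural_network (%s): %d neurons (%d exc / %d inh), %d links\n",
              x$wiring, x$n_neurons, sum(x$types == "exc"), sum(x$types == "inh"),
              sum(x$swm != 0)))
  invisible(x)
}

draw_weights_delays <- function(src_type, n) {
  if (src_type == "exc")
    list(w = rnorm(n, 6, 1), d = sample(1:20, n, replace = TRUE))
  else
    list(w = rnorm(n, -5, 1), d = rep(1L, n))
}

#' Random structural network
#'
#' Every neuron receives exactly `in_degree` afferents, sources drawn
#' uniformly without replacement from the permitted population: excitatory
#' neurons receive 80% excitatory and 20% inhibitory afferents (mirroring the
#' 4:1 population ratio); inhibitory neurons receive only excitatory
#' afferents.
#'
#' @param n number of neurons (divisible by 5; default 1000).
#' @param in_degree afferents per neuron (default 100; the 80/20 split must be
#'   integral, i.e. `in_degree` divisible by 5).
#' @param seed optional RNG seed for reproducible generation.
#' @return a `structural_network`.
#' @export
build_random_network <- function(n = 1000, in_degree = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n %% 5 != 0) stop("n must be divisible by 5 (4:1 excitatory:inhibitory ratio)")
  if (in_degree %% 5 != 0) stop("in_degree must be divisible by 5 (80/20 afferent split)")
  n_exc <- 4L * n %/% 5L
  types <- rep(c("exc", "inh"), c(n_exc, n - n_exc))
  k_ee <- 4L * in_degree %/% 5L   # excitatory afferents of an excitatory neuron
  k_ei <- in_degree - k_ee        # inhibitory afferents of an excitatory neuron
  if (n_exc - 1L < in_degree || n - n_exc < k_ei)
    stop("infeasible: population too small for the requested in-degree")
  exc_ids <- seq_len(n_exc); inh_ids <- seq.int(n_exc + 1L, n)
  swm <- matrix(0, n, n)
  delays <- matrix(0L, n, n)
  for (j in seq_len(n)) {
    if (types[j] == "exc") {
      src_e <- sample(exc_ids[exc_ids != j], k_ee)
      src_i <- sample(inh_ids, k_ei)
    } else {
      src_e <- sample(exc_ids, in_degree)   # j is inhibitory, no autapse risk
      src_i <- integer(0)
    }
    we <- draw_weights_delays("exc", length(src_e))
    swm[src_e, j] <- we$w
    delays[cbind(src_e, j)] <- we$d
    if (length(src_i)) {
      wi <- draw_weights_delays("inh", length(src_i))
      swm[src_i, j] <- wi$w
      delays[cbind(src_i, j)] <- wi$d
    }
  }
  new_structural_network(swm, delays, types, "random", seed)
}

#' Scale-free structural network
#'
#' Directed preferential-attachment growth: nodes are added one at a time and
#' each sends `m` links to distinct existing nodes chosen with probability
#' proportional to (current in-degree + 1), producing a heavy-tailed in-degree
#' distribution. Neuron types (4:1), weight and delay conventions follow the
#' random rule; inhibitory neurons accept no inhibitory afferents and autapses
#' are excluded.
#'
#' @param n number of neurons (>= 50, divisible by 5).
#' @param m attachment links added per node (default 10).
#' @param seed optional RNG seed.
#' @return a `structural_network`.
#' @export
build_scale_free_network <- function(n = 1000, m = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 50) stop("n must be >= 50")
  if (n %% 5 != 0) stop("n must be divisible by 5 (4:1 ratio)")
  if (m < 1 || m >= n %/% 2) stop("invalid attachment parameter m")
  n_exc <- 4L * n %/% 5L
  types <- sample(rep(c("exc", "inh"), c(n_exc, n - n_exc)))
  swm <- matrix(0, n, n)
  delays <- matrix(0L, n, n)
  indeg <- integer(n)
  seed_sz <- m + 1L
  add_edge <- function(i, j) {
    wd <- draw_weights_delays(types[i], 1L)
    swm[i, j] <<- wd$w
    delays[i, j] <<- wd$d
    indeg[j] <<- indeg[j] + 1L
  }
  for (i in seq_len(seed_sz)) for (j in seq_len(seed_sz)) {
    if (i != j && !(types[i] == "inh" && types[j] == "inh")) add_edge(i, j)
  }
  for (i in seq.int(seed_sz + 1L, n)) {
    prior <- seq_len(i - 1L)
    cand <- if (types[i] == "inh") prior[types[prior] == "exc"] else prior
    k <- min(m, length(cand))
    tgt <- sample(cand, k, prob = indeg[cand] + 1)
    for (j in tgt) add_edge(i, j)
  }
  new_structural_network(swm, delays, types, "scale_free", seed)
}

#' Save / load structural networks (edge-list CSV plus a neuron-type table)
#'
#' `prefix` produces `<prefix>_edges.csv` (`source,target,weight,delay_ms`)
#' and `<prefix>_neurons.csv` (`id,type`).
#' @param net a `structural_network`.
#' @param prefix path prefix.
#' @rdname network_io
#' @return [load_structural_network()] returns a `structural_network`;
#'   [save_structural_network()] returns `prefix` invisibly.
#' @export
save_structural_network <- function(net, prefix) {
  nz <- which(net$swm != 0, arr.ind = TRUE)
  edges <- data.frame(source = nz[, 1], target = nz[, 2],
                      weight = net$swm[nz], delay_ms = net$delays_ms[nz])
  write.csv(edges, paste0(prefix, "_edges.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(id = seq_len(net$n_neurons), type = net$types),
            paste0(prefix, "_neurons.csv"), row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname network_io
#' @export
load_structural_network <- function(prefix) {
  edges <- read.csv(paste0(prefix, "_edges.csv"), stringsAsFactors = FALSE)
  neurons <- read.csv(paste0(prefix, "_neurons.csv"), stringsAsFactors = FALSE)
  n <- nrow(neurons)
  swm <- matrix(0, n, n); delays <- matrix(0L, n, n)
  swm[cbind(edges$source, edges$target)] <- edges$weight
  delays[cbind(edges$source, edges$target)] <- as.integer(edges$delay_ms)
  new_structural_network(swm, delays, neurons$type, "loaded", NA)
}
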