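# Independent oracles and fixture generators used across the suite.
# Oracles deliberately take the dumbest correct route (full binned
# convolution, Floyd-Warshall, explicit neighborhood counting) so they share
# no code path with the implementation they check.

# homogeneous Poisson spike train on the sampling grid
poisson_train <- function(rate, duration, fs = 10000) {
  n <- rpois(1, rate * duration)
  sort(unique(round(runif(n, 0, duration) * fs))) / fs
}

poisson_set <- function(n_channels, rate, duration, fs = 10000) {
  sp <- replicate(n_channels, poisson_train(rate, duration, fs), simplify = FALSE)
  names(sp) <- sprintf("ch%03d", seq_len(n_channels))
  spike_train_set(sp, fs, duration)
}

# brute-force normalized correlogram: bin both trains at delta and compute
# the full shifted-product sum for every lag
ncch_oracle <- function(x, y, W, delta, fs = 10000) {
  bw <- delta * fs / 1000
  K <- floor((W / 2) / delta)
  bx <- floor(round(x * fs) / bw + 1e-12)
  by <- floor(round(y * fs) / bw + 1e-12)
  lo <- min(bx, by) - K
  hi <- max(bx, by) + K
  nb <- hi - lo + 1
  X <- tabulate(bx - lo + 1, nbins = nb)
  Y <- tabulate(by - lo + 1, nbins = nb)
  vals <- vapply(-K:K, function(k) {
    idx <- seq_len(nb)
    sh <- idx + k
    ok <- sh >= 1 & sh <= nb
    sum(X[idx[ok]] * Y[sh[ok]])
  }, numeric(1))
  vals / sqrt(length(x) * length(y))
}

# inhibitory pair motif: tonic target with post-reference-spike deletions
inhibitory_motif <- function(duration = 300, fs = 10000, rate_ref = 10,
                             rate_tgt = 25, window_ms = 5) {
  x <- poisson_train(rate_ref, duration, fs)
  y <- poisson_train(rate_tgt, duration, fs)
  for (t in x) y <- y[y <= t | y > t + window_ms / 1000]
  list(x = x, y = y)
}

# excitatory pair motif: shifted copy of the reference train
excitatory_motif <- function(duration = 120, fs = 10000, rate = 3, shift_ms = 5) {
  x <- poisson_train(rate, duration, fs)
  y <- x + shift_ms / 1000
  y <- y[y <= duration]
  list(x = x, y = y)
}

# random simple undirected adjacency matrix
random_adj <- function(n, p) {
  a <- matrix(runif(n * n) < p, n, n)
  a[lower.tri(a, diag = TRUE)] <- FALSE
  a <- a | t(a)
  storage.mode(a) <- "integer"
  a
}

# Watts-Strogatz local clustering by explicit neighborhood counting
cc_oracle <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(x) {
    nb <- which(adj[x, ] == 1)
    v <- length(nb)
    if (v < 2) return(0)
    u <- sum(adj[nb, nb]) / 2
    2 * u / (v * (v - 1))
  }, numeric(1))
}

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
pl_oracle <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  dd <- d[upper.tri(d)]
  fin <- is.finite(dd)
  list(pl = if (any(fin)) mean(dd[fin]) else NaN,
       disconnected_fraction = mean(!fin))
}

# rich-club density among nodes of degree > k by explicit subgraph counting
rcc_oracle <- function(adj, k) {
  deg <- rowSums(adj)
  nodes <- which(deg > k)
  if (length(nodes) < 2) return(NA_real_)
  e <- sum(adj[nodes, nodes]) / 2
  2 * e / (length(nodes) * (length(nodes) - 1))
}

# minimal fcm-shaped object for pruning/validation unit tests
toy_fcm <- function(entity, delays, ids = NULL) {
  n <- nrow(entity)
  if (is.null(ids)) ids <- sprintf("ch%03d", seq_len(n))
  dimnames(entity) <- list(ids, ids)
  dimnames(delays) <- list(ids, ids)
  structure(list(fcm = entity, delays_ms = delays,
                 zero_lag = entity != 0 & delays == 0,
                 channel_ids = ids, params = list(W = 25, delta = 1)),
            class = "fcm")
}

# mirror of the compiled membrane integrator, for the single-neuron oracle
izhikevich_reference <- function(pars, I, duration_ms) {
  v <- -65; u <- pars["b"] * v
  spikes <- integer(0)
  for (t in seq_len(duration_ms) - 1L) {
    v <- v + 0.5 * (0.04 * v * v + 5 * v + 140 - u + I)
    v <- v + 0.5 * (0.04 * v * v + 5 * v + 140 - u + I)
    u <- u + pars["a"] * (pars["b"] * v - u)
    if (v >= 30) {
      spikes <- c(spikes, t)
      v <- pars["c"]; u <- u + pars["d"]
    }
  }
  spikes
}

# bare single-neuron "network" wrapper
isolated_network <- function(n = 5) {
  structure(list(n_neurons = n, swm = matrix(0, n, n),
                 delays_ms = matrix(0L, n, n),
                 types = rep(c("exc", "inh"), c(n - 1, 1)),
                 wiring = "random", seed = NULL),
            class = "structural_network")
}
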