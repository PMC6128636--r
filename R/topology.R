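#' Undirected graph view of a connectivity matrix sign class
#'
#' Directed thresholded connectivity matrices are projected to simple
#' undirected graphs for the topology metrics (a single clustering / path
#' length / small-world value per sign class, with no directed-metric
#' variant): an edge joins two nodes when either directed link of the
#' requested sign exists; self-loops are excluded.
#'
#' @param tcm an `fcm` object or signed matrix.
#' @param sign_class `"all"`, `"excitatory"` or `"inhibitory"`.
#' @param drop_isolated drop nodes with no edge of the class (default TRUE:
#'   topology is computed on the detected subnetwork).
#' @return an igraph undirected simple graph.
#' @export
graph_from_tcm <- function(tcm, sign_class = c("all", "excitatory", "inhibitory"),
                           drop_isolated = TRUE) {
  sign_class <- match.arg(sign_class)
  m <- if (inherits(tcm, "fcm")) tcm$fcm else tcm
  sel <- switch(sign_class, excitatory = m > 0, inhibitory = m < 0, all = m != 0)
  adj <- (sel | t(sel))
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (drop_isolated) g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  g
}

#' Local clustering coefficients and their mean
#'
#' Watts-Strogatz coefficient: per node, the ratio of realized to possible
#' edges among its neighbors (the node itself excluded); nodes with fewer
#' than two neighbors contribute 0 by convention. The mean over all nodes
#' quantifies network segregation.
#'
#' @param graph an igraph undirected simple graph.
#' @return list with `per_node` and `mean`.
#' @export
clustering_coefficient <- function(graph) {
  if (igraph::vcount(graph) == 0) return(list(per_node = numeric(0), mean = NaN))
  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")
  list(per_node = cc, mean = mean(cc))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over connected unordered node pairs.
#' Disconnected pairs are excluded from both numerator and denominator (the
#' textbook formula assumes a connected graph); their fraction is reported.
#'
#' @param graph an igraph undirected graph with at least 2 nodes.
#' @return list with `pl`, `disconnected_fraction`, `n_pairs`.
#' @export
path_length <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2) stop("need at least 2 nodes")
  d <- igraph::distances(graph)
  dd <- d[upper.tri(d)]
  fin <- is.finite(dd)
  if (!any(fin)) stop("no connected pairs")
  list(pl = mean(dd[fin]), disconnected_fraction = mean(!fin),
       n_pairs = sum(fin))
}

surrogate_graph <- function(graph, mode) {
  if (mode == "degree_preserving")
    igraph::rewire(graph, igraph::keeping_degseq(
      niter = max(100, 10 * igraph::ecount(graph))))
  else
    igraph::sample_gnm(igraph::vcount(graph), igraph::ecount(graph))
}

#' Random equivalent surrogate statistics
#'
#' Generates random networks equivalent to the input — by default with the
#' same degree distribution (edge-swap randomization); alternatively only
#' node and edge counts are matched — and averages their clustering
#' coefficient and path length. Graphs too sparse to rewire fall back to the
#' density-matched mode with a warning.
#'
#' @param graph an igraph undirected graph.
#' @param n_surrogates ensemble size (default 100).
#' @param mode `"degree_preserving"` (default) or `"density_matched"`.
#' @return list with `c_rnd`, `l_rnd` (ensemble means), `c_sd`, `l_sd`,
#'   `mode`, `n_surrogates`.
#' @export
random_equivalents <- function(graph, n_surrogates = 100,
                               mode = c("degree_preserving", "density_matched")) {
  mode <- match.arg(mode)
  stopifnot(n_surrogates >= 1)
  if (mode == "degree_preserving" && igraph::ecount(graph) < 2) {
    warning("graph too sparse to rewire; falling back to density_matched")
    mode <- "density_matched"
  }
  cs <- numeric(n_surrogates); ls <- numeric(n_surrogates)
  for (i in seq_len(n_surrogates)) {
    s <- surrogate_graph(graph, mode)
    cs[i] <- clustering_coefficient(s)$mean
    ls[i] <- path_length(s)$pl
  }
  list(c_rnd = mean(cs), l_rnd = mean(ls), c_sd = sd(cs), l_sd = sd(ls),
       mode = mode, n_surrogates = n_surrogates)
}

#' Small-world index
#'
#' `SWI = (C_net / C_rnd) / (L_net / L_rnd)` where the `rnd` terms are
#' ensemble means over random equivalent surrogates. A value well above 1
#' indicates small-world topology (clustered yet short-pathed).
#'
#' @param graph an igraph undirected graph.
#' @param n_surrogates surrogate count (default 100).
#' @param mode see [random_equivalents()].
#' @param surrogates optional precomputed [random_equivalents()] result (or a
#'   list of igraph graphs to use verbatim as the ensemble).
#' @return list of class `small_world_report`: `swi`, `c_net`, `l_net`,
#'   `c_rnd`, `l_rnd`, `n_surrogates`, `mode`.
#' @export
small_world_index <- function(graph, n_surrogates = 100,
                              mode = c("degree_preserving", "density_matched"),
                              surrogates = NULL) {
  mode <- match.arg(mode)
  if (is.null(surrogates)) {
    surrogates <- random_equivalents(graph, n_surrogates, mode)
  } else if (!is.list(surrogates) || is.null(surrogates$c_rnd)) {
    cs <- vapply(surrogates, function(s) clustering_coefficient(s)$mean, numeric(1))
    ls <- vapply(surrogates, function(s) path_length(s)$pl, numeric(1))
    surrogates <- list(c_rnd = mean(cs), l_rnd = mean(ls), mode = "provided",
                       n_surrogates = length(cs))
  }
  c_net <- clustering_coefficient(graph)$mean
  l_net <- path_length(graph)$pl
  if (surrogates$c_rnd == 0 || surrogates$l_rnd == 0)
    stop("degenerate surrogate ensemble (zero clustering or path length)")
  swi <- (c_net / surrogates$c_rnd) / (l_net / surrogates$l_rnd)
  structure(list(swi = swi, c_net = c_net, l_net = l_net,
                 c_rnd = surrogates$c_rnd, l_rnd = surrogates$l_rnd,
                 n_surrogates = surrogates$n_surrogates, mode = surrogates$mode),
            class = "small_world_report")
}

#' @export
print.small_world_report <- function(x, ...) {
  cat(sprintf("SWI = %.3f (C_net %.4f / C_rnd %.4f, L_net %.3f / L_rnd %.3f, %d surrogates, %s)\n",
              x$swi, x$c_net, x$c_rnd, x$l_net, x$l_rnd, x$n_surrogates, x$mode))
  invisible(x)
}

rcc_raw <- function(deg, adj) {
  ks <- seq_len(max(deg))
  out <- lapply(ks, function(k) {
    nodes <- which(deg > k)
    if (length(nodes) < 2) return(NULL)
    e <- sum(adj[nodes, nodes]) / 2
    data.frame(k = k, n_nodes = length(nodes), rcc = 2 * e /
                 (length(nodes) * (length(nodes) - 1)))
  })
  do.call(rbind, out)
}

#' Rich-club coefficient curve with surrogate normalization
#'
#' `RCC(k)` is the edge density among nodes of degree greater than `k`;
#' levels with fewer than two such nodes are undefined and dropped. The raw
#' curve is normalized by its average over random surrogate networks; a
#' maximum normalized value above 1 indicates a privileged highly-connected
#' sub-network (a rich club).
#'
#' @param graph an igraph undirected graph with maximum degree >= 2.
#' @param n_surrogates surrogate count (default 100).
#' @param mode see [random_equivalents()].
#' @return list of class `rich_club_curve`: `curve` (data.frame `k`,
#'   `n_nodes`, `rcc`, `rcc_rnd`, `rcc_norm`), `max_norm`, `k_at_max`,
#'   `rich_club_nodes` (vertex names or indices at the argmax level).
#' @export
rich_club_curve <- function(graph, n_surrogates = 100,
                            mode = c("degree_preserving", "density_matched")) {
  mode <- match.arg(mode)
  deg <- igraph::degree(graph)
  if (max(deg) < 2) stop("maximum degree must be >= 2")
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  curve <- rcc_raw(deg, adj)
  acc <- matrix(NA_real_, n_surrogates, nrow(curve))
  for (i in seq_len(n_surrogates)) {
    s <- surrogate_graph(graph, mode)
    rs <- rcc_raw(igraph::degree(s), igraph::as_adjacency_matrix(s, sparse = FALSE))
    acc[i, ] <- rs$rcc[match(curve$k, rs$k)]
  }
  curve$rcc_rnd <- colMeans(acc, na.rm = TRUE)
  curve$rcc_norm <- curve$rcc / curve$rcc_rnd
  ok <- is.finite(curve$rcc_norm)
  i_max <- which(ok)[which.max(curve$rcc_norm[ok])]
  nodes <- which(deg > curve$k[i_max])
  nm <- igraph::V(graph)$name
  structure(list(curve = curve, max_norm = curve$rcc_norm[i_max],
                 k_at_max = curve$k[i_max],
                 rich_club_nodes = if (!is.null(nm)) nm[nodes] else nodes,
                 mode = mode, n_surrogates = n_surrogates),
            class = "rich_club_curve")
}

#' Small-world index versus electrode density (decimation study)
#'
#' Emulates probing the same preparation with progressively sparser arrays:
#' for each electrode count a maximally uniform spatial subgrid of the layout
#' is selected ([decimate_layout()]), the inference pipeline (correlogram
#' estimation, spatio-temporal filter, hard threshold) is re-run on that
#' channel subset, and the small-world index of the requested sign class is
#' reported. Topology estimates are expected to destabilize below roughly
#' 100 recording sites.
#'
#' @param set a [spike_train_set()].
#' @param layout an [electrode_layout()] covering the channels.
#' @param electrode_counts descending vector of electrode counts.
#' @param sign_class class analyzed (default `"excitatory"`).
#' @param W,delta correlogram parameters.
#' @param params a [pruning_params()].
#' @param n_surrogates surrogates per SWI evaluation.
#' @param ... further arguments to [build_fcm()].
#' @return data.frame with `n_electrodes`, `swi`, `c_net`, `l_net`, `n_links`.
#' @export
decimation_study <- function(set, layout, electrode_counts,
                             sign_class = "excitatory", W = 25, delta = 1,
                             params = pruning_params(), n_surrogates = 100, ...) {
  stopifnot(all(diff(electrode_counts) <= 0))
  rows <- lapply(electrode_counts, function(ne) {
    ids <- decimate_layout(layout, ne)
    keep <- set$channel_ids %in% ids
    sub <- spike_train_set(set$spikes[keep], set$sampling_rate, set$duration,
                           set$channel_ids[keep])
    fc <- build_fcm(sub, W = W, delta = delta, ...)
    fc <- spatiotemporal_filter(fc, layout, params)
    tc <- suppressWarnings(hard_threshold(fc, params))
    g <- graph_from_tcm(tc, sign_class)
    rep <- if (igraph::vcount(g) >= 3 && igraph::ecount(g) >= 2)
      tryCatch(small_world_index(g, n_surrogates), error = function(e) NULL)
    else NULL
    if (is.null(rep))   # too sparse for a stable topology estimate
      return(data.frame(n_electrodes = ne, swi = NA_real_,
                        c_net = if (igraph::vcount(g)) clustering_coefficient(g)$mean else NA_real_,
                        l_net = NA_real_, n_links = igraph::ecount(g)))
    data.frame(n_electrodes = ne, swi = rep$swi, c_net = rep$c_net,
               l_net = rep$l_net, n_links = igraph::ecount(g))
  })
  do.call(rbind, rows)
}
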