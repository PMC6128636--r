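graph_from_adj <- function(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")

test_that("clustering coefficient matches hand-enumerated graphs", {
  k3 <- matrix(1, 3, 3) - diag(3)
  cc <- clustering_coefficient(graph_from_adj(k3))
  expect_equal(cc$per_node, rep(1, 3))
  expect_equal(cc$mean, 1)
  path <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(clustering_coefficient(graph_from_adj(path))$mean, 0)
  # {a-b, b-c, c-a, c-d}: C = (1, 1, 1/3, 0), mean 7/12
  g4 <- matrix(0, 4, 4)
  g4[1, 2] <- g4[2, 3] <- g4[3, 1] <- g4[3, 4] <- 1
  g4 <- g4 + t(g4)
  cc4 <- clustering_coefficient(graph_from_adj(g4))
  expect_equal(cc4$per_node, c(1, 1, 1 / 3, 0))
  expect_equal(cc4$mean, 7 / 12)
})

test_that("path length matches hand-enumerated and oracle values", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(path_length(graph_from_adj(k5))$pl, 1)
  path <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(path_length(graph_from_adj(path))$pl, 4 / 3)
  ring4 <- matrix(0, 4, 4)
  ring4[cbind(1:4, c(2, 3, 4, 1))] <- 1
  ring4 <- ring4 + t(ring4)
  expect_equal(path_length(graph_from_adj(ring4))$pl, pl_oracle(ring4)$pl)
  expect_equal(path_length(graph_from_adj(ring4))$pl, 4 / 3)
  # disconnected pairs excluded and reported
  two <- matrix(0, 4, 4); two[1, 2] <- two[3, 4] <- 1; two <- two + t(two)
  pl <- path_length(graph_from_adj(two))
  expect_equal(pl$pl, 1)
  expect_equal(pl$disconnected_fraction, 4 / 6)
})

test_that("CC/PL/RCC agree with brute-force oracles on random graphs", {
  set.seed(55)
  for (r in 1:60) {
    n <- sample(5:50, 1)
    adj <- random_adj(n, runif(1, 0.05, 0.4))
    g <- graph_from_adj(adj)
    expect_equal(clustering_coefficient(g)$per_node, cc_oracle(adj))
    po <- pl_oracle(adj)
    if (is.finite(po$pl)) {
      got <- path_length(g)
      expect_equal(got$pl, po$pl)
      expect_equal(got$disconnected_fraction, po$disconnected_fraction)
    }
    deg <- rowSums(adj)
    if (max(deg) >= 2) {
      raw <- fncch:::rcc_raw(deg, adj)
      if (!is.null(raw)) for (k in raw$k)
        expect_equal(raw$rcc[raw$k == k], rcc_oracle(adj, k))
    }
  }
})

test_that("rich-club densities on canonical graphs", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(fncch:::rcc_raw(rowSums(k5), k5)$rcc[1], 1)  # K5 at k=1
  # star S5: only the hub has degree > 1 -> level dropped
  s5 <- matrix(0, 6, 6); s5[1, 2:6] <- 1; s5 <- s5 + t(s5)
  raw <- fncch:::rcc_raw(rowSums(s5), s5)
  expect_false(1 %in% raw$k)
  # two K4 cliques joined by one edge, RCC(3) vs oracle
  a <- matrix(0, 8, 8)
  a[1:4, 1:4] <- 1; a[5:8, 5:8] <- 1; diag(a) <- 0; a[4, 5] <- a[5, 4] <- 1
  raw2 <- fncch:::rcc_raw(rowSums(a), a)
  expect_equal(raw2$rcc[raw2$k == 3], rcc_oracle(a, 3))
})

test_that("degree-preserving surrogates keep the degree sequence exactly", {
  set.seed(60)
  g <- graph_from_adj(random_adj(40, 0.15))
  for (r in 1:10) {
    s <- fncch:::surrogate_graph(g, "degree_preserving")
    expect_equal(sort(igraph::degree(s)), sort(igraph::degree(g)))
  }
  s2 <- fncch:::surrogate_graph(g, "density_matched")
  expect_equal(igraph::ecount(s2), igraph::ecount(g))
  expect_equal(igraph::vcount(s2), igraph::vcount(g))
})

test_that("SWI is ~1 on random graphs, >> 1 on a small-world benchmark, and 1 on itself", {
  set.seed(61)
  er <- igraph::sample_gnp(300, 0.05)
  rep_er <- small_world_index(er, n_surrogates = 20)
  expect_lt(abs(rep_er$swi - 1), 0.1)
  ws <- igraph::sample_smallworld(1, 500, 5, 0.05)
  rep_ws <- small_world_index(ws, n_surrogates = 20)
  expect_gt(rep_ws$swi, 3)
  expect_gt(rep_ws$c_net / rep_ws$c_rnd, 3)     # C_net >> C_rnd
  expect_lt(rep_ws$l_net / rep_ws$l_rnd, 2)     # L_net ~ L_rnd
  # identical graph as its own surrogate ensemble
  self <- small_world_index(ws, surrogates = list(ws, ws))
  expect_equal(self$swi, 1)
  # CC and PL (hence SWI's numerator terms) invariant under relabeling
  perm <- igraph::permute(ws, sample(igraph::vcount(ws)))
  expect_equal(clustering_coefficient(perm)$mean, clustering_coefficient(ws)$mean)
  expect_equal(path_length(perm)$pl, path_length(ws)$pl)
})

test_that("normalized rich club of an ER graph stays near 1; planted club found", {
  set.seed(62)
  er <- igraph::sample_gnp(150, 0.08)
  rc <- rich_club_curve(er, n_surrogates = 20)
  ok <- is.finite(rc$curve$rcc_norm) & rc$curve$n_nodes >= 10
  expect_true(all(abs(rc$curve$rcc_norm[ok] - 1) < 0.35))
  # plant a clique among high-degree nodes of a sparse background
  g <- igraph::sample_gnp(100, 0.04)
  hubs <- order(igraph::degree(g), decreasing = TRUE)[1:8]
  for (i in 1:7) for (j in (i + 1):8)
    g <- igraph::add_edges(g, c(hubs[i], hubs[j]))
  g <- igraph::simplify(g)
  rc2 <- rich_club_curve(g, n_surrogates = 20)
  expect_gt(rc2$max_norm, 1)
  expect_true(length(rc2$rich_club_nodes) >= 2)
})

test_that("graph projection from a signed matrix keeps the requested class", {
  ent <- matrix(0, 5, 5)
  ent[1, 2] <- 0.5; ent[2, 1] <- 0.1   # reciprocal exc pair -> single edge
  ent[3, 4] <- -0.2
  fc <- toy_fcm(ent, (ent != 0) * 2)
  ge <- graph_from_tcm(fc, "excitatory")
  expect_equal(igraph::ecount(ge), 1)
  gi <- graph_from_tcm(fc, "inhibitory")
  expect_equal(igraph::ecount(gi), 1)
  ga <- graph_from_tcm(fc, "all", drop_isolated = FALSE)
  expect_equal(igraph::vcount(ga), 5)
  expect_equal(igraph::ecount(ga), 2)
})

test_that("decimation study reproduces the full-set SWI on the identity subset", {
  set.seed(65)
  # small-world spatial network on a 7x7 grid with activity driven by it
  lay <- layout_grid(7, 7, 200)
  n <- 49
  net <- build_random_network(50, in_degree = 10, seed = 65)
  sim <- simulate_network(net, sim_config(duration = 120, seed = 65))
  sp <- sim$spikes$spikes[1:n]
  names(sp) <- lay$channel_id
  set <- spike_train_set(sp, 10000, 120, lay$channel_id)
  tab <- suppressWarnings(
    decimation_study(set, lay, c(49, 25), n_surrogates = 5, min_spikes = 5))
  expect_equal(nrow(tab), 2)
  # identity subset equals the direct pipeline value
  fc <- build_fcm(set, W = 25, delta = 1, min_spikes = 5)
  fc <- spatiotemporal_filter(fc, lay)
  tc <- suppressWarnings(hard_threshold(fc))
  g <- graph_from_tcm(tc, "excitatory")
  expect_equal(tab$n_links[1], igraph::ecount(g))
  if (igraph::vcount(g) > 0)
    expect_equal(tab$c_net[1], clustering_coefficient(g)$mean)
})
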