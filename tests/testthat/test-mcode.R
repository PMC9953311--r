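test_that("highest_k_core handles cliques, trees and the empty graph", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  hk <- highest_k_core(k5)
  expect_identical(hk$k, 4L)
  expect_equal(igraph::vcount(hk$core), 5)

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- letters[1:5]
  expect_identical(highest_k_core(star)$k, 1L)

  expect_identical(highest_k_core(igraph::make_empty_graph(0,
                                                           directed = FALSE))$k,
                   0L)
})

test_that("highest_k_core matches igraph coreness and the subset oracle", {
  for (seed in 1:15) {
    adj <- random_graph(sample(4:8, 1), runif(1, 0.2, 0.7), seed)
    g <- graph_from_adj(adj)
    hk <- highest_k_core(g)
    expect_identical(hk$k, as.integer(max(igraph::coreness(g))))
    bf <- bf_highest_kcore(adj)
    expect_identical(hk$k, bf$k)
    if (hk$k >= 1L)
      expect_setequal(igraph::V(hk$core)$name, rownames(adj)[bf$members])
  }
  # a larger Erdos-Renyi case against iterative pruning via coreness
  set.seed(99)
  g30 <- igraph::sample_gnp(30, 0.2)
  igraph::V(g30)$name <- paste0("v", 1:30)
  hk <- highest_k_core(g30)
  kmax <- max(igraph::coreness(g30))
  expect_identical(hk$k, as.integer(kmax))
  expect_setequal(igraph::V(hk$core)$name,
                  igraph::V(g30)$name[igraph::coreness(g30) >= kmax])
})

test_that("vertex_weight matches hand enumeration on K5 and stars", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(vertex_weight(k5, "a", 2), 4)  # K5 core: k=4, density 1

  star <- igraph::make_star(5, center = 1, mode = "undirected")
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3", "l4")
  expect_equal(vertex_weight(star, "l1", 2), 0)      # leaf below cutoff
  expect_equal(vertex_weight(star, "hub", 2), 0.4)   # k=1, density 8/20
  expect_error(vertex_weight(star, "nope", 2), "not in graph")
})

test_that("vertex weights match the brute-force oracle on random graphs", {
  for (seed in 1:25) {
    n <- sample(4:8, 1)
    adj <- random_graph(n, runif(1, 0.2, 0.8), seed + 1000)
    g <- graph_from_adj(adj)
    for (v in seq_len(n))
      expect_equal(vertex_weight(g, v, 2), bf_vertex_weight(adj, v, 2),
                   tolerance = 1e-12)
  }
})

test_that("find_complexes recovers K6 beside a pendant path", {
  g <- k6_pendant_path()
  mods <- find_complexes(g, mcode_params())
  expect_identical(nrow(mods), 1L)
  expect_equal(mods$score, 6)    # density 1 x 6 vertices
  expect_identical(mods$size, 6L)
  expect_setequal(attr(mods, "modules")[[1]], paste0("k", 1:6))
})

test_that("module score gate is strict and K4 passes only when lowered", {
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- paste0("k", 1:4)
  g <- igraph::add_vertices(g, 4, name = paste0("e", 1:4))
  g <- igraph::add_edges(g, c("e1", "e2", "e3", "e4"))
  expect_identical(nrow(find_complexes(g, mcode_params())), 0L)
  mods <- find_complexes(g, mcode_params(min_module_score = 0))
  expect_identical(nrow(mods), 1L)   # isolated edges have no 2-core
  expect_equal(mods$score, 4)
  expect_setequal(attr(mods, "modules")[[1]], paste0("k", 1:4))
})

test_that("modules are vertex-disjoint with reproducible scores and order", {
  set.seed(17)
  g <- igraph::sample_gnp(60, 0.08)
  igraph::V(g)$name <- sprintf("v%02d", 1:60)
  params <- mcode_params(min_module_score = 0)
  mods <- find_complexes(g, params)
  sets <- attr(mods, "modules")
  expect_identical(anyDuplicated(unlist(sets)), 0L)
  # stored score equals the recomputed density x size of the member set
  for (i in seq_along(sets)) {
    sub <- igraph::induced_subgraph(g, sets[[i]])
    n <- igraph::vcount(sub); e <- igraph::ecount(sub)
    expect_equal(mods$score[i], 2 * e / (n * (n - 1)) * n,
                 tolerance = 1e-12)
  }
  expect_true(all(diff(mods$score) <= 1e-12))
  # deterministic for fixed input
  expect_identical(find_complexes(g, params), mods)
})

test_that("every reported module contains a k-core (exhaustive check, n<=8)", {
  found_any <- FALSE
  for (seed in 1:20) {
    adj <- random_graph(8, runif(1, 0.3, 0.8), seed + 500)
    g <- graph_from_adj(adj)
    mods <- find_complexes(g, mcode_params(min_module_score = 0))
    for (s in attr(mods, "modules")) {
      found_any <- TRUE
      idx <- match(s, rownames(adj))
      expect_true(bf_has_kcore(adj, idx, 2))
    }
  }
  expect_true(found_any)
})

test_that("haircut trims singly-connected module members", {
  # K5 plus one vertex attached by a single edge: the appendage may join the
  # module during expansion but must be cut
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("k", 1:5)
  g <- igraph::add_vertices(g, 1, name = "tail")
  g <- igraph::add_edges(g, c("k1", "tail"))
  mods <- find_complexes(g, mcode_params(min_module_score = 0,
                                         node_score_cutoff = 1))
  expect_false("tail" %in% attr(mods, "modules")[[1]])
  expect_setequal(attr(mods, "modules")[[1]], paste0("k", 1:5))
})

test_that("rank_hubs sorts by degree with lexicographic tie-break", {
  star <- igraph::make_star(6, center = 1, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("l", 1:5))
  expect_identical(rank_hubs(star, 1)$gene, "hub")

  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- c("e", "c", "a", "d", "b")
  rh <- rank_hubs(ring, 10)   # top_k > n returns all
  expect_identical(rh$gene, c("a", "b", "c", "d", "e"))
  expect_true(all(rh$degree == 2L))

  set.seed(23)
  g <- igraph::sample_gnp(40, 0.15)
  igraph::V(g)$name <- sprintf("v%02d", 1:40)
  rh <- rank_hubs(g, 40)
  el <- igraph::as_edgelist(g)
  oracle <- table(factor(c(el[, 1], el[, 2]), levels = igraph::V(g)$name))
  expect_identical(setNames(rh$degree, rh$gene)[names(oracle)],
                   setNames(as.integer(oracle), names(oracle)))
  expect_error(rank_hubs(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("mcode_params validates its invariants", {
  expect_error(mcode_params(degree_cutoff = 0), ">= 1")
  expect_error(mcode_params(node_score_cutoff = 1.2), "\\[0, 1\\]")
  expect_error(mcode_params(k_core = 1), ">= 2")
})
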