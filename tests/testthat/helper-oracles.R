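# Independent brute-force oracles and tiny fixture builders used across the
# suite. Everything here is deliberately naive (subset enumeration, pair
# counting, plain-space summation) and shares no code with the package paths
# it checks.

# tiny expression dataset with explicit values
tiny_dataset <- function(case, control, ids = NULL) {
  case <- as.matrix(case); control <- as.matrix(control)
  m <- cbind(case, control)
  rownames(m) <- if (is.null(ids)) sprintf("f%02d", seq_len(nrow(m))) else ids
  colnames(m) <- c(sprintf("T%d", seq_len(ncol(case))),
                   sprintf("C%d", seq_len(ncol(control))))
  expression_dataset(m, c(rep("TAD", ncol(case)), rep("CON", ncol(control))),
                     case_label = "TAD")
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(letters[seq_len(n)], letters[seq_len(n)])
  adj
}

graph_from_adj <- function(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")

# exhaustive highest k-core: max over nonempty vertex subsets of the minimum
# within-subset degree; the core at that k is the union of all maximising
# subsets
bf_highest_kcore <- function(adj) {
  n <- nrow(adj)
  best_k <- 0L
  members <- seq_len(n)
  if (n > 0) {
    subsets <- lapply(seq_len(2^n - 1), function(m) which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0))
    mindeg <- vapply(subsets, function(s) {
      if (length(s) == 1L) 0L else min(rowSums(adj[s, s, drop = FALSE]))
    }, 0)
    best_k <- max(mindeg)
    members <- sort(unique(unlist(subsets[mindeg == best_k])))
    if (best_k == 0L) members <- seq_len(n)
  }
  list(k = as.integer(best_k), members = members)
}

bf_density <- function(adj, s) {
  if (length(s) < 2L) return(0)
  e <- sum(adj[s, s]) / 2
  2 * e / (length(s) * (length(s) - 1))
}

# brute-force MCODE vertex weight from the adjacency matrix
bf_vertex_weight <- function(adj, v, degree_cutoff = 2L) {
  if (sum(adj[v, ]) < degree_cutoff) return(0)
  nb <- sort(unique(c(v, which(adj[v, ] > 0))))
  sub <- adj[nb, nb, drop = FALSE]
  hk <- bf_highest_kcore(sub)
  if (hk$k == 0L) return(0)
  hk$k * bf_density(sub, hk$members)
}

# does the vertex set contain a nonempty sub-subgraph of min degree >= k?
bf_has_kcore <- function(adj, s, k) {
  s <- as.integer(s)
  if (!length(s)) return(FALSE)
  subsets <- lapply(seq_len(2^length(s) - 1),
                    function(m) s[bitwAnd(m, 2^(seq_along(s) - 1)) > 0])
  any(vapply(subsets, function(ss) {
    length(ss) > 1L && min(rowSums(adj[ss, ss, drop = FALSE])) >= k
  }, logical(1L)))
}

# plain-space hypergeometric upper tail; safe for N <= 1000 in doubles
bf_hypergeom_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# AUC by exhaustive (case, control) pair counting, ties worth one half
bf_auc <- function(scores, is_case) {
  cs <- scores[is_case]; ct <- scores[!is_case]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# K6 with a pendant 3-vertex path hanging off one clique vertex
k6_pendant_path <- function() {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- paste0("k", 1:6)
  g <- igraph::add_vertices(g, 3, name = paste0("p", 1:3))
  igraph::add_edges(g, c("k1", "p1", "p1", "p2", "p2", "p3"))
}

small_sim_config <- function(seed, ...) {
  simulation_config(n_features = c(circ = 300, mir = 200, mrna = 600),
                    n_planted_deg = c(circ = 10, mir = 10, mrna = 20),
                    seed = seed, ...)
}

triplet_key <- function(df)
  sort(paste(df$circRNA, df$miRNA, df$mRNA, sep = "|"))
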