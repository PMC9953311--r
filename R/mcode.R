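#' MCODE parameter set
#'
#' Defaults follow the common Cytoscape-plugin settings used for PPI module
#' mining: degree cutoff 2, node score cutoff 0.2, module 2-core requirement,
#' max expansion depth 100, modules kept when score strictly exceeds 5,
#' haircut on, fluff off.
#'
#' @param degree_cutoff Minimum vertex degree to receive a nonzero weight
#'   (>= 1).
#' @param node_score_cutoff Fraction of the seed weight a neighbour may fall
#'   below and still join the module, in \[0, 1\].
#' @param k_core Every reported module must contain a nonempty k-core of
#'   this order (>= 2).
#' @param max_depth Maximum breadth-first expansion depth from the seed.
#' @param min_module_score Modules with score strictly greater than this are
#'   kept.
#' @param haircut Remove module vertices with fewer than 2 in-module
#'   connections (single pass).
#' @param fluff Expand the module with neighbours whose neighbourhood density
#'   exceeds `fluff_density_cutoff` (applied before haircut, as in the
#'   original algorithm).
#' @param fluff_density_cutoff Density threshold for fluff.
#' @return An `mcode_params` list.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 100L,
                         min_module_score = 5, haircut = TRUE,
                         fluff = FALSE, fluff_density_cutoff = 0.5) {
  if (degree_cutoff < 1) stop("`degree_cutoff` must be >= 1", call. = FALSE)
  if (node_score_cutoff < 0 || node_score_cutoff > 1)
    stop("`node_score_cutoff` must be in [0, 1]", call. = FALSE)
  if (k_core < 2) stop("`k_core` must be >= 2", call. = FALSE)
  if (max_depth < 1) stop("`max_depth` must be >= 1", call. = FALSE)
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth),
                 min_module_score = min_module_score,
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density_cutoff = fluff_density_cutoff),
            class = "mcode_params")
}

graph_density_simple <- function(n_vertices, n_edges) {
  if (n_vertices < 2L) return(0)
  2 * n_edges / (n_vertices * (n_vertices - 1))
}

#' Highest k-core of a graph
#'
#' The k-core is the maximal subgraph in which every vertex has degree >= k.
#' Found by iterative pruning: for increasing k, repeatedly delete vertices
#' of degree < k until stable; the highest k with a nonempty result wins.
#'
#' @param graph Undirected igraph object (possibly empty).
#' @return List with `k` (0 for an empty/edgeless graph) and `core` (the
#'   induced subgraph of the highest k-core).
#' @export
highest_k_core <- function(graph) {
  if (igraph::vcount(graph) == 0L)
    return(list(k = 0L, core = graph))
  best_k <- 0L
  best <- graph
  k <- 1L
  sub <- graph
  repeat {
    repeat {
      deg <- igraph::degree(sub)
      drop <- deg < k
      if (!any(drop)) break
      sub <- igraph::delete_vertices(sub, which(drop))
      if (igraph::vcount(sub) == 0L) break
    }
    if (igraph::vcount(sub) == 0L) break
    best_k <- k
    best <- sub
    k <- k + 1L
  }
  list(k = best_k, core = best)
}

#' MCODE vertex weight (core-clustering coefficient scaled by core order)
#'
#' For a vertex `v` with degree >= `degree_cutoff`, the weight is `k * d`
#' where `k` is the order of the highest k-core of the closed neighbourhood
#' of `v` (v plus its neighbours, induced subgraph) and `d` the density of
#' that core. Vertices below the degree cutoff weigh 0.
#'
#' @param graph Undirected igraph object.
#' @param v Vertex name or index.
#' @param degree_cutoff Minimum degree for a nonzero weight.
#' @return Numeric weight.
#' @export
vertex_weight <- function(graph, v, degree_cutoff = 2L) {
  vid <- if (is.character(v)) which(igraph::V(graph)$name == v) else v
  if (length(vid) != 1L || vid < 1 || vid > igraph::vcount(graph))
    stop("vertex not in graph", call. = FALSE)
  if (igraph::degree(graph, vid) < degree_cutoff) return(0)
  nb <- c(vid, as.integer(igraph::neighbors(graph, vid)))
  sub <- igraph::induced_subgraph(graph, unique(nb))
  hk <- highest_k_core(sub)
  if (hk$k == 0L) return(0)
  hk$k * graph_density_simple(igraph::vcount(hk$core),
                              igraph::ecount(hk$core))
}

all_vertex_weights <- function(graph, degree_cutoff) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(numeric(0))
  vapply(seq_len(n), function(v) vertex_weight(graph, v, degree_cutoff),
         numeric(1L))
}

module_score <- function(graph, vids) {
  sub <- igraph::induced_subgraph(graph, vids)
  graph_density_simple(igraph::vcount(sub), igraph::ecount(sub)) *
    igraph::vcount(sub)
}

#' Detect dense molecular-complex modules (MCODE)
#'
#' Reimplementation of the MCODE algorithm: vertices are weighted by the
#' core-clustering coefficient ([vertex_weight()]); seeds are visited in
#' decreasing weight order (ties broken by vertex name); each module grows
#' breadth-first over unassigned neighbours whose weight is at least
#' `(1 - node_score_cutoff)` times the seed weight, up to `max_depth`;
#' vertices are assigned to at most one module. Post-processing optionally
#' fluffs the module boundary, applies the haircut, requires a nonempty
#' `k_core`-core, and keeps modules whose score (density x size) strictly
#' exceeds `min_module_score`.
#'
#' @param graph Undirected simple igraph object with named vertices.
#' @param params An [mcode_params()] object.
#' @return data.frame with one row per module: `module`, `seed`, `score`,
#'   `size`, `density`, `members` (comma-joined, sorted); ordered by score
#'   descending, ties by size descending then seed name. The per-module
#'   vertex sets are attached as the `"modules"` attribute (list of
#'   character vectors).
#' @export
find_complexes <- function(graph, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  n <- igraph::vcount(graph)
  empty <- data.frame(module = integer(0), seed = character(0),
                      score = numeric(0), size = integer(0),
                      density = numeric(0), members = character(0),
                      stringsAsFactors = FALSE)
  attr(empty, "modules") <- list()
  if (n == 0L) return(empty)
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(n))
  vname <- igraph::V(graph)$name
  w <- all_vertex_weights(graph, params$degree_cutoff)
  adj <- igraph::as_adj_list(graph)

  seed_order <- order(-w, vname)
  assigned <- rep(FALSE, n)
  raw_modules <- list()
  for (seed in seed_order) {
    if (assigned[seed]) next
    threshold <- (1 - params$node_score_cutoff) * w[seed]
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!assigned[u] && w[u] >= threshold) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    raw_modules[[length(raw_modules) + 1L]] <- list(seed = seed,
                                                    members = members)
  }

  finished <- list()
  for (mod in raw_modules) {
    members <- mod$members
    if (params$fluff) {
      boundary <- setdiff(unique(unlist(lapply(members,
                                               function(v) as.integer(adj[[v]])))),
                          members)
      add <- boundary[vapply(boundary, function(u) {
        nb <- unique(c(u, as.integer(adj[[u]])))
        sub <- igraph::induced_subgraph(graph, nb)
        graph_density_simple(igraph::vcount(sub), igraph::ecount(sub)) >
          params$fluff_density_cutoff
      }, logical(1L))]
      members <- c(members, add)
    }
    if (params$haircut && length(members) > 1L) {
      sub <- igraph::induced_subgraph(graph, members)
      keep <- igraph::degree(sub) >= 2
      members <- members[match(igraph::V(sub)$name[keep], vname[members])]
      members <- members[!is.na(members)]
    }
    if (!length(members)) next
    sub <- igraph::induced_subgraph(graph, members)
    core <- sub
    repeat {
      deg <- igraph::degree(core)
      drop <- deg < params$k_core
      if (!any(drop) || igraph::vcount(core) == 0L) break
      core <- igraph::delete_vertices(core, which(drop))
    }
    if (igraph::vcount(core) == 0L) next
    score <- module_score(graph, members)
    if (!(score > params$min_module_score)) next
    finished[[length(finished) + 1L]] <- list(
      seed = vname[mod$seed], members = sort(vname[members]), score = score,
      size = length(members),
      density = graph_density_simple(length(members), igraph::ecount(sub)))
  }
  if (!length(finished)) return(empty)
  tab <- data.frame(
    seed = vapply(finished, `[[`, "", "seed"),
    score = vapply(finished, `[[`, 0, "score"),
    size = vapply(finished, function(x) as.integer(x$size), 0L),
    density = vapply(finished, `[[`, 0, "density"),
    members = vapply(finished, function(x) paste(x$members, collapse = ","),
                     ""),
    stringsAsFactors = FALSE)
  o <- order(-tab$score, -tab$size, tab$seed)
  tab <- tab[o, , drop = FALSE]
  tab <- cbind(module = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  attr(tab, "modules") <- lapply(finished[o], `[[`, "members")
  tab
}

#' Rank hub genes by node degree
#'
#' @param graph Undirected igraph object with named vertices.
#' @param top_k Number of hubs to return; if larger than the vertex count,
#'   all vertices are returned.
#' @return data.frame `gene`, `degree`, sorted by degree descending with
#'   lexicographic tie-break.
#' @export
rank_hubs <- function(graph, top_k = 4L) {
  if (igraph::vcount(graph) == 0L)
    stop("graph is empty", call. = FALSE)
  deg <- igraph::degree(graph)
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_along(deg))
  o <- order(-deg, nm)
  k <- min(top_k, length(deg))
  data.frame(gene = nm[o][seq_len(k)], degree = as.integer(deg[o][seq_len(k)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write MCODE module table and annotated GraphML
#'
#' @param graph The input PPI graph.
#' @param modules Output of [find_complexes()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, named vector of written paths.
#' @export
write_modules <- function(graph, modules, dir, prefix = "mcode") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, paste0(prefix, "_modules.tsv")),
             graphml = file.path(dir, paste0(prefix, ".graphml")))
  utils::write.table(modules, paths[["table"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  membership <- rep(NA_integer_, igraph::vcount(graph))
  sets <- attr(modules, "modules")
  for (i in seq_along(sets))
    membership[match(sets[[i]], igraph::V(graph)$name)] <- i
  g <- igraph::set_vertex_attr(graph, "mcode_module", value = membership)
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  invisible(paths)
}
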