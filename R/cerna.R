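#' Load a target-prediction table
#'
#' Target tables are directed regulator-to-target pair lists with a database
#' provenance tag: columns `source_id`, `target_id`, `database` (TSV with
#' header). Duplicate (source, target, database) rows are collapsed.
#'
#' @param path TSV path.
#' @param kind `"circ_mirna"` (circRNA to miRNA MRE predictions) or
#'   `"mirna_mrna"` (miRNA to mRNA target predictions).
#' @return A `target_table`: data.frame with the three columns plus a `kind`
#'   attribute.
#' @export
load_target_table <- function(path, kind = c("circ_mirna", "mirna_mrna")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  target_table(tab, kind, origin = path)
}

#' Construct a target table from a data.frame
#'
#' @param pairs data.frame with columns `source_id`, `target_id`, `database`.
#' @param kind Relation kind, `"circ_mirna"` or `"mirna_mrna"`.
#' @param origin Optional provenance string used in error messages.
#' @return A `target_table` data.frame.
#' @export
target_table <- function(pairs, kind = c("circ_mirna", "mirna_mrna"),
                         origin = "<data.frame>") {
  kind <- match.arg(kind)
  need <- c("source_id", "target_id", "database")
  if (!all(need %in% names(pairs)))
    stop("target table ", origin, " must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  pairs <- pairs[, need, drop = FALSE]
  bad <- which(!nzchar(pairs$source_id) | !nzchar(pairs$target_id) |
                 is.na(pairs$source_id) | is.na(pairs$target_id))
  if (length(bad))
    stop("empty id in target table ", origin, " at row ", bad[1L],
         call. = FALSE)
  n_in <- nrow(pairs)
  pairs <- unique(pairs)
  if (n_in > nrow(pairs))
    message("target table ", origin, ": dropped ", n_in - nrow(pairs),
            " duplicate rows (", nrow(pairs), " kept)")
  rownames(pairs) <- NULL
  structure(pairs, kind = kind, class = c("target_table", "data.frame"))
}

#' Filter target pairs by multi-database support
#'
#' Keeps (source, target) pairs reported by at least `min_databases`
#' *distinct* database tags. The field convention followed here: mRNA
#' targets of miRNAs must be supported by all three prediction databases
#' (`min_databases = 3`), while circRNA-to-miRNA MRE predictions from the
#' two circRNA resources are merged by union (`min_databases = 1`).
#'
#' @param table A [target_table()].
#' @param min_databases Minimum distinct database count (>= 1).
#' @return data.frame with columns `source_id`, `target_id`, `n_databases`.
#' @export
intersect_database_support <- function(table, min_databases = 1L) {
  if (!is.numeric(min_databases) || min_databases < 1)
    stop("`min_databases` must be >= 1", call. = FALSE)
  if (nrow(table) == 0L)
    return(data.frame(source_id = character(0), target_id = character(0),
                      n_databases = integer(0), stringsAsFactors = FALSE))
  key <- paste(table$source_id, table$target_id, sep = "\r")
  ndb <- tapply(table$database, key, function(d) length(unique(d)))
  keep <- names(ndb)[ndb >= min_databases]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(source_id = vapply(parts, `[`, "", 1L),
                    target_id = vapply(parts, `[`, "", 2L),
                    n_databases = as.integer(ndb[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$source_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Venn-style co-RNA derivation
#'
#' Plain set intersection between a differentially-expressed id set and a
#' predicted-target id set. Used twice in the pipeline: co-miRNAs = DEG
#' miRNAs intersected with targets of DEG circRNAs; co-mRNAs = DEG mRNAs
#' intersected with database-supported targets of the co-miRNAs.
#'
#' @param deg_ids Character vector of differentially expressed feature ids.
#' @param predicted_target_ids Character vector of predicted target ids.
#' @param normalize Optional id-normalization function applied to both sides
#'   (e.g. [normalize_mirna_id]); default `NULL` = case-sensitive exact match.
#' @return Sorted character vector of co-ids.
#' @export
derive_co_set <- function(deg_ids, predicted_target_ids, normalize = NULL) {
  if (!is.null(normalize)) {
    deg_ids <- normalize(deg_ids)
    predicted_target_ids <- normalize(predicted_target_ids)
  }
  sort(intersect(unique(deg_ids), unique(predicted_target_ids)))
}

#' Normalize miRNA-style identifiers
#'
#' Optional hook for [derive_co_set()] and table loading: trims whitespace
#' and lower-cases the `miR`/`mir` prefix so `hsa-miR-1271-5p` and
#' `hsa-mir-1271-5p` match. Off by default everywhere.
#'
#' @param ids Character vector.
#' @return Normalized ids.
#' @export
normalize_mirna_id <- function(ids) {
  ids <- trimws(ids)
  sub("^((hsa|mmu|rno)-)?miR", "\\1mir", ids, ignore.case = FALSE)
}

#' Assemble the tripartite ceRNA network
#'
#' Enumerates all (circRNA, miRNA, mRNA) triplets such that the circRNA is a
#' DEG, the miRNA is a co-miRNA targeted by that circRNA, the mRNA is a
#' co-mRNA with a database-supported miRNA-to-mRNA link. Node sets
#' (ce-circRNAs, ce-miRNAs, ce-mRNAs) are derived from the triplets only, so
#' every node participates in at least one complete triplet.
#'
#' @param deg_circ,deg_mirna,deg_mrna DEG tables per layer (output of
#'   [filter_degs()]; columns `id`, `direction` used).
#' @param circ_mi_pairs data.frame of circRNA-to-miRNA pairs (columns
#'   `source_id`, `target_id`), already union-merged across the circRNA
#'   databases (see [intersect_database_support()] with `min_databases = 1`).
#' @param mi_m_pairs data.frame of database-supported miRNA-to-mRNA pairs
#'   (columns `source_id`, `target_id`).
#' @return A `cerna_network`: list with `triplets` (data.frame circRNA,
#'   miRNA, mRNA), `nodes` (data.frame id, layer, direction) and the
#'   intermediate `co_mirnas`, `co_mrnas` sets.
#' @export
assemble_network <- function(deg_circ, deg_mirna, deg_mrna,
                             circ_mi_pairs, mi_m_pairs) {
  circ_ids <- unique(deg_circ$id)
  # restrict the MRE predictions to DEG circRNAs, then Venn against DEG miRNAs
  cm <- circ_mi_pairs[circ_mi_pairs$source_id %in% circ_ids, , drop = FALSE]
  co_mirnas <- derive_co_set(deg_mirna$id, cm$target_id)
  mm <- mi_m_pairs[mi_m_pairs$source_id %in% co_mirnas, , drop = FALSE]
  co_mrnas <- derive_co_set(deg_mrna$id, mm$target_id)

  cm <- cm[cm$target_id %in% co_mirnas, , drop = FALSE]
  mm <- mm[mm$target_id %in% co_mrnas, , drop = FALSE]
  if (nrow(cm) && nrow(mm)) {
    trip <- merge(
      data.frame(circRNA = cm$source_id, miRNA = cm$target_id,
                 stringsAsFactors = FALSE),
      data.frame(miRNA = mm$source_id, mRNA = mm$target_id,
                 stringsAsFactors = FALSE),
      by = "miRNA")[, c("circRNA", "miRNA", "mRNA")]
    trip <- unique(trip)
    trip <- trip[order(trip$circRNA, trip$miRNA, trip$mRNA), , drop = FALSE]
    rownames(trip) <- NULL
  } else {
    trip <- data.frame(circRNA = character(0), miRNA = character(0),
                       mRNA = character(0), stringsAsFactors = FALSE)
  }
  new_cerna_network(trip, deg_circ, deg_mirna, deg_mrna,
                    co_mirnas = co_mirnas, co_mrnas = co_mrnas)
}

new_cerna_network <- function(triplets, deg_circ, deg_mirna, deg_mrna,
                              co_mirnas = NULL, co_mrnas = NULL) {
  dirmap <- function(deg) stats::setNames(deg$direction, deg$id)
  dirs <- c(dirmap(deg_circ), dirmap(deg_mirna), dirmap(deg_mrna))
  node_df <- function(ids, layer)
    data.frame(id = sort(unique(ids)), layer = rep(layer, length(unique(ids))),
               stringsAsFactors = FALSE)
  nodes <- rbind(node_df(triplets$circRNA, "circRNA"),
                 node_df(triplets$miRNA, "miRNA"),
                 node_df(triplets$mRNA, "mRNA"))
  nodes$direction <- unname(dirs[nodes$id])
  structure(list(triplets = triplets, nodes = nodes,
                 co_mirnas = co_mirnas, co_mrnas = co_mrnas,
                 deg_tables = list(circRNA = deg_circ, miRNA = deg_mirna,
                                   mRNA = deg_mrna)),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  n <- table(factor(x$nodes$layer, levels = c("circRNA", "miRNA", "mRNA")))
  cat("cerna_network:", nrow(x$triplets), "triplets;",
      n[["circRNA"]], "ce-circRNAs,", n[["miRNA"]], "ce-miRNAs,",
      n[["mRNA"]], "ce-mRNAs\n")
  invisible(x)
}

#' Direction-consistency filter for sponge triplets
#'
#' Keeps triplets showing the canonical sponge expression pattern:
#' circRNA and mRNA change in the same direction while the shared miRNA
#' changes in the opposite direction (e.g. circRNA down, miRNA up, mRNA
#' down in cases). Off by default in the pipeline; the pattern is used for
#' axis selection rather than network construction.
#'
#' @param network A `cerna_network` from [assemble_network()].
#' @return The filtered `cerna_network` (node sets recomputed).
#' @export
direction_consistency_filter <- function(network) {
  trip <- network$triplets
  dirs <- stats::setNames(network$nodes$direction, network$nodes$id)
  need <- unique(unlist(trip[, c("circRNA", "miRNA", "mRNA")]))
  missing <- need[!need %in% names(dirs) | is.na(dirs[need])]
  if (length(missing))
    stop("nodes missing a DEG direction: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  sgn <- function(d) ifelse(dirs[d] == "up", 1L, -1L)
  keep <- sgn(trip$circRNA) == sgn(trip$mRNA) &
    sgn(trip$miRNA) == -sgn(trip$circRNA)
  trip <- trip[keep, , drop = FALSE]
  rownames(trip) <- NULL
  new_cerna_network(trip, network$deg_tables$circRNA,
                    network$deg_tables$miRNA, network$deg_tables$mRNA,
                    co_mirnas = network$co_mirnas,
                    co_mrnas = network$co_mrnas)
}

#' Convert a ceRNA network to an igraph object
#'
#' Tripartite undirected graph with node attributes `layer` and `direction`;
#' edges are the circRNA-miRNA and miRNA-mRNA links of the triplets.
#'
#' @param network A `cerna_network`.
#' @return An igraph object.
#' @export
cerna_igraph <- function(network) {
  trip <- network$triplets
  edges <- unique(rbind(
    data.frame(from = trip$circRNA, to = trip$miRNA,
               stringsAsFactors = FALSE),
    data.frame(from = trip$miRNA, to = trip$mRNA,
               stringsAsFactors = FALSE)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = network$nodes)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

#' Write ceRNA network outputs (node TSV, triplet TSV, GraphML, SIF)
#'
#' @param network A `cerna_network`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, named vector of written paths.
#' @export
write_cerna_network <- function(network, dir, prefix = "cerna") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(nodes = file.path(dir, paste0(prefix, "_nodes.tsv")),
             triplets = file.path(dir, paste0(prefix, "_triplets.tsv")),
             graphml = file.path(dir, paste0(prefix, ".graphml")),
             sif = file.path(dir, paste0(prefix, ".sif")))
  utils::write.table(network$nodes, paths[["nodes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(network$triplets, paths[["triplets"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- cerna_igraph(network)
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  write_sif(g, paths[["sif"]], interaction = "targets")
  invisible(paths)
}
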