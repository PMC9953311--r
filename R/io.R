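#' Read an expression matrix TSV plus its sample-group TSV
#'
#' Expression file: first column feature id, remaining columns one per
#' sample, tab-separated with header. Group file: two columns
#' `sample<TAB>group` with header, labels typically `"TAD"`/`"CON"`.
#'
#' @param exprs_path Path to the expression TSV.
#' @param groups_path Path to the sample-to-group TSV.
#' @param case_label Passed to [expression_dataset()].
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(exprs_path, groups_path, case_label = NULL) {
  tab <- utils::read.delim(exprs_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression file must have a feature-id column plus samples: ",
         exprs_path, call. = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1L]])
  grp <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (ncol(grp) < 2L)
    stop("group file must have columns sample, group: ", groups_path,
         call. = FALSE)
  gmap <- stats::setNames(as.character(grp[[2L]]), as.character(grp[[1L]]))
  missing <- setdiff(colnames(mat), names(gmap))
  if (length(missing))
    stop("samples missing from group file: ",
         paste(missing, collapse = ", "), call. = FALSE)
  expression_dataset(mat, gmap[colnames(mat)], case_label = case_label)
}

#' Write an expression dataset as TSV (matrix + group file)
#'
#' @param dataset An [expression_dataset()].
#' @param exprs_path,groups_path Output paths.
#' @return Invisibly, `c(exprs_path, groups_path)`.
#' @export
write_expression_tsv <- function(dataset, exprs_path, groups_path) {
  df <- data.frame(feature_id = rownames(dataset$exprs),
                   dataset$exprs, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, exprs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gdf <- data.frame(sample = colnames(dataset$exprs),
                    group = as.character(dataset$group),
                    stringsAsFactors = FALSE)
  utils::write.table(gdf, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(exprs_path, groups_path))
}

#' Read a GEO series-matrix-style expression file
#'
#' Accepts the tab-separated series-matrix dialect: metadata lines prefixed
#' `!`, an optional `!series_matrix_table_begin` / `!series_matrix_table_end`
#' fence around the data block, quoted sample ids in the header, first
#' column `ID_REF`. Group labels are not parsed from metadata (GEO encodes
#' them inconsistently); supply them via a group TSV or the `group` argument.
#'
#' @param path Series-matrix TSV (uncompressed).
#' @param group Character vector of group labels, one per sample column, or
#'   `NULL` to return just the matrix.
#' @param case_label Passed to [expression_dataset()] when `group` is given.
#' @return An [expression_dataset()] if `group` is supplied, otherwise the
#'   numeric matrix.
#' @export
read_series_matrix <- function(path, group = NULL, case_label = NULL) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) == 1L && length(end) == 1L) {
    lines <- lines[(begin + 1L):(end - 1L)]
  } else {
    lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  tab <- utils::read.delim(text = lines, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1L]])
  if (is.null(group)) return(mat)
  expression_dataset(mat, group, case_label = case_label)
}

#' Read an undirected interaction network from SIF or edge-list TSV
#'
#' SIF lines are `node1<TAB>interaction<TAB>node2`; edge lists are
#' two-or-more column TSVs (STRING export style: optional header recognised
#' by the names `node1`/`protein1`/`source`, extra columns ignored).
#' Self-loops are dropped and duplicate undirected edges collapsed.
#'
#' @param path Input file.
#' @param format `"auto"` (default: `.sif` extension means SIF), `"sif"` or
#'   `"edgelist"`.
#' @return An undirected simple [igraph::graph] object.
#' @export
read_ppi <- function(path, format = c("auto", "sif", "edgelist")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif"
              else "edgelist"
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(igraph::make_empty_graph(0, directed = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "sif") {
    # single-token lines are isolated vertices; >= 3 tokens are
    # node <interaction> target [target ...]; 2 tokens are malformed
    bad <- which(vapply(parts, length, 0L) == 2L)
    if (length(bad))
      stop("malformed SIF line ", bad[1L], " in ", path, call. = FALSE)
    iso <- unlist(lapply(parts[vapply(parts, length, 0L) == 1L], `[`, 1L))
    eparts <- parts[vapply(parts, length, 0L) >= 3L]
    edges <- do.call(rbind, lapply(eparts, function(x)
      cbind(x[1L], x[3:length(x)])))
    if (is.null(edges)) edges <- matrix(character(0), 0, 2)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    iso <- setdiff(iso, igraph::V(g)$name)
    if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
    return(igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE))
  } else {
    header_names <- tolower(parts[[1L]][1:2])
    if (any(header_names %in% c("node1", "protein1", "source", "from")))
      parts <- parts[-1L]
    bad <- which(vapply(parts, length, 0L) < 2L)
    if (length(bad))
      stop("malformed edge-list line in ", path, call. = FALSE)
    edges <- t(vapply(parts, function(x) x[1:2], character(2L)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as SIF
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @param interaction Interaction type string for the middle column.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(graph, path, interaction = "pp") {
  el <- igraph::as_edgelist(graph)
  lines <- if (nrow(el)) paste(el[, 1L], interaction, el[, 2L], sep = "\t")
           else character(0)
  # isolated vertices are preserved as single-token SIF lines
  iso <- igraph::V(graph)$name[igraph::degree(graph) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT: one set per line, `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @return A `gene_set_collection` (see [gene_set_collection()]).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], " (need term, description, >=1 gene)",
         call. = FALSE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  desc <- vapply(parts, `[`, "", 2L)
  gene_set_collection(sets, descriptions = stats::setNames(desc, names(sets)))
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
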