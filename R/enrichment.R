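#' Gene-set collection
#'
#' Named gene sets with descriptions and an explicit background universe.
#' The universe defaults to the union of all set members; sets are restricted
#' to the universe and emptied sets dropped.
#'
#' @param sets Named list of character vectors (term id -> member genes).
#' @param descriptions Optional named character vector of term descriptions.
#' @param universe Optional character vector of background gene ids.
#' @return A `gene_set_collection`: list with `sets`, `descriptions`,
#'   `universe`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, intersect, y = universe)
  keep <- lengths(sets) > 0L
  sets <- sets[keep]
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  descriptions <- descriptions[names(sets)]
  descriptions[is.na(descriptions)] <- names(sets)[is.na(descriptions)]
  structure(list(sets = sets,
                 descriptions = stats::setNames(as.character(descriptions),
                                                names(sets)),
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets over a universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Upper-tail hypergeometric probability, log-space
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' universe of `N` containing `K` annotated genes, the probability of seeing
#' `k` or more annotated genes. Summed in log space (lchoose + log-sum-exp)
#' for numerical stability at large N.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Annotated-set size.
#' @param n Query size.
#' @param N Universe size.
#' @return Probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(K, n); ",
         "K, n <= N)", call. = FALSE)
  if (k == 0) return(1)
  i <- k:min(K, n)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, exp(log_sum_exp(lp)))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set in a collection for over-representation in a query
#' gene list using the upper-tail hypergeometric distribution over the
#' collection's universe. Query genes outside the universe are dropped with
#' a warning. Only sets with overlap `k >= min_count` enter the result (and
#' the BH family).
#'
#' @param query Character vector of query gene ids.
#' @param collection A [gene_set_collection()].
#' @param min_count Minimum overlap to report a term (default 2).
#' @return data.frame sorted by p: `term`, `description`, `count`,
#'   `set_size`, `query_size`, `universe_size`, `p`, `adj_p`, `genes`
#'   (comma-joined overlap).
#' @export
enrich <- function(query, collection, min_count = 2L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(length(outside), " query genes not in the universe were dropped",
            call. = FALSE)
    query <- intersect(query, collection$universe)
  }
  if (!length(query))
    stop("query is empty after restriction to the universe", call. = FALSE)
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(term) {
    members <- collection$sets[[term]]
    ov <- intersect(query, members)
    k <- length(ov)
    if (k < min_count) return(NULL)
    data.frame(term = term,
               description = unname(collection$descriptions[[term]]),
               count = k, set_size = length(members), query_size = n,
               universe_size = N,
               p = hypergeom_upper_tail(k, length(members), n, N),
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(term = character(0), description = character(0),
                      count = integer(0), set_size = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p = numeric(0), adj_p = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$term),
             c("term", "description", "count", "set_size", "query_size",
               "universe_size", "p", "adj_p", "genes")]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param result Output of [enrich()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
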