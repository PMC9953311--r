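#' Pipeline configuration
#'
#' Collects the inputs and tuning parameters for a full run: per-layer
#' expression/group TSV paths, the two target tables, the PPI graph, an
#' optional GMT collection, thresholds and flags. Can be built in code or
#' loaded from JSON ([read_pipeline_config()]).
#'
#' @param circ_exprs,circ_groups,mir_exprs,mir_groups,mrna_exprs,mrna_groups
#'   Paths to the per-layer expression and group TSVs.
#' @param targets_circ_mi,targets_mi_m Paths to the circRNA-miRNA and
#'   miRNA-mRNA target tables.
#' @param ppi Path to the PPI graph (SIF or edge list).
#' @param gene_sets Optional GMT path (`NULL` skips enrichment).
#' @param out_dir Output directory.
#' @param thresholds A [deg_thresholds()] applied to all three layers, or a
#'   named list (`circ`, `mir`, `mrna`) of them.
#' @param dge_method `"moderated"` or `"welch"`.
#' @param min_databases Distinct-database support required for miRNA-mRNA
#'   pairs (default 3, the all-three-databases rule).
#' @param direction_filter Apply [direction_consistency_filter()] to the
#'   assembled network (default off).
#' @param mcode A [mcode_params()] object.
#' @param top_hubs How many hub genes to rank by degree (default 4).
#' @param enrich_query `"hubs"` (default) or `"module"`: enrich the top hub
#'   genes or the members of the top MCODE module.
#' @param roc_genes Genes (mRNA layer) to evaluate as single-gene ROC
#'   biomarkers; `"hubs"` (default) uses the ranked hub genes.
#' @param circ_whitelist Optional character vector restricting the DEG
#'   circRNAs carried into network assembly (the upstream studies sometimes
#'   hand-pick a subset; the rule is the user's, not the package's).
#' @param seed Integer seed echoed into the report (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(circ_exprs, circ_groups, mir_exprs, mir_groups,
                            mrna_exprs, mrna_groups, targets_circ_mi,
                            targets_mi_m, ppi, gene_sets = NULL,
                            out_dir = "cernet_out",
                            thresholds = deg_thresholds(),
                            dge_method = c("moderated", "welch"),
                            min_databases = 3L, direction_filter = FALSE,
                            mcode = mcode_params(), top_hubs = 4L,
                            enrich_query = c("hubs", "module"),
                            roc_genes = "hubs", circ_whitelist = NULL,
                            seed = 1L) {
  dge_method <- match.arg(dge_method)
  enrich_query <- match.arg(enrich_query)
  if (inherits(thresholds, "deg_thresholds"))
    thresholds <- list(circ = thresholds, mir = thresholds, mrna = thresholds)
  stopifnot(all(c("circ", "mir", "mrna") %in% names(thresholds)))
  structure(list(
    paths = list(circ_exprs = circ_exprs, circ_groups = circ_groups,
                 mir_exprs = mir_exprs, mir_groups = mir_groups,
                 mrna_exprs = mrna_exprs, mrna_groups = mrna_groups,
                 targets_circ_mi = targets_circ_mi,
                 targets_mi_m = targets_mi_m, ppi = ppi,
                 gene_sets = gene_sets),
    out_dir = out_dir, thresholds = thresholds, dge_method = dge_method,
    min_databases = as.integer(min_databases),
    direction_filter = isTRUE(direction_filter), mcode = mcode,
    top_hubs = as.integer(top_hubs), enrich_query = enrich_query,
    roc_genes = roc_genes, circ_whitelist = circ_whitelist,
    seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Build a pipeline configuration for a fixture bundle directory
#'
#' Convenience wrapper mapping the file names written by
#' [write_fixture_bundle()] onto [pipeline_config()].
#'
#' @param fixture_dir Directory written by [write_fixture_bundle()].
#' @param out_dir Output directory (default: `<fixture_dir>/out`).
#' @param ... Further arguments to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_for_bundle <- function(fixture_dir,
                                       out_dir = file.path(fixture_dir,
                                                           "out"),
                                       ...) {
  p <- function(f) file.path(fixture_dir, f)
  pipeline_config(
    circ_exprs = p("exprs_circ.tsv"), circ_groups = p("groups_circ.tsv"),
    mir_exprs = p("exprs_mir.tsv"), mir_groups = p("groups_mir.tsv"),
    mrna_exprs = p("exprs_mrna.tsv"), mrna_groups = p("groups_mrna.tsv"),
    targets_circ_mi = p("targets_circ_mir.tsv"),
    targets_mi_m = p("targets_mir_mrna.tsv"),
    ppi = p("ppi.sif"), gene_sets = p("gene_sets.gmt"),
    out_dir = out_dir, ...)
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors the [pipeline_config()] arguments; nested objects
#' `thresholds` and `mcode` override individual defaults of
#' [deg_thresholds()] and [mcode_params()].
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- do.call(deg_thresholds, as.list(raw$thresholds))
  mc <- do.call(mcode_params, as.list(raw$mcode))
  args <- raw[setdiff(names(raw), c("thresholds", "mcode"))]
  do.call(pipeline_config, c(args, list(thresholds = thr, mcode = mc)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full ceRNA discovery pipeline
#'
#' Executes differential expression on the three layers, ceRNA network
#' assembly (co-miRNA / co-mRNA derivation, database-support filtering,
#' triplet enumeration, optional direction filter), MCODE module detection
#' and hub ranking on the PPI graph restricted to ce-mRNAs' neighbourhood,
#' hypergeometric enrichment of the hub or module genes, and single-gene ROC
#' diagnostics, persisting every intermediate as TSV under
#' `config$out_dir` plus a machine-readable `run_report.json`.
#'
#' On a stage failure the run aborts with the stage name; outputs written so
#' far are retained and a `FAILED` marker file records the stage and cause.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out, "pipeline.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }
  on_fail <- function(e) {
    writeLines(conditionMessage(e), file.path(out, "FAILED"))
    stop(e)
  }

  report <- tryCatch({
    layers <- c("circ", "mir", "mrna")
    degs <- list(); dge_tabs <- list()
    for (l in layers) {
      ds <- stage(paste0("dge_", l), read_expression_tsv(
        config$paths[[paste0(l, "_exprs")]],
        config$paths[[paste0(l, "_groups")]]))
      tab <- stage(paste0("dge_", l),
                   test_differential(ds, method = config$dge_method))
      dge_tabs[[l]] <- tab
      degs[[l]] <- filter_degs(tab, config$thresholds[[l]])
      write_tsv(tab, file.path(out, paste0("dge_", l, ".tsv")))
      logmsg("dge[", l, "]: ", nrow(tab), " features -> ", nrow(degs[[l]]),
             " DEGs")
    }
    if (!is.null(config$circ_whitelist))
      degs$circ <- degs$circ[degs$circ$id %in% config$circ_whitelist, ,
                             drop = FALSE]
    for (l in layers)
      write_tsv(degs[[l]], file.path(out, paste0("deg_", l, ".tsv")))

    tt_cm <- stage("cerna", load_target_table(config$paths$targets_circ_mi,
                                              "circ_mirna"))
    tt_mm <- stage("cerna", load_target_table(config$paths$targets_mi_m,
                                              "mirna_mrna"))
    cm_pairs <- intersect_database_support(tt_cm, min_databases = 1L)
    mm_pairs <- intersect_database_support(tt_mm,
                                           min_databases = config$min_databases)
    network <- stage("cerna", assemble_network(degs$circ, degs$mir,
                                               degs$mrna, cm_pairs, mm_pairs))
    if (config$direction_filter)
      network <- stage("cerna", direction_consistency_filter(network))
    net_paths <- write_cerna_network(network, out)
    logmsg("cerna: ", nrow(network$triplets), " triplets (",
           length(network$co_mirnas), " co-miRNAs, ",
           length(network$co_mrnas), " co-mRNAs)")

    ppi <- stage("modules", read_ppi(config$paths$ppi))
    modules <- stage("modules", find_complexes(ppi, config$mcode))
    write_modules(ppi, modules, out)
    # hub genes are ranked within the top module, whose members carry the
    # signal; degree ties are broken lexicographically
    hub_graph <- if (nrow(modules))
      igraph::induced_subgraph(ppi, attr(modules, "modules")[[1L]])
    else ppi
    hubs <- stage("modules", rank_hubs(hub_graph, config$top_hubs))
    write_tsv(hubs, file.path(out, "hub_genes.tsv"))
    logmsg("modules: ", nrow(modules), " modules; top hubs: ",
           paste(hubs$gene, collapse = ", "))

    enr <- NULL
    if (!is.null(config$paths$gene_sets)) {
      gsc <- stage("enrich", read_gmt(config$paths$gene_sets))
      query <- if (config$enrich_query == "hubs") hubs$gene
               else if (nrow(modules)) attr(modules, "modules")[[1L]]
               else character(0)
      query <- intersect(query, gsc$universe)
      if (length(query)) {
        enr <- stage("enrich", enrich(query, gsc))
        write_tsv(enr, file.path(out, "enrichment.tsv"))
        logmsg("enrich: ", nrow(enr), " terms for ", length(query),
               " query genes")
      } else {
        logmsg("enrich: skipped (empty query after universe restriction)")
      }
    }

    mrna_ds <- read_expression_tsv(config$paths$mrna_exprs,
                                   config$paths$mrna_groups)
    roc_genes <- if (identical(config$roc_genes, "hubs")) hubs$gene
                 else config$roc_genes
    roc_genes <- intersect(roc_genes, rownames(mrna_ds$exprs))
    rocs <- lapply(roc_genes, function(g) {
      r <- stage("roc", roc_auc(mrna_ds$exprs[g, ],
                                as.character(mrna_ds$group),
                                case_label = mrna_ds$case_label))
      write_roc(r, file.path(out, paste0("roc_", g, "_points.tsv")),
                file.path(out, paste0("roc_", g, ".json")))
      list(gene = g, auc = r$auc, p = r$p, orientation = r$orientation)
    })
    if (length(rocs))
      logmsg("roc: ", paste(sprintf("%s AUC=%.3f",
                                    vapply(rocs, `[[`, "", "gene"),
                                    vapply(rocs, `[[`, 0, "auc")),
                            collapse = "; "))

    report <- list(
      package_version = as.character(utils::packageVersion("cernet")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = config$seed,
      counts = list(
        features = lapply(dge_tabs, nrow),
        degs = lapply(degs, nrow),
        co_mirnas = length(network$co_mirnas),
        co_mrnas = length(network$co_mrnas),
        ce_circRNAs = sum(network$nodes$layer == "circRNA"),
        ce_miRNAs = sum(network$nodes$layer == "miRNA"),
        ce_mRNAs = sum(network$nodes$layer == "mRNA"),
        triplets = nrow(network$triplets),
        modules = nrow(modules),
        enriched_terms = if (is.null(enr)) 0L else nrow(enr)),
      hubs = hubs,
      top_module = if (nrow(modules))
        list(score = modules$score[1L], size = modules$size[1L],
             members = attr(modules, "modules")[[1L]]) else NULL,
      roc = rocs,
      config = list(dge_method = config$dge_method,
                    min_databases = config$min_databases,
                    direction_filter = config$direction_filter,
                    thresholds = lapply(config$thresholds, unclass),
                    mcode = unclass(config$mcode),
                    top_hubs = config$top_hubs))
    audit_report(report, out)
    jsonlite::write_json(report, file.path(out, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    report
  }, error = on_fail)
  invisible(report)
}

# self-consistency: report counts must equal emitted table row counts
audit_report <- function(report, out) {
  check <- function(count, file) {
    n <- nrow(utils::read.delim(file.path(out, file)))
    if (n != count)
      stop("run-report audit failed: ", file, " has ", n,
           " rows but report says ", count, call. = FALSE)
  }
  check(report$counts$triplets, "cerna_triplets.tsv")
  check(report$counts$modules, "mcode_modules.tsv")
  for (l in c("circ", "mir", "mrna"))
    check(report$counts$degs[[l]], paste0("deg_", l, ".tsv"))
  invisible(TRUE)
}
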