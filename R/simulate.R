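#' Simulation configuration for the synthetic ceRNA study
#'
#' Describes a three-layer (circRNA / miRNA / mRNA) case-control study with
#' planted differential features and planted sponge axes. Defaults mirror
#' the cohort shapes of the small aortic-dissection microarray studies this
#' emulates: 3 vs 3 circRNA samples, 6 vs 5 miRNA samples, 7 vs 5 mRNA
#' samples, log2 intensities around a baseline of 8 with Gaussian noise.
#'
#' @param n_case,n_control Named numeric vectors (`circ`, `mir`, `mrna`) of
#'   case/control sample counts per layer.
#' @param n_features Named numeric vector of feature counts per layer.
#' @param baseline_mean,baseline_sd Log2 baseline intensity and noise SD.
#' @param effect_size Log2 fold-change magnitude planted into case samples
#'   (>= 0; 0 gives a global-null dataset).
#' @param n_planted_deg Named numeric vector of planted DEG counts per layer.
#' @param n_planted_axes Number of planted circRNA-miRNA-mRNA sponge axes;
#'   each axis uses one planted-down circRNA, one planted-up miRNA and one
#'   planted-down mRNA, with both links wired into the target tables (the
#'   miRNA-mRNA link in all three simulated databases).
#' @param db_overlap_prob Probability that any one of the three simulated
#'   miRNA-target databases reports a given background pair.
#' @param decoy_pair_rate Probability that a random cross-layer pair becomes
#'   a background (decoy) target pair.
#' @param seed Integer RNG seed; identical seeds give identical datasets.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_case = c(circ = 3, mir = 6, mrna = 7),
                              n_control = c(circ = 3, mir = 5, mrna = 5),
                              n_features = c(circ = 1000, mir = 500,
                                             mrna = 2000),
                              baseline_mean = 8, baseline_sd = 0.3,
                              effect_size = 2,
                              n_planted_deg = c(circ = 20, mir = 20,
                                                mrna = 40),
                              n_planted_axes = 5,
                              db_overlap_prob = 0.5,
                              decoy_pair_rate = 0.01,
                              seed = 1L) {
  layers <- c("circ", "mir", "mrna")
  for (v in list(n_case, n_control, n_features, n_planted_deg)) {
    if (!all(layers %in% names(v)))
      stop("per-layer counts need names circ, mir, mrna", call. = FALSE)
  }
  cfg <- list(n_case = n_case[layers], n_control = n_control[layers],
              n_features = n_features[layers],
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              effect_size = effect_size,
              n_planted_deg = n_planted_deg[layers],
              n_planted_axes = n_planted_axes,
              db_overlap_prob = db_overlap_prob,
              decoy_pair_rate = decoy_pair_rate,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  fail <- function(...) stop("invalid simulation_config: ", ...,
                             call. = FALSE)
  counts <- c(cfg$n_case, cfg$n_control, cfg$n_features)
  if (any(counts < 1) || any(counts != round(counts)))
    fail("sample and feature counts must be positive integers")
  if (any(cfg$n_planted_deg < 0))
    fail("n_planted_deg must be non-negative")
  if (any(cfg$n_planted_deg > cfg$n_features))
    fail("n_planted_deg exceeds n_features")
  if (cfg$baseline_sd <= 0) fail("baseline_sd must be positive")
  # effect_size = 0 is allowed: it is the global-null world used for
  # type-I-error calibration
  if (cfg$effect_size < 0) fail("effect_size must be >= 0")
  for (p in c(cfg$db_overlap_prob, cfg$decoy_pair_rate))
    if (p < 0 || p > 1) fail("probabilities must lie in [0, 1]")
  if (cfg$n_planted_axes < 0 ||
      cfg$n_planted_axes > min(cfg$n_planted_deg))
    fail("n_planted_axes must be <= min(n_planted_deg) per layer")
  invisible(cfg)
}

layer_prefix <- c(circ = "circ_", mir = "mir_", mrna = "m_")

feature_ids <- function(layer, n) {
  sprintf("%s%04d", layer_prefix[[layer]], seq_len(n))
}

simulate_layer <- function(layer, cfg, planted) {
  nf <- cfg$n_features[[layer]]
  n1 <- cfg$n_case[[layer]]; n2 <- cfg$n_control[[layer]]
  ids <- feature_ids(layer, nf)
  mat <- matrix(stats::rnorm(nf * (n1 + n2), cfg$baseline_mean,
                             cfg$baseline_sd),
                nrow = nf,
                dimnames = list(ids, c(sprintf("%s_TAD_%d", layer,
                                               seq_len(n1)),
                                       sprintf("%s_CON_%d", layer,
                                               seq_len(n2)))))
  shift <- ifelse(planted$direction == "up", cfg$effect_size,
                  -cfg$effect_size)
  mat[planted$id, seq_len(n1)] <-
    mat[planted$id, seq_len(n1), drop = FALSE] + shift
  group <- c(rep("TAD", n1), rep("CON", n2))
  expression_dataset(mat, group, case_label = "TAD")
}

sample_pairs <- function(sources, targets, rate) {
  total <- length(sources) * length(targets)
  n_pick <- stats::rbinom(1L, total, rate)
  if (n_pick == 0L)
    return(data.frame(source_id = character(0), target_id = character(0),
                      stringsAsFactors = FALSE))
  idx <- sample.int(total, n_pick)
  data.frame(source_id = sources[((idx - 1L) %% length(sources)) + 1L],
             target_id = targets[((idx - 1L) %/% length(sources)) + 1L],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic three-layer ceRNA study with known ground truth
#'
#' Draws log2 expression matrices for the circRNA, miRNA and mRNA layers
#' (i.i.d. Gaussian noise around the baseline, planted DEGs shifted by
#' +/- `effect_size` in case samples), builds target-prediction tables
#' (planted axis links forced in: the circRNA-miRNA link in both circRNA
#' databases, the miRNA-mRNA link in all three miRNA-target databases; decoy
#' pairs added at `decoy_pair_rate`, each decoy miRNA-mRNA pair reported by
#' each database independently with `db_overlap_prob`), a PPI graph whose
#' planted mRNAs form a dense clique over sparse background, and a gene-set
#' collection containing one set enriched for planted-axis mRNAs.
#'
#' Planted axes follow the sponge direction pattern: circRNA down, miRNA up,
#' mRNA down in cases.
#'
#' @param config A [simulation_config()].
#' @return List of class `cerna_simulation` with elements `datasets`
#'   (`$circ`, `$mir`, `$mrna` [expression_dataset()]s), `targets_circ_mi`
#'   and `targets_mi_m` ([target_table()]s), `ppi` (igraph), `gene_sets`
#'   ([gene_set_collection()]), `truth` (planted DEG ids/directions per
#'   layer, axis triples, all simulated pairs, clique members, enriched-set
#'   name) and `config`.
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  layers <- c("circ", "mir", "mrna")
  ids <- lapply(stats::setNames(layers, layers),
                function(l) feature_ids(l, config$n_features[[l]]))

  axis_dir <- c(circ = "down", mir = "up", mrna = "down")
  planted <- list()
  for (l in layers) {
    pick <- sample(ids[[l]], config$n_planted_deg[[l]])
    n_axes <- config$n_planted_axes
    dirs <- character(length(pick))
    if (n_axes > 0) dirs[seq_len(n_axes)] <- axis_dir[[l]]
    if (length(pick) > n_axes)
      dirs[(n_axes + 1):length(pick)] <-
        sample(c("up", "down"), length(pick) - n_axes, replace = TRUE)
    planted[[l]] <- data.frame(id = pick, direction = dirs,
                               stringsAsFactors = FALSE)
  }
  axes <- data.frame(
    circRNA = planted$circ$id[seq_len(config$n_planted_axes)],
    miRNA = planted$mir$id[seq_len(config$n_planted_axes)],
    mRNA = planted$mrna$id[seq_len(config$n_planted_axes)],
    stringsAsFactors = FALSE)

  datasets <- lapply(stats::setNames(layers, layers),
                     function(l) simulate_layer(l, config, planted[[l]]))

  circ_dbs <- c("CSCD", "circBase")
  mi_dbs <- c("miRDB", "TargetScan", "miRTarbase")
  # planted links: circRNA->miRNA in both circRNA resources,
  # miRNA->mRNA in all three databases (makes the all-three rule attainable)
  cm_rows <- if (nrow(axes)) expand.grid(i = seq_len(nrow(axes)),
                                         database = circ_dbs,
                                         stringsAsFactors = FALSE)
             else data.frame(i = integer(0), database = character(0))
  cm <- data.frame(source_id = axes$circRNA[cm_rows$i],
                   target_id = axes$miRNA[cm_rows$i],
                   database = cm_rows$database, stringsAsFactors = FALSE)
  mm_rows <- if (nrow(axes)) expand.grid(i = seq_len(nrow(axes)),
                                         database = mi_dbs,
                                         stringsAsFactors = FALSE)
             else data.frame(i = integer(0), database = character(0))
  mm <- data.frame(source_id = axes$miRNA[mm_rows$i],
                   target_id = axes$mRNA[mm_rows$i],
                   database = mm_rows$database, stringsAsFactors = FALSE)

  # decoys: random cross-layer pairs; each decoy miRNA->mRNA pair lands in
  # each database independently, so only a fraction p^3 survives the
  # all-three-databases rule
  cm_decoy <- sample_pairs(ids$circ, ids$mir, config$decoy_pair_rate)
  if (nrow(cm_decoy)) {
    cm_decoy$database <- sample(circ_dbs, nrow(cm_decoy), replace = TRUE)
    cm <- rbind(cm, cm_decoy)
  }
  mm_decoy <- sample_pairs(ids$mir, ids$mrna, config$decoy_pair_rate)
  if (nrow(mm_decoy)) {
    hits <- matrix(stats::runif(nrow(mm_decoy) * 3) < config$db_overlap_prob,
                   ncol = 3)
    keep <- which(hits, arr.ind = TRUE)
    if (nrow(keep)) {
      mm <- rbind(mm, data.frame(source_id = mm_decoy$source_id[keep[, 1L]],
                                 target_id = mm_decoy$target_id[keep[, 1L]],
                                 database = mi_dbs[keep[, 2L]],
                                 stringsAsFactors = FALSE))
    }
  }
  targets_circ_mi <- target_table(unique(cm), "circ_mirna",
                                  origin = "<simulated>")
  targets_mi_m <- target_table(unique(mm), "mirna_mrna",
                               origin = "<simulated>")

  # PPI: planted mRNAs form a dense clique (recoverable MCODE module:
  # a clique of c nodes scores c, so use >= 8 to clear the score > 5 gate),
  # over a sparse Erdos-Renyi background of other mRNAs
  clique_size <- min(max(8L, config$n_planted_axes),
                     config$n_planted_deg[["mrna"]])
  clique_genes <- planted$mrna$id[seq_len(clique_size)]
  n_bg <- min(200L, config$n_features[["mrna"]])
  bg_genes <- setdiff(ids$mrna[seq_len(n_bg)], clique_genes)
  edges <- if (length(clique_genes) >= 2L) t(utils::combn(clique_genes, 2L))
           else matrix(character(0), 0, 2)
  if (length(bg_genes) >= 2L) {
    bg <- sample_pairs(bg_genes, bg_genes, 2 / length(bg_genes))
    bg <- bg[bg$source_id != bg$target_id, , drop = FALSE]
    edges <- rbind(edges, cbind(bg$source_id, bg$target_id))
    # tether the clique to the background so the graph is not all clique
    if (length(clique_genes))
      edges <- rbind(edges, cbind(clique_genes[1L], bg_genes[1L]))
  }
  ppi <- igraph::simplify(igraph::graph_from_edgelist(edges,
                                                      directed = FALSE))

  # gene sets: one set enriched for planted-axis mRNAs + random background
  universe <- ids$mrna
  n_sets <- 20L
  sets <- lapply(seq_len(n_sets), function(i) sample(universe, 15L))
  names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
  planted_set <- unique(c(clique_genes, sample(universe, 5L)))
  sets[["PLANTED_PATHWAY"]] <- planted_set
  gene_sets <- gene_set_collection(sets, universe = universe)

  truth <- list(planted_degs = planted, axes = axes,
                target_pairs = list(circ_mirna = targets_circ_mi,
                                    mirna_mrna = targets_mi_m),
                clique_genes = clique_genes,
                enriched_set = "PLANTED_PATHWAY")
  structure(list(datasets = datasets, targets_circ_mi = targets_circ_mi,
                 targets_mi_m = targets_mi_m, ppi = ppi,
                 gene_sets = gene_sets, truth = truth, config = config),
            class = "cerna_simulation")
}

#' Write a simulated study to disk as a plain-text fixture bundle
#'
#' Emits, into `directory`: per-layer expression and group TSVs, the two
#' target tables, the PPI graph as SIF and edge-list TSV, the gene sets as
#' GMT, and the ground truth as JSON. All files round-trip through the
#' package readers.
#'
#' @param sim A `cerna_simulation` from [generate_dataset()].
#' @param directory Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_fixture_bundle <- function(sim, directory) {
  stopifnot(inherits(sim, "cerna_simulation"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    stop("cannot create fixture directory: ", directory, call. = FALSE)
  p <- function(...) file.path(directory, paste0(...))
  paths <- c(exprs_circ = p("exprs_circ.tsv"), groups_circ = p("groups_circ.tsv"),
             exprs_mir = p("exprs_mir.tsv"), groups_mir = p("groups_mir.tsv"),
             exprs_mrna = p("exprs_mrna.tsv"), groups_mrna = p("groups_mrna.tsv"),
             targets_circ_mi = p("targets_circ_mir.tsv"),
             targets_mi_m = p("targets_mir_mrna.tsv"),
             ppi_sif = p("ppi.sif"), ppi_edges = p("ppi_edges.tsv"),
             gene_sets = p("gene_sets.gmt"), truth = p("truth.json"))
  for (l in c("circ", "mir", "mrna"))
    write_expression_tsv(sim$datasets[[l]], paths[[paste0("exprs_", l)]],
                         paths[[paste0("groups_", l)]])
  utils::write.table(sim$targets_circ_mi, paths[["targets_circ_mi"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$targets_mi_m, paths[["targets_mi_m"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sif(sim$ppi, paths[["ppi_sif"]])
  el <- igraph::as_edgelist(sim$ppi)
  utils::write.table(data.frame(node1 = el[, 1L], node2 = el[, 2L]),
                     paths[["ppi_edges"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(sim$gene_sets, paths[["gene_sets"]])
  jsonlite::write_json(
    list(planted_degs = sim$truth$planted_degs,
         axes = sim$truth$axes,
         clique_genes = sim$truth$clique_genes,
         enriched_set = sim$truth$enriched_set,
         config = unclass(sim$config)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
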