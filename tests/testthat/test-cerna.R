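make_target_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("source_id\ttarget_id\tdatabase", rows), path)
  path
}

test_that("load_target_table deduplicates and validates", {
  p <- make_target_tsv(c("c1\tm1\tCSCD", "c1\tm1\tCSCD", "c1\tm2\tcircBase"))
  expect_message(tt <- load_target_table(p, "circ_mirna"), "1 duplicate")
  expect_identical(nrow(tt), 2L)

  empty <- make_target_tsv(character(0))
  expect_identical(nrow(load_target_table(empty, "circ_mirna")), 0L)

  bad <- make_target_tsv("c1\t\tCSCD")
  expect_error(load_target_table(bad, "circ_mirna"), "row 1")
  expect_error(target_table(data.frame(a = 1), "circ_mirna"),
               "must have columns")
})

test_that("intersect_database_support counts distinct databases", {
  tt <- suppressMessages(target_table(data.frame(
    source_id = c("mi1", "mi1", "mi1", "mi2", "mi2", "mi2", "mi3"),
    target_id = c("g1", "g1", "g1", "g2", "g2", "g2", "g3"),
    database = c("dbA", "dbB", "dbC", "dbA", "dbA", "dbB", "dbA")),
    "mirna_mrna"))
  # duplicate (mi2, g2, dbA) row collapses; distinct tags = 2
  out3 <- intersect_database_support(tt, 3)
  expect_identical(out3$source_id, "mi1")
  out1 <- intersect_database_support(tt, 1)
  expect_identical(nrow(out1), 3L)
  expect_error(intersect_database_support(tt, 0), ">= 1")
})

test_that("intersect_database_support matches a brute-force groupby oracle", {
  set.seed(8)
  tab <- data.frame(
    source_id = sample(sprintf("mi%d", 1:15), 200, replace = TRUE),
    target_id = sample(sprintf("g%d", 1:25), 200, replace = TRUE),
    database = sample(c("dbA", "dbB", "dbC"), 200, replace = TRUE))
  tt <- suppressMessages(target_table(tab, "mirna_mrna"))
  for (min_db in 1:3) {
    got <- intersect_database_support(tt, min_db)
    # oracle: loop over unique pairs, count unique tags
    pairs <- unique(tab[, 1:2])
    keep <- vapply(seq_len(nrow(pairs)), function(i) {
      sel <- tab$source_id == pairs$source_id[i] &
        tab$target_id == pairs$target_id[i]
      length(unique(tab$database[sel])) >= min_db
    }, logical(1))
    oracle <- pairs[keep, ]
    oracle <- oracle[order(oracle$source_id, oracle$target_id), ]
    expect_equal(got[, 1:2], oracle, ignore_attr = TRUE)
  }
})

test_that("relaxing min_databases never shrinks the supported pair set", {
  sim <- generate_dataset(small_sim_config(4, decoy_pair_rate = 0.05))
  n_pairs <- vapply(3:1, function(k)
    nrow(intersect_database_support(sim$targets_mi_m, k)), 0L)
  expect_true(all(diff(n_pairs) >= 0))
})

test_that("derive_co_set is plain intersection with optional normalization", {
  expect_identical(derive_co_set(c("a", "b", "c"), c("b", "c", "d")),
                   c("b", "c"))
  expect_identical(derive_co_set(c("a"), c("b")), character(0))
  expect_identical(
    derive_co_set("hsa-miR-1271-5p", "hsa-mir-1271-5p",
                  normalize = normalize_mirna_id),
    "hsa-mir-1271-5p")
})

deg_df <- function(ids, dirs)
  data.frame(id = ids, logFC = ifelse(dirs == "up", 2, -2), p = 0.01,
             adj_p = 0.02, direction = dirs, stringsAsFactors = FALSE)

test_that("assemble_network enumerates complete triplets only", {
  deg_c <- deg_df("c1", "down")
  deg_mi <- deg_df(c("mi1", "mi2"), c("up", "up"))
  deg_m <- deg_df(c("g1", "g2"), c("down", "down"))
  cm <- data.frame(source_id = c("c1", "c1"), target_id = c("mi1", "mi2"))
  mm <- data.frame(source_id = c("mi1", "mi1"), target_id = c("g1", "g2"))
  net <- assemble_network(deg_c, deg_mi, deg_m, cm, mm)
  expect_identical(nrow(net$triplets), 2L)
  expect_identical(sum(net$nodes$layer == "circRNA"), 1L)
  expect_identical(sum(net$nodes$layer == "miRNA"), 1L)
  expect_identical(sum(net$nodes$layer == "mRNA"), 2L)
  # mi2 has no surviving mRNA target: no triplet, absent from ce-miRNAs
  expect_false("mi2" %in% net$nodes$id)
  # every node participates in at least one complete triplet
  expect_true(all(net$nodes$id %in%
                    unlist(net$triplets[, c("circRNA", "miRNA", "mRNA")])))
})

test_that("direction filter keeps the sponge pattern and nothing else", {
  deg_c <- deg_df(c("c1", "c2"), c("down", "down"))
  deg_mi <- deg_df(c("mi1", "mi2"), c("up", "down"))
  deg_m <- deg_df(c("g1", "g2"), c("down", "down"))
  cm <- data.frame(source_id = c("c1", "c2"), target_id = c("mi1", "mi2"))
  mm <- data.frame(source_id = c("mi1", "mi2"), target_id = c("g1", "g2"))
  net <- assemble_network(deg_c, deg_mi, deg_m, cm, mm)
  expect_identical(nrow(net$triplets), 2L)
  filtered <- direction_consistency_filter(net)
  # (down, up, down) kept; (down, down, down) removed
  expect_identical(filtered$triplets$circRNA, "c1")
  expect_false("c2" %in% filtered$nodes$id)
})

test_that("direction filter refuses nodes without a DGE direction", {
  deg_c <- deg_df("c1", "down")
  deg_mi <- deg_df("mi1", "up")
  deg_m <- deg_df("g1", "down")
  cm <- data.frame(source_id = "c1", target_id = "mi1")
  mm <- data.frame(source_id = "mi1", target_id = "g1")
  net <- assemble_network(deg_c, deg_mi, deg_m, cm, mm)
  net$nodes$direction[1] <- NA
  expect_error(direction_consistency_filter(net), "missing a DEG direction")
})

test_that("planted axes are recovered exactly without decoys", {
  sim <- generate_dataset(small_sim_config(9, decoy_pair_rate = 0))
  degs <- lapply(sim$datasets, function(d) filter_degs(test_differential(d)))
  cm <- intersect_database_support(sim$targets_circ_mi, 1)
  mm <- intersect_database_support(sim$targets_mi_m, 3)
  net <- assemble_network(degs$circ, degs$mir, degs$mrna, cm, mm)
  expect_identical(triplet_key(net$triplets), triplet_key(sim$truth$axes))
  # all planted-axis miRNAs appear in the co-miRNA set
  expect_true(all(sim$truth$axes$miRNA %in% net$co_mirnas))
})

test_that("network exports are written and the graph is tripartite", {
  sim <- generate_dataset(small_sim_config(10, decoy_pair_rate = 0))
  degs <- lapply(sim$datasets, function(d) filter_degs(test_differential(d)))
  net <- assemble_network(degs$circ, degs$mir, degs$mrna,
                          intersect_database_support(sim$targets_circ_mi, 1),
                          intersect_database_support(sim$targets_mi_m, 3))
  dir <- withr::local_tempdir()
  paths <- write_cerna_network(net, dir)
  expect_true(all(file.exists(paths)))
  g <- cerna_igraph(net)
  layer <- setNames(igraph::V(g)$layer, igraph::V(g)$name)
  el <- igraph::as_edgelist(g)
  ok <- (layer[el[, 1]] == "circRNA" & layer[el[, 2]] == "miRNA") |
    (layer[el[, 1]] == "miRNA" & layer[el[, 2]] == "circRNA") |
    (layer[el[, 1]] == "miRNA" & layer[el[, 2]] == "mRNA") |
    (layer[el[, 1]] == "mRNA" & layer[el[, 2]] == "miRNA")
  expect_true(all(ok))
  nodes <- read.delim(paths[["nodes"]])
  expect_identical(nrow(nodes), nrow(net$nodes))
})
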