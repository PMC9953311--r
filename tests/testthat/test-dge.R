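test_that("log2_fold_change is the difference of group means", {
  ds <- tiny_dataset(case = rbind(c(3, 3), c(2, 2), c(2.9, 3.0)),
                     control = rbind(c(1, 1), c(2, 2), c(0.9, 1.0)))
  lfc <- log2_fold_change(ds)
  expect_equal(unname(lfc), c(2, 0, 2))

  # derived oracle: arbitrary values, per-feature arithmetic means
  set.seed(11)
  case <- matrix(rnorm(30), 10); control <- matrix(rnorm(40), 10)
  ds2 <- tiny_dataset(case, control)
  oracle <- apply(case, 1, mean) - apply(control, 1, mean)
  expect_equal(unname(log2_fold_change(ds2)), oracle)

  ds3 <- tiny_dataset(rbind(c(2.9, 3.0, 3.1)), rbind(c(0.9, 1.0, 1.1)))
  expect_equal(unname(log2_fold_change(ds3)), 2.0)
})

test_that("welch t matches the hand formula and t.test", {
  ds <- tiny_dataset(rbind(c(2.9, 3.0, 3.1), c(1, 2, 3)),
                     rbind(c(0.9, 1.0, 1.1), c(1, 2, 3)))
  res <- test_differential(ds, method = "welch")
  # t = delta / sqrt(s1^2/n1 + s2^2/n2) = 2 / sqrt(0.01/3 * 2)
  expect_equal(res$t[1], 2 / sqrt(0.01 / 3 + 0.01 / 3), tolerance = 1e-12)
  expect_equal(res$t[1], 24.49489742783178, tolerance = 1e-10)
  tt <- t.test(c(2.9, 3.0, 3.1), c(0.9, 1.0, 1.1))
  expect_equal(res$t[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  expect_equal(res$t[2], 0)
  expect_equal(res$p[2], 1)
})

test_that("welch t is antisymmetric under group-label swap", {
  set.seed(5)
  m <- matrix(rnorm(60, 8), 10)
  rownames(m) <- sprintf("f%02d", 1:10)
  colnames(m) <- sprintf("s%d", 1:6)
  a <- expression_dataset(m, c("TAD", "TAD", "TAD", "CON", "CON", "CON"))
  b <- expression_dataset(m, c("CON", "CON", "CON", "TAD", "TAD", "TAD"))
  ra <- test_differential(a, "welch"); rb <- test_differential(b, "welch")
  expect_equal(ra$t, -rb$t)
  expect_equal(ra$p, rb$p)
  expect_equal(ra$logFC, -rb$logFC)
})

test_that("zero variance with nonzero difference reports p = 0 with warning", {
  ds <- tiny_dataset(rbind(c(3, 3), c(5, 6)), rbind(c(1, 1), c(5, 7)))
  expect_warning(res <- test_differential(ds, "welch"), "zero within-group")
  expect_equal(res$p[1], 0)
  expect_true(is.infinite(res$t[1]) && res$t[1] > 0)
  expect_true(res$zero_variance[1])
})

test_that("moderated t reduces to the pooled t when prior df is zero", {
  set.seed(42)
  m <- matrix(rnorm(50 * 8, 8, 0.5), 50)
  m[1:10, 1:4] <- m[1:10, 1:4] + 1.5
  rownames(m) <- sprintf("g%03d", 1:50)
  colnames(m) <- sprintf("s%d", 1:8)
  ds <- expression_dataset(m, rep(c("TAD", "CON"), each = 4))
  res <- test_differential(ds, "moderated", prior_df = 0)
  oracle <- apply(m, 1, function(x)
    t.test(x[1:4], x[5:8], var.equal = TRUE)$p.value)
  expect_equal(res$p, unname(oracle), tolerance = 1e-12)
})

test_that("moderated t agrees closely with the limma empirical-Bayes oracle", {
  set.seed(7)
  m <- matrix(rnorm(200 * 10, 8, 0.4), 200)
  m[1:20, 1:5] <- m[1:20, 1:5] + 2
  rownames(m) <- sprintf("g%03d", 1:200)
  colnames(m) <- sprintf("s%d", 1:10)
  ds <- expression_dataset(m, rep(c("TAD", "CON"), each = 5))
  res <- test_differential(ds, "moderated")
  design <- cbind(1, rep(c(1, 0), each = 5))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(res$logFC, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  # the prior is fit by a different (method-of-moments) estimator, so match
  # approximately, not identically
  expect_gt(cor(res$t, fit$t[, 2]), 0.999)
  expect_gt(cor(log(res$p), log(fit$p.value[, 2])), 0.999)
})

test_that("bh_adjust matches the step-up enumeration and p.adjust", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^2
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_adjust is invariant under input permutation", {
  set.seed(9)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("filter_degs applies strict thresholds on p and |logFC|", {
  rec <- data.frame(id = c("a", "b", "c", "d"),
                    logFC = c(1.0, -1.2, 3.0, -2.0),
                    t = 0, p = c(0.01, 0.03, 0.05, 0.002),
                    adj_p = c(0.04, 0.2, 0.2, 0.008),
                    direction = c("up", "down", "up", "down"))
  out <- filter_degs(rec, deg_thresholds())
  expect_equal(out$id, c("b", "d"))          # a: |logFC| not > 1; c: p not < .05
  expect_equal(out$direction, c("down", "down"))
  out_adj <- filter_degs(rec, deg_thresholds(use_adjusted_p = TRUE))
  expect_equal(out_adj$id, "d")
  expect_error(deg_thresholds(lfc_threshold = -1), "positive")
  expect_error(deg_thresholds(p_threshold = 0), "positive")
})

test_that("planted DEGs are recalled on easy synthetic data", {
  # effect 2, sd 0.3, 3v3 circRNA layer: recall of planted DEGs >= 0.9
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    sim <- generate_dataset(small_sim_config(seed))
    tab <- test_differential(sim$datasets$circ)
    degs <- filter_degs(tab)
    truth <- sim$truth$planted_degs$circ$id
    hits <- hits + sum(truth %in% degs$id)
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.9)
})

test_that("input validation catches bad datasets", {
  m <- matrix(1:6, 2, dimnames = list(c("a", "a"), NULL))
  expect_error(expression_dataset(m, c("T", "T", "C")), "duplicate")
  m2 <- matrix(rnorm(4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_dataset(m2, c("T", "T")), "two distinct")
  ds <- tiny_dataset(cbind(c(1, 2)), cbind(c(1, 1)))
  expect_error(test_differential(ds), "at least 2 samples")
})
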