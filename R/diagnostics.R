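#' ROC curve and AUC for a single-feature biomarker
#'
#' AUC is computed through the Mann-Whitney identity: the fraction of
#' (case, control) pairs where the case sample outranks the control, ties
#' counted one half. Orientation is auto-selected so the reported AUC is
#' >= 0.5 (a down-regulated marker is as diagnostic as an up-regulated one);
#' the chosen polarity is reported. Significance against the null AUC = 0.5
#' is two-sided: exact by complete enumeration of label assignments when
#' `choose(n, n_case)` is small enough (covers the small-cohort designs this
#' targets, e.g. 7 vs 5), otherwise a tie-corrected normal approximation.
#'
#' @param scores Numeric vector (e.g. log2 expression of one gene).
#' @param labels Binary labels, same length; `case_label` marks cases.
#' @param case_label Which label is the case class (default `"TAD"` when
#'   present, else the second unique label).
#' @param max_exact Enumerate the exact permutation null while
#'   `choose(n, n_case) <= max_exact`.
#' @return An object of class `roc_result`: list with `auc`, `p`,
#'   `orientation` (`"case_high"` or `"case_low"`), `p_method` (`"exact"` or
#'   `"normal"`), `n_case`, `n_control`, and `curve` (data.frame `fpr`,
#'   `tpr`, monotone from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels, case_label = NULL, max_exact = 2e5) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  labs <- unique(labels)
  if (length(labs) != 2L)
    stop("labels must contain exactly two classes", call. = FALSE)
  if (is.null(case_label))
    case_label <- if ("TAD" %in% labs) "TAD" else labs[2L]
  is_case <- labels == case_label
  n1 <- sum(is_case); n2 <- sum(!is_case)

  auc_raw <- auc_mann_whitney(scores, is_case)
  orientation <- if (auc_raw >= 0.5) "case_high" else "case_low"
  oriented <- if (orientation == "case_high") scores else -scores
  auc <- max(auc_raw, 1 - auc_raw)

  # two-sided p under the permutation null of exchangeable labels
  dev_obs <- abs(auc_raw - 0.5)
  n <- n1 + n2
  if (choose(n, n1) <= max_exact) {
    combs <- utils::combn(n, n1)
    devs <- apply(combs, 2L, function(idx) {
      lab <- logical(n); lab[idx] <- TRUE
      abs(auc_mann_whitney(scores, lab) - 0.5)
    })
    p <- mean(devs >= dev_obs - 1e-12)
    p_method <- "exact"
  } else {
    r <- rank(scores)
    ties <- table(scores)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    u <- auc_raw * n1 * n2
    z <- (u - n1 * n2 / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    p_method <- "normal"
  }

  curve <- roc_points(oriented, is_case)
  structure(list(auc = auc, p = p, orientation = orientation,
                 p_method = p_method, n_case = n1, n_control = n2,
                 curve = curve),
            class = "roc_result")
}

auc_mann_whitney <- function(scores, is_case) {
  n1 <- sum(is_case); n2 <- sum(!is_case)
  r <- rank(scores) # midranks handle ties (half credit per tied pair)
  u <- sum(r[is_case]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

roc_points <- function(scores, is_case) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[is_case] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!is_case] >= t), 0)
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%s scores in cases), p = %.4g [%s], %d vs %d\n",
              x$auc, if (x$orientation == "case_high") "higher" else "lower",
              x$p, x$p_method, x$n_case, x$n_control))
  invisible(x)
}

#' Write ROC outputs (curve points TSV + JSON summary)
#'
#' @param roc A `roc_result` from [roc_auc()].
#' @param points_path TSV path for the (fpr, tpr) points.
#' @param summary_path JSON path for AUC, p, orientation and class sizes.
#' @return Invisibly, the two paths.
#' @export
write_roc <- function(roc, points_path, summary_path) {
  utils::write.table(roc$curve, points_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(auc = roc$auc, p = roc$p, orientation = roc$orientation,
         p_method = roc$p_method, n_case = roc$n_case,
         n_control = roc$n_control),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(points_path, summary_path))
}

#' Pearson correlation with two-sided t-based p value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `rho` and `p` (two-sided, t transform on n-2 df).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  rho <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) return(list(rho = rho, p = 0))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE))
}
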