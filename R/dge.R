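#' Construct an expression dataset for one omics layer
#'
#' Bundles a log2-scale expression matrix (features x samples) with binary
#' case/control labels. This is the input container for the differential
#' expression stage; one is built per omics layer (circRNA, miRNA, mRNA).
#'
#' @param exprs Numeric matrix, features in rows (unique rownames required),
#'   samples in columns, values on the log2 scale.
#' @param group Character or factor of length `ncol(exprs)` with exactly two
#'   distinct labels.
#' @param case_label Label in `group` identifying case samples. Defaults to
#'   `"TAD"` when present, otherwise the second factor level.
#' @param drop_incomplete Drop features containing non-finite values (with a
#'   message reporting how many). If `FALSE`, non-finite values are an error.
#' @return An object of class `expression_dataset`: list with elements
#'   `exprs`, `group` (factor, levels = c(control, case)), `case_label`,
#'   `control_label`.
#' @export
expression_dataset <- function(exprs, group, case_label = NULL,
                               drop_incomplete = TRUE) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("`exprs` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(exprs)))
    stop("`exprs` must have feature ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(exprs)))
    stop("duplicate feature ids in `exprs`", call. = FALSE)
  group <- as.character(group)
  if (length(group) != ncol(exprs))
    stop("`group` length must equal ncol(exprs)", call. = FALSE)
  labs <- unique(group)
  if (length(labs) != 2L)
    stop("`group` must contain exactly two distinct labels", call. = FALSE)
  if (is.null(case_label))
    case_label <- if ("TAD" %in% labs) "TAD" else labs[2L]
  if (!case_label %in% labs)
    stop("case_label '", case_label, "' not found in group labels",
         call. = FALSE)
  control_label <- setdiff(labs, case_label)
  bad <- !apply(is.finite(exprs), 1L, all)
  if (any(bad)) {
    if (!drop_incomplete)
      stop(sum(bad), " features contain non-finite values", call. = FALSE)
    message("dropping ", sum(bad), " features with non-finite values")
    exprs <- exprs[!bad, , drop = FALSE]
  }
  structure(
    list(exprs = exprs,
         group = factor(group, levels = c(control_label, case_label)),
         case_label = case_label,
         control_label = control_label),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$exprs), "features x",
      ncol(x$exprs), "samples\n")
  cat("  case   (", x$case_label, "): ",
      sum(x$group == x$case_label), " samples\n", sep = "")
  cat("  control(", x$control_label, "): ",
      sum(x$group == x$control_label), " samples\n", sep = "")
  invisible(x)
}

group_split_idx <- function(dataset) {
  list(case = which(dataset$group == dataset$case_label),
       control = which(dataset$group == dataset$control_label))
}

#' Per-feature log2 fold change (case minus control)
#'
#' The matrix is assumed already log2 scale, so the fold change is a plain
#' difference of group means.
#'
#' @param dataset An [expression_dataset()].
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(dataset) {
  idx <- group_split_idx(dataset)
  if (length(idx$case) == 0L || length(idx$control) == 0L)
    stop("both groups must contain at least one sample", call. = FALSE)
  rowMeans(dataset$exprs[, idx$case, drop = FALSE]) -
    rowMeans(dataset$exprs[, idx$control, drop = FALSE])
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing function).
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Method-of-moments fit of a scaled inverse-chi-square prior on residual
# variances, working on log variances: if s2 ~ s0^2 * chisq_d/d / (chisq_d0/d0)
# then var(log s2) = trigamma(d/2) + trigamma(d0/2) and
# E[log s2] = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2).
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2L) return(list(d0 = Inf, s0_2 = stats::median(s2[s2 > 0])))
  z <- log(s2[ok])
  e_resid <- digamma(df / 2) - log(df / 2)
  v <- stats::var(z) - trigamma(df / 2)
  if (!is.finite(v) || v <= 0) {
    # observed log-variances less dispersed than a chi-square with df:
    # infinite prior df, all variances shrunk to the common value
    d0 <- Inf
    s0_2 <- exp(mean(z) - e_resid)
  } else {
    d0 <- 2 * trigamma_inverse(v)
    s0_2 <- exp(mean(z) - e_resid + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Per-feature two-sample differential expression test
#'
#' Computes log2 fold change (case minus control) and a two-sided two-sample
#' test per feature. `method = "welch"` is the Welch unequal-variance t with
#' Satterthwaite degrees of freedom. `method = "moderated"` is an
#' empirical-Bayes moderated t: per-feature pooled variances are shrunk
#' toward a scaled inverse-chi-square prior whose scale `s0^2` and degrees of
#' freedom `d0` are fit by method of moments on the log variances; the
#' posterior variance is `(d0*s0^2 + d*s2)/(d0 + d)` and the t statistic is
#' referred to a t distribution with `d0 + d` degrees of freedom.
#'
#' Features whose variance is exactly zero in both groups but whose means
#' differ produce an infinite t; these are reported with `p = 0` and flagged
#' in the `zero_variance` column (a warning is emitted).
#'
#' @param dataset An [expression_dataset()] with at least two samples per
#'   group.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param prior_df Override for the moderated prior degrees of freedom `d0`
#'   (mainly for testing; `NULL` fits it from the data). `prior_df = 0`
#'   reduces the moderated test to the ordinary pooled-variance t.
#' @return `data.frame` with columns `id`, `logFC`, `t`, `p`, `adj_p`
#'   (Benjamini-Hochberg), `direction` (`"up"`/`"down"`), `zero_variance`.
#' @export
test_differential <- function(dataset, method = c("moderated", "welch"),
                              prior_df = NULL) {
  method <- match.arg(method)
  idx <- group_split_idx(dataset)
  n1 <- length(idx$case); n2 <- length(idx$control)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 samples per group for testing", call. = FALSE)
  x <- dataset$exprs
  if (method == "moderated" && nrow(x) < 2L)
    stop("moderated test needs at least 2 features", call. = FALSE)
  m1 <- rowMeans(x[, idx$case, drop = FALSE])
  m2 <- rowMeans(x[, idx$control, drop = FALSE])
  v1 <- apply(x[, idx$case, drop = FALSE], 1L, stats::var)
  v2 <- apply(x[, idx$control, drop = FALSE], 1L, stats::var)
  lfc <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tval <- lfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    df_resid <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_resid
    prior <- if (is.null(prior_df)) fit_variance_prior(s2, df_resid)
             else list(d0 = prior_df,
                       s0_2 = if (prior_df > 0) fit_variance_prior(s2, df_resid)$s0_2 else 0)
    if (is.finite(prior$d0)) {
      s2_post <- (prior$d0 * prior$s0_2 + df_resid * s2) / (prior$d0 + df_resid)
      df <- rep(prior$d0 + df_resid, length(s2))
    } else {
      s2_post <- rep(prior$s0_2, length(s2))
      df <- rep(Inf, length(s2))
    }
    tval <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  }

  zero_var <- !is.finite(tval) | is.nan(tval)
  # identical groups (lfc == 0, zero variance): t = 0, p = 1
  null_zero <- zero_var & lfc == 0
  tval[null_zero] <- 0
  # zero variance but real mean difference: +/-Inf t convention, p = 0
  inf_idx <- zero_var & lfc != 0
  tval[inf_idx] <- sign(lfc[inf_idx]) * Inf
  if (any(inf_idx))
    warning(sum(inf_idx),
            " features have zero within-group variance but nonzero logFC;",
            " reported with p = 0", call. = FALSE)
  p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  p[null_zero] <- 1
  p[inf_idx] <- 0

  data.frame(id = rownames(x), logFC = lfc, t = tval, p = p,
             adj_p = bh_adjust(p),
             direction = ifelse(lfc >= 0, "up", "down"),
             zero_variance = zero_var,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort p ascending, multiply by m/rank, enforce monotonicity by
#' a cumulative minimum from the largest p, cap at 1, return in input order.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Differential-expression thresholds
#'
#' The screening gate used throughout: a feature is differentially expressed
#' when its p value (nominal by default, BH-adjusted if `use_adjusted_p`) is
#' strictly below `p_threshold` and |logFC| is strictly above
#' `lfc_threshold`.
#'
#' @param p_threshold Positive p-value cutoff (strict `<`), default 0.05.
#' @param lfc_threshold Positive |log2FC| cutoff (strict `>`), default 1.
#' @param use_adjusted_p Gate on the BH-adjusted p instead of the nominal p.
#' @return `deg_thresholds` object.
#' @export
deg_thresholds <- function(p_threshold = 0.05, lfc_threshold = 1.0,
                           use_adjusted_p = FALSE) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L || p_threshold <= 0)
    stop("`p_threshold` must be a positive number", call. = FALSE)
  if (!is.numeric(lfc_threshold) || length(lfc_threshold) != 1L ||
      lfc_threshold <= 0)
    stop("`lfc_threshold` must be a positive number", call. = FALSE)
  structure(list(p_threshold = p_threshold, lfc_threshold = lfc_threshold,
                 use_adjusted_p = isTRUE(use_adjusted_p)),
            class = "deg_thresholds")
}

#' Filter differential-expression records into a DEG list
#'
#' @param records Output of [test_differential()].
#' @param thresholds A [deg_thresholds()] object.
#' @return Subset of `records` (columns `id`, `logFC`, `p`, `adj_p`,
#'   `direction`) passing both gates, strict inequalities.
#' @export
filter_degs <- function(records, thresholds = deg_thresholds()) {
  stopifnot(inherits(thresholds, "deg_thresholds"))
  pcol <- if (thresholds$use_adjusted_p) records$adj_p else records$p
  keep <- pcol < thresholds$p_threshold &
    abs(records$logFC) > thresholds$lfc_threshold
  records[keep, c("id", "logFC", "p", "adj_p", "direction"), drop = FALSE]
}
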