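#' Per-analyte Wilcoxon-Mann-Whitney test between two groups
#'
#' Two-sided rank-sum p-values. The exact null distribution is used when
#' the combined sample size is at most 12 and the analyte has no ties;
#' otherwise the normal approximation with midranks, tie-corrected
#' variance and continuity correction is used.
#'
#' @param matrix a complete (post-imputation) [omics_matrix()]
#' @param metadata a [sample_metadata()] table
#' @param group_a,group_b group labels as in [group_samples()]
#' @return named numeric vector of p-values, one per analyte
#' @export
wilcoxon_mw <- function(matrix, metadata, group_a, group_b) {
  sa <- intersect(group_samples(metadata, group_a), sample_ids(matrix))
  sb <- intersect(group_samples(metadata, group_b), sample_ids(matrix))
  if (length(sa) < 2 || length(sb) < 2)
    stop("both groups need >= 2 samples present in the matrix")
  va <- matrix$values[, sa, drop = FALSE]
  vb <- matrix$values[, sb, drop = FALSE]
  if (anyNA(va) || anyNA(vb))
    stop("matrix contains missing values; impute before testing")
  n <- length(sa) + length(sb)
  p <- vapply(seq_len(nrow(va)), function(i) {
    x <- va[i, ]; y <- vb[i, ]
    ties <- anyDuplicated(c(x, y)) > 0
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(
      stats::wilcox.test(x, y, exact = (n <= 12 && !ties),
                         correct = TRUE)$p.value)
  }, numeric(1))
  names(p) <- analyte_ids(matrix)
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes q-values q_(i) = min_{j >= i} m p_(j) / j (capped at 1),
#' returned in the original order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`
#' @return numeric vector of BH-adjusted q-values, names preserved
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p_values)
  if (m == 0) return(p_values)
  o <- order(p_values)
  q_sorted <- pmin(1, cummin(rev(m * p_values[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  names(q) <- names(p_values)
  q
}

#' Signed fold change with bootstrap confidence limits
#'
#' The point estimate is the ratio of group means mean(b)/mean(a),
#' reported on the symmetric signed scale: ratios below 1 are reported as
#' the negative reciprocal (a halving is -2, not 0.5). The 95% limits
#' come from a seeded percentile bootstrap of the mean ratio, transformed
#' to the same signed scale (the transform is monotone, so percentiles
#' carry over).
#'
#' @inheritParams wilcoxon_mw
#' @param ci_level confidence level (default 0.95)
#' @param n_boot bootstrap resamples (default 2000)
#' @param seed integer seed for the bootstrap
#' @return data.frame of class `differential_result` with columns
#'   `analyte_id`, `group_a`, `group_b`, `fold_change`, `ci_low`,
#'   `ci_high`
#' @export
fold_change <- function(matrix, metadata, group_a, group_b, ci_level = 0.95,
                        n_boot = 2000, seed = 1) {
  sa <- intersect(group_samples(metadata, group_a), sample_ids(matrix))
  sb <- intersect(group_samples(metadata, group_b), sample_ids(matrix))
  if (!length(sa) || !length(sb)) stop("empty group")
  va <- matrix$values[, sa, drop = FALSE]
  vb <- matrix$values[, sb, drop = FALSE]
  if (anyNA(va) || anyNA(vb))
    stop("matrix contains missing values; impute before fold change")
  ma <- rowMeans(va); mb <- rowMeans(vb)
  if (any(ma == 0) || any(mb == 0))
    stop("zero group mean; cannot form a ratio on intensity data")
  set.seed(seed)
  na <- ncol(va); nb <- ncol(vb)
  ia <- matrix(sample.int(na, na * n_boot, replace = TRUE), na)
  ib <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nb)
  alpha <- (1 - ci_level) / 2
  lo <- hi <- numeric(nrow(va))
  for (i in seq_len(nrow(va))) {
    boot_ratio <- colMeans(matrix(vb[i, ib], nb)) /
      colMeans(matrix(va[i, ia], na))
    qs <- stats::quantile(boot_ratio, c(alpha, 1 - alpha), names = FALSE)
    lo[i] <- qs[1]; hi[i] <- qs[2]
  }
  out <- data.frame(analyte_id = analyte_ids(matrix), group_a = group_a,
                    group_b = group_b,
                    fold_change = .signed_ratio(mb / ma),
                    ci_low = .signed_ratio(lo), ci_high = .signed_ratio(hi),
                    stringsAsFactors = FALSE)
  class(out) <- c("differential_result", "data.frame")
  out
}

# symmetric signed ratio: r >= 1 -> r, r < 1 -> -1/r (monotone on (0, Inf))
.signed_ratio <- function(r) ifelse(r >= 1, r, -1 / r)

#' Full per-analyte differential abundance analysis
#'
#' Combines [wilcoxon_mw()], [bh_adjust()] and [fold_change()] into the
#' standard per-analyte record, with the direction of change at the
#' given significance threshold.
#'
#' @inheritParams fold_change
#' @param q_threshold BH q-value threshold used for the `direction` call
#' @return a `differential_result` data.frame with columns `analyte_id`,
#'   `group_a`, `group_b`, `fold_change`, `ci_low`, `ci_high`, `p_raw`,
#'   `q_bh`, `direction` (`up`/`down`/`ns`, for group_b relative to
#'   group_a)
#' @export
differential_analysis <- function(matrix, metadata, group_a, group_b,
                                  ci_level = 0.95, n_boot = 2000, seed = 1,
                                  q_threshold = 0.05) {
  fc <- fold_change(matrix, metadata, group_a, group_b, ci_level, n_boot,
                    seed)
  p <- wilcoxon_mw(matrix, metadata, group_a, group_b)
  fc$p_raw <- unname(p[fc$analyte_id])
  fc$q_bh <- unname(bh_adjust(p)[fc$analyte_id])
  fc$direction <- ifelse(fc$q_bh >= q_threshold, "ns",
                         ifelse(fc$fold_change > 0, "up", "down"))
  fc
}

#' Roll up significant analytes into annotation classes
#'
#' Mirrors the manual clustering of metabolites into chemical-structure /
#' pathway classes: for each direction of change, counts significant
#' analytes per class and the percentage of that direction's total.
#' Unannotated analytes fall into class `"unknown"`.
#'
#' @param results a `differential_result` from [differential_analysis()]
#' @param annotation named character vector or two-column data.frame
#'   (`analyte_id`, `class`) mapping analytes to class labels
#' @param q_threshold significance threshold on `q_bh`
#' @return data.frame with columns `direction`, `class`, `n`, `percent`
#' @export
class_rollup <- function(results, annotation = NULL, q_threshold = 0.05) {
  if (is.data.frame(annotation))
    annotation <- stats::setNames(as.character(annotation$class),
                                  annotation$analyte_id)
  sig <- results[results$q_bh < q_threshold, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(direction = character(0), class = character(0),
                      n = integer(0), percent = numeric(0)))
  cls <- annotation[sig$analyte_id]
  cls[is.na(cls)] <- "unknown"
  dir <- ifelse(sig$fold_change > 0, "up", "down")
  out <- do.call(rbind, lapply(unique(dir), function(d) {
    tb <- sort(table(cls[dir == d]), decreasing = TRUE)
    data.frame(direction = d, class = names(tb), n = as.integer(tb),
               percent = 100 * as.integer(tb) / sum(dir == d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
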