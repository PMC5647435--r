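#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model, computed from
#' the pair-count contingency table:
#' ARI = (Index - Expected) / (Max - Expected).
#'
#' @param partition_a,partition_b named vectors of cluster labels over
#'   the same id set (names), or unnamed vectors of equal length in
#'   matching order
#' @return a real in `[-1, 1]`; 1 for identical partitions
#' @export
adjusted_rand <- function(partition_a, partition_b) {
  if (!is.null(names(partition_a)) || !is.null(names(partition_b))) {
    common <- intersect(names(partition_a), names(partition_b))
    if (!length(common)) stop("partitions share no ids")
    partition_a <- partition_a[common]
    partition_b <- partition_b[common]
  } else if (length(partition_a) != length(partition_b))
    stop("unnamed partitions must have equal length")
  ct <- table(partition_a, partition_b)
  n <- sum(ct)
  if (n < 2) stop("need at least 2 elements")
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Recovery of planted structure by the pipeline
#'
#' Scores a detected module partition (and optionally its eigengenes and
#' design associations) against the generator's ground truth:
#' \describe{
#'   \item{ari}{adjusted Rand index between detected and planted module
#'     labels over analytes assigned by both (grey and planted
#'     background excluded by default)}
#'   \item{background_rejection}{fraction of planted background analytes
#'     (among those entering the comparison universe) left grey}
#'   \item{module_purity}{per detected module, the largest fraction of
#'     members from one planted module}
#'   \item{eigengene_fidelity}{mean over detected modules of the best
#'     absolute correlation between the module eigengene and any planted
#'     latent activity}
#'   \item{trait_assignment_accuracy}{fraction of flagged modules whose
#'     dominant planted trait matches the flagged factor}
#' }
#'
#' @param truth ground truth from [simulate_cohort()] (`$truth`)
#' @param partition a `module_partition` from [detect_modules()]
#' @param eigengenes optional `eigengene_table`
#' @param associations optional `module_association` table
#' @param include_background include planted-background/grey analytes in
#'   the ARI (default `FALSE`)
#' @return a list of class `recovery_report`
#' @export
recovery_report <- function(truth, partition, eigengenes = NULL,
                            associations = NULL,
                            include_background = FALSE) {
  tr <- truth$partition
  common <- intersect(tr$analyte_id, partition$analyte_id)
  if (!length(common)) stop("no shared analyte ids with the ground truth")
  planted <- stats::setNames(tr$module_id, tr$analyte_id)[common]
  detected <- stats::setNames(partition$module,
                              partition$analyte_id)[common]
  if (include_background) {
    ari <- adjusted_rand(planted, detected)
  } else {
    use <- planted != "background" & detected != "grey"
    ari <- if (sum(use) >= 2) adjusted_rand(planted[use], detected[use])
    else NA_real_
  }
  bg <- planted == "background"
  background_rejection <- if (any(bg)) mean(detected[bg] == "grey")
  else NA_real_
  mods <- setdiff(unique(detected), "grey")
  purity <- vapply(mods, function(m) {
    tb <- table(planted[detected == m])
    max(tb) / sum(tb)
  }, numeric(1))

  fidelity <- dominant_trait <- NULL
  if (!is.null(eigengenes)) {
    act <- truth$activities
    samp <- intersect(colnames(eigengenes$scores), colnames(act))
    cors <- abs(stats::cor(t(eigengenes$scores[, samp, drop = FALSE]),
                           t(act[, samp, drop = FALSE])))
    fidelity <- apply(cors, 1, max)
  }
  accuracy <- NA_real_
  if (!is.null(associations)) {
    flagged <- associations[associations$flagged_of_interest, , drop = FALSE]
    if (nrow(flagged)) {
      good <- vapply(seq_len(nrow(flagged)), function(i) {
        m <- flagged$module[i]
        tb <- table(planted[detected == m & planted != "background"])
        if (!length(tb)) return(FALSE)
        dom <- names(tb)[which.max(tb)]
        trait <- truth$module_traits[dom]
        facs <- strsplit(flagged$flagged_factors[i], "+", fixed = TRUE)[[1]]
        trait %in% facs ||
          (trait == "neutral" && identical(facs, "interaction"))
      }, logical(1))
      accuracy <- mean(good)
    }
  }
  structure(list(ari = ari, background_rejection = background_rejection,
                 module_purity = purity,
                 eigengene_fidelity = if (!is.null(fidelity)) mean(fidelity)
                 else NA_real_,
                 eigengene_fidelity_per_module = fidelity,
                 trait_assignment_accuracy = accuracy),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report\n")
  cat(sprintf("  ARI (planted vs detected):    %.3f\n", x$ari))
  cat(sprintf("  background rejection:         %.3f\n",
              x$background_rejection))
  cat(sprintf("  mean module purity:           %.3f\n",
              mean(x$module_purity)))
  cat(sprintf("  mean eigengene fidelity:      %.3f\n",
              x$eigengene_fidelity))
  cat(sprintf("  trait assignment accuracy:    %.3f\n",
              x$trait_assignment_accuracy))
  invisible(x)
}
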