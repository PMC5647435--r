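#' Pooled-QC relative standard deviation filter
#'
#' Computes, per metabolite feature, the relative standard deviation
#' (RSD, percent: 100 * SD / mean) over its non-missing values in the
#' pooled-QC injections, and marks features with RSD above `threshold`
#' as technically unreliable. Features never detected in any QC
#' injection are likewise removed (reason `rsd`): technical
#' reproducibility cannot be established for them.
#'
#' Transcriptome matrices have no pooled-QC concept; they pass through
#' unfiltered with a warning.
#'
#' @param matrix an [omics_matrix()]
#' @param metadata a [sample_metadata()] table
#' @param threshold RSD removal threshold in percent (default 20)
#' @return a `filter_report` data.frame with columns `analyte_id`,
#'   `qc_rsd`, `detection_fraction` (NA here), `kept`, `removal_reason`
#' @export
qc_rsd_filter <- function(matrix, metadata, threshold = 20) {
  ids <- analyte_ids(matrix)
  if (matrix$dataset_tag == "transcriptome") {
    warning("transcriptome input: QC RSD filter is a pass-through")
    return(.filter_report(ids, qc_rsd = NA_real_, kept = TRUE,
                          reason = "none"))
  }
  qc <- intersect(qc_samples(metadata), sample_ids(matrix))
  if (length(qc) < 2)
    stop("QC RSD filter requires >= 2 pooled-QC samples for a metabolome ",
         "dataset; found ", length(qc))
  v <- matrix$values[, qc, drop = FALSE]
  mu <- rowMeans(v, na.rm = TRUE)
  sd_ <- apply(v, 1, stats::sd, na.rm = TRUE)
  n_obs <- rowSums(!is.na(v))
  rsd <- ifelse(n_obs >= 2, 100 * sd_ / mu, NA_real_)
  removed <- is.na(rsd) | rsd > threshold
  .filter_report(ids, qc_rsd = rsd, kept = !removed,
                 reason = ifelse(removed, "rsd", "none"))
}

#' Detection-rate filter
#'
#' Removes features detected (non-missing) in fewer than `min_detection`
#' of the biological samples. Pooled-QC columns are excluded from the
#' denominator by default; set `include_qc = TRUE` for the alternative
#' reading that counts QC injections among "samples".
#'
#' @param matrix an [omics_matrix()]
#' @param metadata a [sample_metadata()] table
#' @param min_detection minimum detection fraction (default 0.70)
#' @param include_qc count QC samples in the detection denominator
#' @return a `filter_report` data.frame (see [qc_rsd_filter()])
#' @export
detection_filter <- function(matrix, metadata, min_detection = 0.70,
                             include_qc = FALSE) {
  pool <- if (include_qc) metadata$sample_id else biological_samples(metadata)
  cols <- intersect(pool, sample_ids(matrix))
  if (!length(cols)) stop("no biological samples found in the matrix")
  v <- matrix$values[, cols, drop = FALSE]
  frac <- rowSums(!is.na(v)) / length(cols)
  removed <- frac < min_detection
  .filter_report(analyte_ids(matrix), detection = frac, kept = !removed,
                 reason = ifelse(removed, "detection", "none"))
}

#' Combined feature-quality filtering
#'
#' Applies the pooled-QC RSD filter and the detection filter and combines
#' them. Under `rule = "independent"` (the default) a feature is removed
#' if it fails either criterion; `rule = "conjunctive"` implements the
#' literal conjunctive reading (removed only when it fails both).
#'
#' @inheritParams qc_rsd_filter
#' @param min_detection minimum detection fraction over biological samples
#' @param rule `"independent"` (OR-removal) or `"conjunctive"` (AND)
#' @return a `filter_report` with both criteria's columns filled;
#'   `removal_reason` names the first failing criterion (`rsd` before
#'   `detection`)
#' @export
apply_feature_filters <- function(matrix, metadata, threshold = 20,
                                  min_detection = 0.70,
                                  rule = c("independent", "conjunctive")) {
  rule <- match.arg(rule)
  det <- detection_filter(matrix, metadata, min_detection)
  if (matrix$dataset_tag == "transcriptome") {
    rep_ <- .filter_report(analyte_ids(matrix), detection = det$detection_fraction,
                           kept = TRUE, reason = "none")
    return(rep_)
  }
  rsd <- qc_rsd_filter(matrix, metadata, threshold)
  fail_rsd <- !rsd$kept
  fail_det <- !det$kept
  removed <- if (rule == "independent") fail_rsd | fail_det else
    fail_rsd & fail_det
  .filter_report(analyte_ids(matrix), qc_rsd = rsd$qc_rsd,
                 detection = det$detection_fraction, kept = !removed,
                 reason = ifelse(!removed, "none",
                                 ifelse(fail_rsd, "rsd", "detection")))
}

#' Drop removed analytes according to a filter report
#' @param matrix an [omics_matrix()]
#' @param report a `filter_report` for this matrix
#' @return filtered `omics_matrix`
#' @export
apply_filter_report <- function(matrix, report) {
  keep <- report$analyte_id[report$kept]
  if (!length(keep)) stop("no analytes survive filtering")
  subset_omics(matrix, analytes = keep)
}

.filter_report <- function(ids, qc_rsd = NA_real_, detection = NA_real_,
                           kept, reason) {
  out <- data.frame(analyte_id = ids, qc_rsd = qc_rsd,
                    detection_fraction = detection, kept = kept,
                    removal_reason = reason, stringsAsFactors = FALSE)
  stopifnot(all(out$kept == (out$removal_reason == "none")))
  class(out) <- c("filter_report", "data.frame")
  out
}
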