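#' @title Omics abundance matrix
#'
#' @description An `omics_matrix` holds one dataset's analyte x sample
#' abundance table: a numeric matrix with analyte ids as row names, sample
#' ids as column names, and `NA` marking missing (undetected) entries.
#' Missing values are only permitted for metabolome datasets; RNA-seq
#' expression estimates are complete by construction.
#'
#' @param values numeric matrix, analytes in rows, samples in columns; row
#'   and column names are mandatory and unique. Non-missing entries must be
#'   non-negative.
#' @param dataset_tag one of `"transcriptome"`, `"metabolome_pos"`,
#'   `"metabolome_neg"`.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, dataset_tag = c("transcriptome",
                                                 "metabolome_pos",
                                                 "metabolome_neg")) {
  dataset_tag <- match.arg(dataset_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry analyte row names and sample column names")
  dup_a <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_a))
    stop("duplicate analyte id(s): ", paste(dup_a, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (any(values < 0, na.rm = TRUE))
    stop("negative abundance values are not allowed")
  if (dataset_tag == "transcriptome" && anyNA(values))
    stop("missing values are not allowed in a transcriptome matrix")
  structure(list(values = values, dataset_tag = dataset_tag),
            class = "omics_matrix")
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("omics_matrix [%s]: %d analytes x %d samples, %.1f%% missing\n",
              x$dataset_tag, nrow(v), ncol(v), 100 * mean(is.na(v))))
  invisible(x)
}

#' Analyte ids of an omics matrix
#' @param x an `omics_matrix`
#' @return character vector of analyte ids
#' @export
analyte_ids <- function(x) rownames(x$values)

#' Sample ids of an omics matrix
#' @param x an `omics_matrix`
#' @return character vector of sample ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an omics matrix by analytes and/or samples
#'
#' @param x an `omics_matrix`
#' @param analytes,samples character vectors of ids to keep (default all)
#' @return a new `omics_matrix`
#' @export
subset_omics <- function(x, analytes = analyte_ids(x), samples = sample_ids(x)) {
  missing_a <- setdiff(analytes, analyte_ids(x))
  if (length(missing_a))
    stop("unknown analyte id(s): ", paste(utils::head(missing_a, 5), collapse = ", "))
  missing_s <- setdiff(samples, sample_ids(x))
  if (length(missing_s))
    stop("unknown sample id(s): ", paste(utils::head(missing_s, 5), collapse = ", "))
  omics_matrix(x$values[analytes, samples, drop = FALSE], x$dataset_tag)
}

#' Sample metadata table
#'
#' Builds and validates the per-sample design table: diet (`CON`/`HFD`),
#' exercise (`pre`/`post`), a pooled-QC flag and the injection run order.
#' QC samples carry `NA` for both design factors.
#'
#' @param sample_id character vector of unique sample ids
#' @param diet factor/character in `{CON, HFD}` (`NA` for QC samples)
#' @param exercise factor/character in `{pre, post}` (`NA` for QC samples)
#' @param is_qc logical pooled-QC flag
#' @param run_order integer injection order (unique)
#' @return a `data.frame` of class `sample_metadata`
#' @export
sample_metadata <- function(sample_id, diet, exercise, is_qc,
                            run_order = seq_along(sample_id)) {
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in metadata")
  diet <- as.character(diet); exercise <- as.character(exercise)
  ok_diet <- is.na(diet) | diet %in% c("CON", "HFD")
  ok_ex <- is.na(exercise) | exercise %in% c("pre", "post")
  if (!all(ok_diet)) stop("diet must be CON or HFD (NA for QC)")
  if (!all(ok_ex)) stop("exercise must be pre or post (NA for QC)")
  if (!is.logical(is_qc) || anyNA(is_qc)) stop("is_qc must be TRUE/FALSE")
  if (any(!is_qc & (is.na(diet) | is.na(exercise))))
    stop("biological samples must have both diet and exercise set")
  if (anyDuplicated(run_order)) stop("run_order must be unique")
  out <- data.frame(sample_id = as.character(sample_id), diet = diet,
                    exercise = exercise, is_qc = is_qc,
                    run_order = as.integer(run_order),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Biological (non-QC) sample ids in a metadata table
#' @param metadata a `sample_metadata` table
#' @return character vector
#' @export
biological_samples <- function(metadata) {
  metadata$sample_id[!metadata$is_qc]
}

#' Pooled-QC sample ids in a metadata table
#' @param metadata a `sample_metadata` table
#' @return character vector
#' @export
qc_samples <- function(metadata) {
  metadata$sample_id[metadata$is_qc]
}

#' Sample ids belonging to one diet x exercise group
#'
#' Group labels follow the `<diet>_<exercise>` convention, e.g. `"HFD_pre"`.
#'
#' @param metadata a `sample_metadata` table
#' @param group a label like `"CON_pre"`, `"HFD_post"`
#' @return character vector of sample ids
#' @export
group_samples <- function(metadata, group) {
  parts <- strsplit(group, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("CON", "HFD") ||
      !parts[2] %in% c("pre", "post"))
    stop("group must be one of CON_pre, CON_post, HFD_pre, HFD_post")
  with(metadata, sample_id[!is_qc & diet == parts[1] & exercise == parts[2]])
}
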