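#' Read an analyte x sample TSV into an omics matrix
#'
#' The expected dialect is a tab-separated table whose first column holds
#' analyte ids and whose header row holds sample ids. Empty cells and any
#' string in `na_strings` parse to missing. Metabolite feature ids are
#' typically "m/z_rt" pair strings and may contain commas, which is why the
#' on-disk format is TSV rather than CSV.
#'
#' @param path file path
#' @param dataset_tag dataset label, see [omics_matrix()]
#' @param na_strings strings parsed as missing (besides the empty cell)
#' @return an `omics_matrix`
#' @export
read_matrix <- function(path, dataset_tag, na_strings = c("NA", "")) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("malformed header in ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = na_strings, check.names = FALSE,
                           colClasses = c("character", rep("numeric",
                                                           length(header) - 1L)),
                           stringsAsFactors = FALSE)
  if (any(lengths(strsplit(readLines(path), "\t", fixed = TRUE)) !=
          length(header)))
    stop("ragged rows in ", path)
  ids <- tab[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate analyte id(s) in ", path, ": ",
                        paste(dup, collapse = ", "))
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- ids
  omics_matrix(values, dataset_tag)
}

#' Write an omics matrix as TSV
#'
#' Missing entries are written as the literal string `NA`; round-trips
#' through [read_matrix()] reproduce the matrix including its missing mask.
#'
#' @param x an `omics_matrix`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_matrix <- function(x, path) {
  v <- x$values
  chr <- matrix(sprintf("%.17g", v), nrow(v), dimnames = dimnames(v))
  chr[is.na(v)] <- "NA"
  tab <- data.frame(analyte_id = analyte_ids(x), chr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata TSV
#' @param path file path to a table with columns sample_id, diet, exercise,
#'   is_qc, run_order
#' @return a `sample_metadata` table
#' @export
read_metadata <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("sample_id", "diet", "exercise", "is_qc", "run_order")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  sample_metadata(tab$sample_id, tab$diet, tab$exercise,
                  as.logical(tab$is_qc), tab$run_order)
}

#' Write a sample metadata table as TSV
#' @param metadata a `sample_metadata` table
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' GMT is tab-delimited: set name, description, then member ids, one set
#' per line.
#'
#' @param path file path
#' @return named list of character vectors of member ids
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}
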