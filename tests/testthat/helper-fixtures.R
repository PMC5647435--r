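# Shared fixtures built in code at test time.

# small metabolome matrix with explicit QC columns
make_metab <- function(values_bio, values_qc,
                       tag = "metabolome_pos") {
  stopifnot(nrow(values_bio) == nrow(values_qc))
  n_bio <- ncol(values_bio)
  n_qc <- ncol(values_qc)
  v <- cbind(values_bio, values_qc)
  rownames(v) <- sprintf("m_%03d", seq_len(nrow(v)))
  colnames(v) <- c(sprintf("S%02d", seq_len(n_bio)),
                   sprintf("QC_%02d", seq_len(n_qc)))
  m <- omics_matrix(v, tag)
  md <- sample_metadata(
    sample_id = colnames(v),
    diet = c(rep(c("CON", "HFD"), each = n_bio / 2), rep(NA, n_qc)),
    exercise = c(rep(c("pre", "post"), n_bio / 2), rep(NA, n_qc)),
    is_qc = c(rep(FALSE, n_bio), rep(TRUE, n_qc)))
  list(matrix = m, metadata = md)
}

# scaled-down cohort config for fast end-to-end tests
small_sim_config <- function(seed = 1, ...) {
  args <- list(n_per_group = 6, n_qc = 8, n_transcripts = 300,
               n_metabolites_pos = 120, n_metabolites_neg = 120,
               n_modules = 3, module_size_range = c(12, 16), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# metadata for a plain 2x2 design with no QC samples
design_metadata <- function(n_per_group = 6) {
  g <- expand.grid(exercise = c("pre", "post"), diet = c("CON", "HFD"),
                   stringsAsFactors = FALSE)
  ids <- unlist(lapply(seq_len(nrow(g)), function(i)
    paste0(g$diet[i], "_", g$exercise[i], "_", seq_len(n_per_group))))
  sample_metadata(ids,
                  diet = rep(g$diet, each = n_per_group),
                  exercise = rep(g$exercise, each = n_per_group),
                  is_qc = rep(FALSE, length(ids)))
}

# omics matrix over a design's samples from a plain numeric matrix
as_omics <- function(values, metadata, tag = "metabolome_pos",
                     prefix = "m") {
  rownames(values) <- sprintf("%s_%03d", prefix, seq_len(nrow(values)))
  colnames(values) <- metadata$sample_id[seq_len(ncol(values))]
  omics_matrix(values, tag)
}

# random symmetric adjacency in [0,1] with unit diagonal
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# block TOM: perfect within-block overlap, none between
block_tom <- function(sizes) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  tom <- outer(lab, lab, function(i, j) as.numeric(i == j))
  dimnames(tom) <- list(sprintf("n%03d", 1:n), sprintf("n%03d", 1:n))
  tom
}
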