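# first principal component of an analyte x sample block: sample scores
# (first right singular vector of the row-standardised block) plus the
# fraction of variance explained
.first_pc <- function(block) {
  b <- t(scale(t(block)))
  b[!is.finite(b)] <- 0
  sv <- svd(b, nu = 0, nv = 1)
  scores <- sv$v[, 1]
  # orientation: positive correlation with the module mean profile
  mp <- colMeans(b)
  if (sum(mp * scores) < 0) scores <- -scores
  list(scores = scores, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' member x sample submatrix: the sample-score vector (unit norm) of the
#' leading singular direction. Orientation is fixed so the eigengene
#' correlates positively with the module's mean analyte profile. Grey
#' (unassigned) analytes are excluded.
#'
#' @param combined a `combined_matrix` from [combine_and_scale()]
#' @param partition a `module_partition` from [detect_modules()]
#' @return an `eigengene_table`: list with `scores` (module x sample),
#'   `var_explained` (named per module)
#' @export
module_eigengenes <- function(combined, partition) {
  missing_ids <- setdiff(partition$analyte_id, rownames(combined$values))
  if (length(missing_ids))
    stop("partition names analytes absent from the combined matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  mods <- setdiff(unique(partition$module), "grey")
  if (!length(mods)) stop("no modules (all analytes grey)")
  scores <- matrix(NA_real_, length(mods), ncol(combined$values),
                   dimnames = list(mods, colnames(combined$values)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    members <- partition$analyte_id[partition$module == m]
    if (length(members) == 1)
      warning("module ", m, " has a single analyte; eigengene is its ",
              "scaled profile")
    pc <- .first_pc(combined$values[members, , drop = FALSE])
    scores[m, ] <- pc$scores
    ve[m] <- pc$var_explained
  }
  structure(list(scores = scores, var_explained = ve),
            class = "eigengene_table")
}

#' Associate module eigengenes with the diet x exercise design
#'
#' For every module eigengene: Pearson correlation with the HFD
#' indicator and with the post-exercise indicator (with correlation-test
#' p-values), an interaction p-value from the two-factor fixed-effects
#' linear model eigengene ~ diet * exercise, and BH adjustment across
#' modules within each factor. A module is flagged of interest when any
#' factor's q-value falls below `alpha`.
#'
#' @param eigengenes an `eigengene_table` from [module_eigengenes()]
#' @param metadata a [sample_metadata()] table (biological samples must
#'   cover >= 2 samples in every design cell)
#' @param alpha flagging threshold on the BH q-values (default 0.05)
#' @return data.frame of class `module_association`: one row per module
#'   with `diet_cor`, `diet_p`, `diet_q`, `exercise_cor`, `exercise_p`,
#'   `exercise_q`, `interaction_p`, `interaction_q`,
#'   `flagged_of_interest`, `flagged_factors`
#' @export
associate_modules <- function(eigengenes, metadata, alpha = 0.05) {
  samp <- colnames(eigengenes$scores)
  md <- metadata[match(samp, metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("eigengene samples missing from metadata")
  md <- md[!md$is_qc, ]
  cells <- table(md$diet, md$exercise)
  if (sum(cells > 0) < 2)
    stop("the design has a single cell; association is not estimable")
  if (!all(dim(cells) == c(2, 2)) || any(cells < 2))
    stop("every diet x exercise design cell needs >= 2 samples")
  es <- eigengenes$scores[, md$sample_id, drop = FALSE]
  hfd <- as.numeric(md$diet == "HFD")
  post <- as.numeric(md$exercise == "post")
  one <- function(e) {
    ct_d <- stats::cor.test(e, hfd)
    ct_e <- stats::cor.test(e, post)
    an <- stats::anova(stats::lm(e ~ hfd * post))
    c(diet_cor = unname(ct_d$estimate), diet_p = ct_d$p.value,
      exercise_cor = unname(ct_e$estimate), exercise_p = ct_e$p.value,
      interaction_p = an["hfd:post", "Pr(>F)"])
  }
  stats_ <- t(apply(es, 1, one))
  out <- data.frame(module = rownames(es), stats_, stringsAsFactors = FALSE)
  out$diet_q <- bh_adjust(out$diet_p)
  out$exercise_q <- bh_adjust(out$exercise_p)
  out$interaction_q <- bh_adjust(out$interaction_p)
  flags <- cbind(diet = out$diet_q < alpha, exercise = out$exercise_q < alpha,
                 interaction = out$interaction_q < alpha)
  out$flagged_of_interest <- rowSums(flags) > 0
  out$flagged_factors <- apply(flags, 1, function(f)
    paste(colnames(flags)[f], collapse = "+"))
  rownames(out) <- NULL
  class(out) <- c("module_association", "data.frame")
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value per gene set for the overlap
#' between a module's members and each set, both intersected with the
#' universe, with BH adjustment across sets.
#'
#' @param module_members character vector of analyte ids (must be a
#'   subset of `universe`)
#' @param gene_sets named list of character vectors (e.g. [read_gmt()])
#' @param universe character vector of all testable ids
#' @return data.frame with `set`, `set_size`, `overlap`, `p`, `q_bh`,
#'   `overlap_ids`
#' @export
overrepresentation <- function(module_members, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  extra <- setdiff(module_members, universe)
  if (length(extra))
    stop("module members outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  module_members <- unique(module_members)
  n_u <- length(universe)
  n_m <- length(module_members)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    ov <- intersect(module_members, set)
    p <- stats::phyper(length(ov) - 1, length(set), n_u - length(set), n_m,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = length(ov),
               p = p, overlap_ids = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- bh_adjust(out$p)
  out[, c("set", "set_size", "overlap", "p", "q_bh", "overlap_ids")]
}
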