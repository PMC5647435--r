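#' Network construction parameters
#'
#' @param beta soft-threshold power (positive integer) or `"auto"` to
#'   select by the scale-free topology criterion at pipeline level
#' @param network_sign `"unsigned"` (adjacency |cor|^beta, the default)
#'   or `"signed"` (((1+cor)/2)^beta)
#' @param min_module_size smallest admissible module (default 20)
#' @param merge_cut_height modules whose eigengenes correlate above
#'   1 - merge_cut_height are merged (default 0.25)
#' @param cut_height dendrogram cut height on the 1 - TOM dissimilarity
#'   (default 0.99); branches joining above it are separate
#' @param deep_split split sensitivity (0-4, default 2); larger values
#'   accept more finely separated branches as modules
#' @param kme_min module-membership refinement threshold: after the tree
#'   cut, analytes are reassigned to the module whose eigengene they
#'   correlate with best, provided |cor| >= `kme_min`, otherwise grey;
#'   0 disables refinement
#' @return a validated `network_params` list
#' @export
network_params <- function(beta = 6, network_sign = c("unsigned", "signed"),
                           min_module_size = 20, merge_cut_height = 0.25,
                           cut_height = 0.99, deep_split = 2,
                           kme_min = 0.5) {
  network_sign <- match.arg(network_sign)
  if (!identical(beta, "auto") && (beta < 1 || beta != round(beta)))
    stop("`beta` must be a positive integer or \"auto\"")
  if (min_module_size < 3) stop("`min_module_size` must be >= 3")
  if (merge_cut_height < 0 || merge_cut_height > 1)
    stop("`merge_cut_height` must lie in [0, 1]")
  if (cut_height <= 0 || cut_height > 1)
    stop("`cut_height` must lie in (0, 1]")
  if (kme_min < 0 || kme_min >= 1) stop("`kme_min` must lie in [0, 1)")
  structure(list(beta = beta, network_sign = network_sign,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 cut_height = cut_height, deep_split = deep_split,
                 kme_min = kme_min),
            class = "network_params")
}

#' Retain the most variable analytes of a dataset
#'
#' Keeps the ceil(`top_fraction` x n) analytes with the largest sample
#' variance, computed over biological samples. Ties are broken
#' deterministically by analyte id (lexicographic).
#'
#' @param matrix a complete [omics_matrix()] (biological samples only, or
#'   supply `metadata` to restrict)
#' @param top_fraction fraction of analytes to keep (default 0.20)
#' @param metadata optional [sample_metadata()]; when given, QC columns
#'   are dropped and variance uses biological samples only
#' @return an `omics_matrix` restricted to the selected analytes
#' @export
variance_select <- function(matrix, top_fraction = 0.20, metadata = NULL) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("`top_fraction` must lie in (0, 1]")
  if (!is.null(metadata))
    matrix <- subset_omics(matrix, samples = intersect(
      biological_samples(metadata), sample_ids(matrix)))
  v <- matrix$values
  if (anyNA(v)) stop("impute before variance selection")
  n_keep <- ceiling(top_fraction * nrow(v))
  if (n_keep < 2) stop("fewer than 2 analytes would remain after selection")
  vars <- apply(v, 1, stats::var)
  ord <- order(-vars, rownames(v))
  subset_omics(matrix, analytes = rownames(v)[ord[seq_len(n_keep)]])
}

#' Combine per-dataset matrices into one standardised analyte matrix
#'
#' Row-concatenates the selected per-dataset matrices over their common
#' biological samples, then centres and scales every analyte to mean 0,
#' SD 1. The result is the input to network construction.
#'
#' @param matrices named list of [omics_matrix()] objects (names are
#'   dataset tags); sample sets must coincide after dropping QC columns
#' @param metadata a [sample_metadata()] table
#' @return a `combined_matrix`: list with `values` (analyte x sample),
#'   `dataset` (tag per analyte)
#' @export
combine_and_scale <- function(matrices, metadata) {
  bio <- biological_samples(metadata)
  mats <- lapply(matrices, function(m)
    m$values[, intersect(bio, sample_ids(m)), drop = FALSE])
  samp <- colnames(mats[[1]])
  for (i in seq_along(mats)) {
    diff <- union(setdiff(samp, colnames(mats[[i]])),
                  setdiff(colnames(mats[[i]]), samp))
    if (length(diff))
      stop("biological sample sets differ between datasets: ",
           paste(diff, collapse = ", "))
    mats[[i]] <- mats[[i]][, samp, drop = FALSE]
  }
  values <- do.call(rbind, unname(mats))
  dataset <- rep(names(matrices), vapply(mats, nrow, integer(1)))
  if (anyNA(values)) stop("impute before combining")
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance analyte(s) cannot be z-scaled: ",
         paste(utils::head(rownames(values)[sds == 0], 5), collapse = ", "))
  values <- t(scale(t(values)))
  attr(values, "scaled:center") <- NULL
  attr(values, "scaled:scale") <- NULL
  structure(list(values = values, dataset = dataset),
            class = "combined_matrix")
}

#' Soft-threshold adjacency matrix
#'
#' Unsigned: a_ij = |cor(x_i, x_j)|^beta; signed: ((1 + cor)/2)^beta.
#' The diagonal is stored as 1 but excluded from connectivity sums.
#'
#' @param combined a `combined_matrix` from [combine_and_scale()], or a
#'   plain analyte x sample numeric matrix
#' @param beta soft-threshold power
#' @param network_sign `"unsigned"` or `"signed"`
#' @return symmetric adjacency matrix in `[0, 1]`
#' @export
adjacency_matrix <- function(combined, beta = 6,
                             network_sign = c("unsigned", "signed")) {
  network_sign <- match.arg(network_sign)
  v <- if (inherits(combined, "combined_matrix")) combined$values else combined
  cc <- stats::cor(t(v))
  a <- if (network_sign == "unsigned") abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(a) <- 1
  a
}

#' Node connectivity of an adjacency matrix
#' @param adj symmetric adjacency with unit diagonal
#' @return numeric vector k_i = sum_{j != i} a_ij
#' @export
connectivity <- function(adj) rowSums(adj) - diag(adj)

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivities, regresses log10 frequency on log10 mean bin
#' connectivity, and returns the signed fit index -sign(slope) * R^2
#' (positive only when frequency decays with connectivity, the
#' scale-free signature).
#'
#' @param k numeric vector of connectivities
#' @param n_bins histogram bins (default 10)
#' @return list with `fit` (signed R^2) and `slope`
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k)]
  if (length(unique(k)) < 2 || stats::sd(k) == 0)
    return(list(fit = NA_real_, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  meank <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & meank > 0
  if (sum(keep) < 3) return(list(fit = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[keep]) ~ log10(meank[keep]))
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  list(fit = -sign(slope) * r2, slope = slope)
}

#' Choose the soft-threshold power by the scale-free criterion
#'
#' Returns the smallest candidate beta whose signed scale-free fit R^2
#' reaches `r2_target`; if none reaches it, the argmax beta is returned
#' with a warning. Degenerate connectivity (all nodes equal) returns the
#' conventional default beta = 6 with a warning.
#'
#' @param combined a `combined_matrix` or plain analyte x sample matrix
#'   (>= 10 analytes)
#' @param candidate_betas candidate powers (default 1:20)
#' @param r2_target target signed R^2 (default 0.80)
#' @param network_sign see [adjacency_matrix()]
#' @return list with `beta`, and `table` of per-candidate fits
#' @export
pick_soft_power <- function(combined, candidate_betas = 1:20,
                            r2_target = 0.80,
                            network_sign = c("unsigned", "signed")) {
  network_sign <- match.arg(network_sign)
  v <- if (inherits(combined, "combined_matrix")) combined$values else combined
  if (nrow(v) < 10) stop("soft-power selection needs >= 10 analytes")
  cc <- stats::cor(t(v))
  base <- if (network_sign == "unsigned") abs(cc) else (1 + cc) / 2
  diag(base) <- 0
  fits <- vapply(candidate_betas, function(b) {
    k <- rowSums(base^b)
    if (stats::sd(k) < 1e-12) return(NA_real_)
    scale_free_fit(k)$fit
  }, numeric(1))
  tab <- data.frame(beta = candidate_betas, fit = fits)
  if (all(is.na(fits))) {
    warning("degenerate connectivity; returning default beta = 6")
    return(list(beta = 6L, table = tab))
  }
  hit <- which(!is.na(fits) & fits >= r2_target)
  if (length(hit)) {
    beta <- candidate_betas[hit[1]]
  } else {
    beta <- candidate_betas[which.max(fits)]
    warning("no candidate beta reached scale-free R^2 >= ", r2_target,
            "; using argmax beta = ", beta)
  }
  list(beta = as.integer(beta), table = tab)
}

#' Topological overlap matrix
#'
#' TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' L_ij = sum_{u != i,j} a_iu a_uj and k_i = sum_{u != i} a_iu; the
#' diagonal is 1. The clustering dissimilarity is 1 - TOM.
#'
#' @param adj symmetric adjacency in `[0, 1]` with unit diagonal
#' @return symmetric TOM in `[0, 1]`
#' @export
topological_overlap <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-12)) stop("adjacency must be symmetric")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a                      # L_ij = sum_u a_iu a_uj, u != i,j
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# WGCNA's conventional module colour sequence (size-ordered labels)
.module_colours <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

.colour_for <- function(i) {
  ifelse(i <= length(.module_colours), .module_colours[pmin(i, length(.module_colours))],
         paste0("module", i))
}

#' Detect modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering of 1 - TOM followed by an
#' adaptive branch cut. Average linkage is monotone, so every dendrogram
#' branch's internal cohesion is the height of its own top merge; a
#' branch is declared a module when it (a) has at least
#' `min_module_size` members, (b) is cohesive (own height at most
#' `cut_height`), and (c) is separated from its surroundings: the height
#' at which it joins the rest of the tree exceeds its own height by at
#' least a gap controlled by `deep_split` (0 = 0.05 ... 4 = 0.005;
#' default 2 = 0.02). Maximal qualifying branches are taken top-down, so
#' loosely attached stragglers fall back to grey rather than diluting a
#' module. Chains of mutually unrelated analytes accrue height in tiny
#' increments, never open a gap, and end up grey.
#'
#' When the combined expression matrix is supplied, modules whose
#' eigengenes correlate above 1 - `merge_cut_height` are merged
#' iteratively. Modules are labelled with the conventional colour
#' sequence in decreasing size order; ties in size break by the smallest
#' member analyte id.
#'
#' @param tom a TOM from [topological_overlap()] with analyte dimnames
#' @param params a [network_params()]
#' @param combined optional `combined_matrix` used for the eigengene
#'   merge stage (skipped when absent)
#' @return a `module_partition` data.frame: `analyte_id`, `dataset`
#'   (when known), `module` colour, plus attribute `dendrogram`
#'   (the hclust object)
#' @export
detect_modules <- function(tom, params = network_params(), combined = NULL) {
  n <- nrow(tom)
  ids <- rownames(tom)
  if (is.null(ids)) ids <- paste0("node", seq_len(n))
  if (n < params$min_module_size) {
    warning("fewer analytes than min_module_size; all grey")
    return(.module_partition(ids, rep("grey", n), combined, dend = NULL))
  }
  d <- stats::as.dist(1 - tom)
  dend <- stats::hclust(d, method = "average")
  gap <- c(0.05, 0.03, 0.02, 0.01, 0.005)[
    pmin(pmax(params$deep_split, 0), 4) + 1]
  assign <- .branch_cut(dend, min_size = params$min_module_size,
                        cut_height = params$cut_height, gap = gap)
  keep <- setdiff(unique(assign), "grey")
  if (!is.null(combined) && length(keep) > 1)
    assign <- .merge_close_modules(assign, combined, ids,
                                   params$merge_cut_height)
  if (!is.null(combined) && params$kme_min > 0)
    assign <- .kme_refine(assign, combined, ids, params$kme_min,
                          params$min_module_size)
  .module_partition(ids, assign, combined, dend = dend)
}

# module-membership refinement: reassign every analyte to the module whose
# eigengene it correlates with most strongly (absolute value), grey when no
# module reaches kme_min; iterate to a fixed point (at most 3 rounds) and
# drop modules that shrink below min_size
.kme_refine <- function(assign, combined, ids, kme_min, min_size,
                        max_iter = 3) {
  for (iter in seq_len(max_iter)) {
    labs <- setdiff(unique(assign), "grey")
    if (!length(labs)) return(assign)
    eig <- vapply(labs, function(l) {
      .first_pc(combined$values[ids[assign == l], , drop = FALSE])$scores
    }, numeric(ncol(combined$values)))
    kme <- abs(stats::cor(t(combined$values[ids, , drop = FALSE]), eig))
    best <- max.col(kme, ties.method = "first")
    new_assign <- ifelse(kme[cbind(seq_along(ids), best)] >= kme_min,
                         labs[best], "grey")
    sizes <- table(new_assign)
    small <- setdiff(names(sizes)[sizes < min_size], "grey")
    new_assign[new_assign %in% small] <- "grey"
    if (identical(new_assign, assign)) return(assign)
    assign <- new_assign
  }
  assign
}

# top-down adaptive branch cut on a monotone (average-linkage) dendrogram:
# a branch qualifies as a module iff size >= min_size, own merge height
# <= cut_height, and (join height - own height) >= gap; the root's virtual
# join height is 1, the maximum of the 1 - TOM dissimilarity. A qualifying
# branch is accepted only when neither of its children qualifies on its
# own, so nested separated structure splits as deep as the gap criterion
# supports; sibling over-splits are healed later by the eigengene merge.
.branch_cut <- function(dend, min_size, cut_height, gap) {
  merge <- dend$merge
  h <- dend$height
  n <- length(dend$order)
  sizes <- integer(nrow(merge))
  for (i in seq_len(nrow(merge)))
    sizes[i] <- sum(ifelse(merge[i, ] < 0, 1L, sizes[pmax(merge[i, ], 1)]))
  qualifies <- function(node, join_h) {
    node > 0 && sizes[node] >= min_size && h[node] <= cut_height &&
      join_h - h[node] >= gap
  }
  members <- function(node) {
    # iterative stack walk; returns leaf indices under internal node
    out <- integer(0); stack <- node
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (x < 0) out <- c(out, -x) else stack <- c(stack, merge[x, ])
    }
    out
  }
  assign <- rep("grey", n)
  mod_i <- 0L
  stack_node <- nrow(merge)
  stack_join <- 1
  while (length(stack_node)) {
    node <- stack_node[length(stack_node)]
    join_h <- stack_join[length(stack_node)]
    stack_node <- stack_node[-length(stack_node)]
    stack_join <- stack_join[-length(stack_join)]
    if (node < 0) next
    child_q <- qualifies(merge[node, 1], h[node]) ||
      qualifies(merge[node, 2], h[node])
    if (qualifies(node, join_h) && !child_q) {
      mod_i <- mod_i + 1L
      assign[members(node)] <- paste0("B", mod_i)
    } else {
      stack_node <- c(stack_node, merge[node, ])
      stack_join <- c(stack_join, h[node], h[node])
    }
  }
  assign
}

# iteratively merge module pairs whose eigengenes correlate > 1 - cut
.merge_close_modules <- function(assign, combined, ids, merge_cut_height) {
  if (merge_cut_height <= 0) return(assign)
  repeat {
    labs <- setdiff(unique(assign), "grey")
    if (length(labs) < 2) return(assign)
    eig <- vapply(labs, function(l) {
      v <- combined$values[ids[assign == l], , drop = FALSE]
      .first_pc(v)$scores
    }, numeric(ncol(combined$values)))
    cc <- stats::cor(eig)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 1 - merge_cut_height) return(assign)
    assign[assign == labs[best[2]]] <- labs[best[1]]
  }
}

# label clusters by size-ordered colours; carries dataset tags when known
.module_partition <- function(ids, assign, combined = NULL, dend = NULL) {
  labs <- setdiff(unique(assign), "grey")
  if (length(labs)) {
    sizes <- vapply(labs, function(l) sum(assign == l), integer(1))
    first_id <- vapply(labs, function(l) min(ids[assign == l]), character(1))
    ord <- labs[order(-sizes, first_id)]
    colour_map <- stats::setNames(.colour_for(seq_along(ord)), ord)
    module <- ifelse(assign == "grey", "grey", colour_map[assign])
  } else module <- rep("grey", length(ids))
  out <- data.frame(analyte_id = ids,
                    dataset = if (!is.null(combined))
                      combined$dataset[match(ids, rownames(combined$values))]
                    else NA_character_,
                    module = unname(module), stringsAsFactors = FALSE)
  class(out) <- c("module_partition", "data.frame")
  attr(out, "dendrogram") <- dend
  out
}
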