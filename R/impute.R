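#' k-nearest-neighbour imputation of missing feature intensities
#'
#' Imputes missing entries in analyte space, the classical
#' expression-matrix KNNimpute convention: for a missing entry
#' (analyte a, sample s) the k analytes nearest to a — by Euclidean
#' distance normalised to the co-observed sample count — among analytes
#' observed at s contribute their values at s, and the imputed value is
#' their unweighted mean. Observed entries are never altered.
#'
#' Fallbacks: fewer than `k` eligible neighbours uses all of them (with a
#' warning); no eligible neighbour imputes the analyte's own observed
#' mean (with a warning).
#'
#' @param matrix an [omics_matrix()]; every analyte must have at least
#'   one observed value
#' @param k number of neighbours (default 3)
#' @return an `omics_matrix` with no missing entries
#' @export
knn_impute <- function(matrix, k = 3) {
  X <- matrix$values
  if (!anyNA(X)) return(matrix)
  if (k < 1) stop("`k` must be >= 1")
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0))
    stop("analyte(s) with no observed values cannot be imputed: ",
         paste(utils::head(rownames(X)[rowSums(obs) == 0], 5), collapse = ", "))
  n <- nrow(X)
  out <- X
  n_short <- 0L
  n_mean <- 0L
  Xz <- X
  Xz[!obs] <- 0
  for (a in which(rowSums(!obs) > 0)) {
    xa <- Xz[a, ]
    oa <- obs[a, ]
    # squared differences over co-observed samples, normalised by count
    co <- obs %*% oa                       # co-observed counts vs analyte a
    d2 <- rowSums(sweep(Xz, 2, xa)^2 * rep(oa, each = n) * obs)
    d <- sqrt(d2 / ifelse(co > 0, co, NA))
    d[a] <- Inf
    for (s in which(!oa)) {
      elig <- which(obs[, s] & is.finite(d))
      if (!length(elig)) {
        out[a, s] <- mean(X[a, oa])
        n_mean <- n_mean + 1L
        next
      }
      if (length(elig) < k) n_short <- n_short + 1L
      nb <- elig[order(d[elig])][seq_len(min(k, length(elig)))]
      out[a, s] <- mean(X[nb, s])
    }
  }
  if (n_short) warning(n_short, " missing entr(ies) had fewer than k = ", k,
                       " eligible neighbours; all eligible neighbours used")
  if (n_mean) warning(n_mean, " missing entr(ies) had no eligible ",
                      "neighbour; analyte observed mean used")
  omics_matrix(out, matrix$dataset_tag)
}
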