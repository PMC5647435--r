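#' Configuration for the synthetic paired-cohort generator
#'
#' The generator emulates the statistical structure of a 2x2 diet
#' (CON/HFD) by exercise (pre/post) mouse cohort profiled by RNA-seq and
#' two untargeted LC-MS metabolomics assays (positive and negative ion
#' mode) that share pooled-QC injections. Latent co-regulated analyte
#' modules span all three datasets; designated modules respond to diet
#' and/or exercise with an additive shift on the latent scale. Observed
#' intensities are lognormal (latent Gaussian, exponentiated, scaled to a
#' dataset-typical magnitude); the metabolome additionally carries
#' per-feature technical noise realized in the QC replicates,
#' detection-limit (left-censored) missingness, and random missingness.
#'
#' Defaults state the emulated world: 6 biological samples per group and
#' 16 pooled-QC injections (10 lead-in, one per 6 biological injections,
#' 2 at the end of the run).
#'
#' @param n_per_group biological samples per diet x exercise cell
#' @param n_qc pooled-QC injections (metabolome datasets only)
#' @param n_transcripts,n_metabolites_pos,n_metabolites_neg dataset sizes
#' @param n_modules planted modules (traits cycle diet, exercise, neutral)
#' @param module_size_range min/max analytes per module per dataset
#' @param diet_effect latent-scale activity shift in HFD samples for
#'   diet-responsive modules
#' @param exercise_effect latent-scale shift in post samples for
#'   exercise-responsive modules
#' @param loading_range min/max absolute analyte loading on its module
#'   activity (sign random)
#' @param noise_sd analyte-level residual SD on the latent scale
#' @param qc_rsd_range min/max per-feature target technical RSD, percent
#' @param detection_quantile per-feature quantile of biological
#'   intensities below which metabolome values are censored to missing
#' @param mcar_rate additional completely-at-random metabolome missingness
#' @param seed master seed; per-dataset streams are derived from it so
#'   adding a dataset does not perturb the others
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_per_group = 6, n_qc = 16, n_transcripts = 2000,
                       n_metabolites_pos = 600, n_metabolites_neg = 600,
                       n_modules = 6, module_size_range = c(25, 35),
                       diet_effect = 2, exercise_effect = 1.5,
                       loading_range = c(0.6, 1), noise_sd = 0.5,
                       qc_rsd_range = c(2, 30), detection_quantile = 0.05,
                       mcar_rate = 0.02, seed = 1) {
  cfg <- list(n_per_group = n_per_group, n_qc = n_qc,
              n_transcripts = n_transcripts,
              n_metabolites_pos = n_metabolites_pos,
              n_metabolites_neg = n_metabolites_neg,
              n_modules = n_modules, module_size_range = module_size_range,
              diet_effect = diet_effect, exercise_effect = exercise_effect,
              loading_range = loading_range, noise_sd = noise_sd,
              qc_rsd_range = qc_rsd_range,
              detection_quantile = detection_quantile,
              mcar_rate = mcar_rate, seed = as.integer(seed))
  counts <- c("n_per_group", "n_qc", "n_transcripts", "n_metabolites_pos",
              "n_metabolites_neg", "n_modules")
  for (f in counts)
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]]))
      stop("`", f, "` must be a count >= 1")
  for (f in c("module_size_range", "loading_range", "qc_rsd_range"))
    if (length(cfg[[f]]) != 2 || any(is.na(cfg[[f]])) ||
        cfg[[f]][1] > cfg[[f]][2] || any(cfg[[f]] < 0))
      stop("`", f, "` must be an ordered non-negative (min, max) pair")
  if (cfg$module_size_range[1] < 1)
    stop("modules must have at least one analyte per dataset")
  sizes <- c(cfg$n_transcripts, cfg$n_metabolites_pos, cfg$n_metabolites_neg)
  if (any(cfg$n_modules * cfg$module_size_range[2] > sizes))
    stop("n_modules x max module size exceeds a dataset size")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (cfg$diet_effect < 0 || cfg$exercise_effect < 0)
    stop("effect sizes must be non-negative")
  if (cfg$detection_quantile < 0 || cfg$detection_quantile >= 1)
    stop("`detection_quantile` must lie in [0, 1)")
  if (cfg$mcar_rate < 0 || cfg$mcar_rate >= 1)
    stop("`mcar_rate` must lie in [0, 1)")
  if (cfg$detection_quantile + cfg$mcar_rate >= 1)
    stop("detection_quantile + mcar_rate must be < 1")
  structure(cfg, class = "sim_config")
}

# dataset-typical intensity magnitude on the natural-log scale; the spread
# (0.5) deliberately compresses the dynamic range of real assays so that
# raw-intensity variance ranking remains informative (see vignette)
.sim_base <- list(transcriptome = log(50), metabolome_pos = log(1e6),
                  metabolome_neg = log(1e6))
.sim_base_sd <- 0.5
# gain from latent units to natural-log intensity units: one latent SD of
# a typical analyte maps to ~0.3-0.65 log units, i.e. biological CVs of
# roughly 20-70%; larger gains produce unrealistically skewed intensities
# whose Pearson correlations no longer reflect the latent structure
.sim_latent_gain <- 0.4

#' Generate a synthetic paired transcript/metabolite cohort
#'
#' @param config a [sim_config()]
#' @return a list with elements
#'   \describe{
#'     \item{datasets}{named list of three [omics_matrix()] objects
#'       (`transcriptome`, `metabolome_pos`, `metabolome_neg`)}
#'     \item{metadata}{a [sample_metadata()] table covering biological and
#'       pooled-QC samples}
#'     \item{truth}{planted ground truth: `partition` (analyte_id, dataset,
#'       module_id, module_trait), `module_traits`, `activities` (module x
#'       biological sample latent activities), and `qc_target_rsd` per
#'       metabolome feature}
#'   }
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  ng <- config$n_per_group
  groups <- c("CON_pre", "CON_post", "HFD_pre", "HFD_post")
  bio_ids <- unlist(lapply(groups, function(g) paste0(g, "_", seq_len(ng))))
  qc_ids <- sprintf("QC_%02d", seq_len(config$n_qc))
  n_bio <- length(bio_ids)
  diet <- rep(c("CON", "CON", "HFD", "HFD"), each = ng)
  exercise <- rep(c("pre", "post", "pre", "post"), each = ng)

  # master stream: shared structure (traits, latent activities, run order)
  set.seed(config$seed)
  # one diet-responsive and one exercise-responsive module (the paper-style
  # brown/green analogue), remaining modules neutral; a second module per
  # trait would share its latent shift and be observationally confounded
  # with the first
  traits <- c("diet", "exercise",
              rep("neutral", max(0, config$n_modules - 2)))[
                seq_len(config$n_modules)]
  names(traits) <- paste0("M", seq_len(config$n_modules))
  shift <- outer(ifelse(traits == "diet", config$diet_effect, 0),
                 as.numeric(diet == "HFD")) +
    outer(ifelse(traits == "exercise", config$exercise_effect, 0),
          as.numeric(exercise == "post"))
  activities <- shift + matrix(stats::rnorm(config$n_modules * n_bio),
                               config$n_modules, n_bio)
  dimnames(activities) <- list(names(traits), bio_ids)
  run_order <- .sim_run_order(sample(n_bio), config$n_qc)

  specs <- list(
    transcriptome = list(n = config$n_transcripts, prefix = "tx", idx = 1L),
    metabolome_pos = list(n = config$n_metabolites_pos, prefix = "mzp",
                          idx = 2L),
    metabolome_neg = list(n = config$n_metabolites_neg, prefix = "mzn",
                          idx = 3L))
  datasets <- list()
  partition <- list()
  qc_rsd <- list()
  for (tag in names(specs)) {
    sp <- specs[[tag]]
    set.seed(config$seed + sp$idx)  # independent stream per dataset
    n <- sp$n
    ids <- if (tag == "transcriptome") sprintf("tx_%05d", seq_len(n)) else
      sprintf("%s_%07.3f_%05.1f", sp$prefix, stats::runif(n, 100, 1000),
              stats::runif(n, 10, 1200))
    ids <- make.unique(ids, sep = "_d")
    sizes <- sample(seq(config$module_size_range[1],
                        config$module_size_range[2]),
                    config$n_modules, replace = TRUE)
    members_all <- sample(n, sum(sizes))
    module_of <- rep(NA_character_, n)
    module_of[members_all] <- rep(names(traits), times = sizes)
    loading <- stats::runif(n, config$loading_range[1],
                            config$loading_range[2]) *
      sample(c(-1, 1), n, replace = TRUE)

    latent <- matrix(stats::rnorm(n * n_bio, sd = config$noise_sd), n, n_bio)
    planted <- !is.na(module_of)
    latent[planted, ] <- latent[planted, , drop = FALSE] +
      loading[planted] * activities[module_of[planted], , drop = FALSE]
    base <- exp(stats::rnorm(n, .sim_base[[tag]], .sim_base_sd))
    values <- base * exp(.sim_latent_gain * latent)
    dimnames(values) <- list(ids, bio_ids)

    if (tag != "transcriptome") {
      pool <- rowMeans(values)
      target_rsd <- stats::runif(n, config$qc_rsd_range[1],
                                 config$qc_rsd_range[2])
      sigma <- sqrt(log1p((target_rsd / 100)^2))
      qcv <- pool * exp(matrix(stats::rnorm(n * config$n_qc), n) * sigma)
      colnames(qcv) <- qc_ids
      values <- cbind(values, qcv)
      # left-censoring at the per-feature detection quantile, then MCAR
      if (config$detection_quantile > 0) {
        lod <- apply(values[, bio_ids, drop = FALSE], 1, stats::quantile,
                     probs = config$detection_quantile)
        values[values < lod] <- NA
      }
      if (config$mcar_rate > 0)
        values[matrix(stats::runif(length(values)) < config$mcar_rate,
                      nrow(values))] <- NA
      qc_rsd[[tag]] <- data.frame(analyte_id = ids, dataset = tag,
                                  target_rsd = target_rsd,
                                  stringsAsFactors = FALSE)
    }
    datasets[[tag]] <- omics_matrix(values, tag)
    partition[[tag]] <- data.frame(
      analyte_id = ids, dataset = tag,
      module_id = ifelse(is.na(module_of), "background", module_of),
      module_trait = ifelse(is.na(module_of), "background",
                            traits[module_of]),
      stringsAsFactors = FALSE)
  }

  metadata <- sample_metadata(
    sample_id = c(bio_ids, qc_ids),
    diet = c(diet, rep(NA, config$n_qc)),
    exercise = c(exercise, rep(NA, config$n_qc)),
    is_qc = c(rep(FALSE, n_bio), rep(TRUE, config$n_qc)),
    run_order = run_order)

  list(datasets = datasets, metadata = metadata,
       truth = list(partition = do.call(rbind, unname(partition)),
                    module_traits = traits, activities = activities,
                    qc_target_rsd = do.call(rbind, unname(qc_rsd))),
       config = config)
}

# injection order mimicking the acquisition scheme: lead-in QCs, a QC after
# every 6th biological sample, closing QCs; returns order for c(bio, qc)
.sim_run_order <- function(bio_perm, n_qc) {
  n_bio <- length(bio_perm)
  n_lead <- min(10L, n_qc)
  n_tail <- min(2L, n_qc - n_lead)
  n_mid <- n_qc - n_lead - n_tail
  slots <- character(0)
  qi <- 0L
  slots <- c(slots, rep("q", n_lead))
  for (i in seq_len(n_bio)) {
    slots <- c(slots, "b")
    if (n_mid > 0 && i %% 6 == 0 && qi < n_mid) {
      slots <- c(slots, "q"); qi <- qi + 1L
    }
  }
  slots <- c(slots, rep("q", n_mid - qi), rep("q", n_tail))
  pos_b <- which(slots == "b")
  pos_q <- which(slots == "q")
  ord <- integer(n_bio + n_qc)
  ord[seq_len(n_bio)] <- pos_b[order(bio_perm)]
  ord[n_bio + seq_len(n_qc)] <- pos_q
  ord
}

#' Write a simulated cohort to a directory
#'
#' Emits one TSV per dataset, the metadata TSV, and ground-truth sidecar
#' files (`truth_partition.tsv`, `truth_activities.tsv`). The sidecars are
#' evaluation-only: no analysis stage reads them.
#'
#' @param cohort result of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return named character vector of written paths, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (tag in names(cohort$datasets)) {
    p <- file.path(dir, paste0(tag, ".tsv"))
    write_matrix(cohort$datasets[[tag]], p)
    paths[tag] <- p
  }
  paths["metadata"] <- file.path(dir, "metadata.tsv")
  write_metadata(cohort$metadata, paths[["metadata"]])
  paths["truth_partition"] <- file.path(dir, "truth_partition.tsv")
  utils::write.table(cohort$truth$partition, paths[["truth_partition"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth_activities"] <- file.path(dir, "truth_activities.tsv")
  act <- data.frame(module_id = rownames(cohort$truth$activities),
                    module_trait = cohort$truth$module_traits,
                    cohort$truth$activities, check.names = FALSE)
  utils::write.table(act, paths[["truth_activities"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
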