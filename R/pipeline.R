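#' Pipeline configuration
#'
#' Collects every stage parameter, the input/output paths and the master
#' seed into one validated object. Unknown keys are rejected. Every run
#' writes a resolved copy of the configuration next to its outputs, which
#' is sufficient to replay the run bit-identically.
#'
#' @param transcriptome,metabolome_pos,metabolome_neg,metadata input TSV
#'   paths (see [read_matrix()], [read_metadata()])
#' @param truth_partition,truth_activities optional ground-truth sidecar
#'   paths; when given, the evaluate stage runs
#' @param gmt optional GMT gene-set path; when given, the enrichment
#'   stage runs on every flagged module
#' @param out output directory
#' @param rsd_threshold,min_detection,filter_rule feature filters, see
#'   [apply_feature_filters()]
#' @param k kNN imputation neighbours
#' @param diff_group_a,diff_group_b differential comparison (defaults:
#'   CON_pre vs HFD_pre, the diet effect at rest)
#' @param n_boot,ci_level fold-change bootstrap settings
#' @param top_fraction per-dataset variance-selection fraction
#' @param log2_transcripts apply log2(x + 1) to the transcriptome before
#'   variance selection and combination (default `FALSE`)
#' @param beta soft power (positive integer, default 6 — the canonical
#'   unsigned-network default) or `"auto"` for scale-free selection;
#'   block-structured data is not scale-free, so `"auto"` can pick
#'   powers too low to suppress background correlation (see vignette)
#' @param network_sign,min_module_size,merge_cut_height,cut_height,deep_split
#'   see [network_params()]
#' @param r2_target scale-free fit target when `beta = "auto"`
#' @param alpha module-association flagging threshold
#' @param q_threshold differential significance threshold
#' @param seed master seed
#' @param run_diffstat,run_enrich,run_evaluate stage toggles
#' @param write_tom persist the TOM as TSV (large; default `FALSE`)
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(transcriptome, metabolome_pos, metabolome_neg,
                            metadata, truth_partition = NULL,
                            truth_activities = NULL, gmt = NULL,
                            out = "wacna_out", rsd_threshold = 20,
                            min_detection = 0.70,
                            filter_rule = "independent", k = 3,
                            diff_group_a = "CON_pre",
                            diff_group_b = "HFD_pre", n_boot = 2000,
                            ci_level = 0.95, top_fraction = 0.20,
                            log2_transcripts = FALSE, beta = 6,
                            network_sign = "unsigned", min_module_size = 20,
                            merge_cut_height = 0.25, cut_height = 0.99,
                            deep_split = 2, r2_target = 0.80, alpha = 0.05,
                            q_threshold = 0.05, seed = 1,
                            run_diffstat = TRUE, run_enrich = !is.null(gmt),
                            run_evaluate = !is.null(truth_partition),
                            write_tom = FALSE) {
  cfg <- as.list(environment())
  network_params(beta = if (identical(beta, "auto")) "auto" else beta,
                 network_sign = network_sign,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 cut_height = cut_height, deep_split = deep_split)
  if (cfg$run_enrich && is.null(cfg$gmt))
    stop("run_enrich = TRUE requires a `gmt` path")
  if (cfg$run_evaluate && is.null(cfg$truth_partition))
    stop("run_evaluate = TRUE requires truth sidecar paths")
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' Unknown keys are rejected; missing keys take [pipeline_config()]
#' defaults.
#'
#' @param path JSON file path
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(pipeline_config, raw)
}

#' Run the full WACNA pipeline
#'
#' Executes the stages in the canonical order: feature QC -> kNN
#' imputation -> differential statistics -> per-dataset variance
#' selection -> combine and z-scale -> soft-power / adjacency / TOM ->
#' module detection -> eigengenes -> design association -> optional
#' enrichment -> optional evaluation against ground truth. Every stage
#' logs its parameters; artifact checksums are written to
#' `manifest.json` and the resolved configuration to
#' `resolved_config.json`. Identical configuration and seed reproduce
#' identical artifact checksums.
#'
#' @param config a [pipeline_config()]
#' @param quiet suppress progress messages
#' @return (invisibly) a list with all in-memory stage results and
#'   `artifacts`, the named vector of written paths
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  artifacts <- c()
  stage <- "read"
  res <- tryCatch({
    logf("stage read: loading inputs")
    metadata <- read_metadata(config$metadata)
    datasets <- list(
      transcriptome = read_matrix(config$transcriptome, "transcriptome"),
      metabolome_pos = read_matrix(config$metabolome_pos, "metabolome_pos"),
      metabolome_neg = read_matrix(config$metabolome_neg, "metabolome_neg"))

    stage <- "qc"
    reports <- list()
    for (tag in c("metabolome_pos", "metabolome_neg")) {
      rep_ <- apply_feature_filters(datasets[[tag]], metadata,
                                    threshold = config$rsd_threshold,
                                    min_detection = config$min_detection,
                                    rule = config$filter_rule)
      reports[[tag]] <- rep_
      p <- file.path(config$out, paste0("filter_report_", tag, ".tsv"))
      utils::write.table(rep_, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      artifacts[paste0("filter_report_", tag)] <- p
      datasets[[tag]] <- apply_filter_report(datasets[[tag]], rep_)
      logf(sprintf("stage qc [%s]: kept %d / %d features (rsd > %g%% or detection < %g)",
                   tag, sum(rep_$kept), nrow(rep_), config$rsd_threshold,
                   config$min_detection))
    }

    stage <- "impute"
    for (tag in c("metabolome_pos", "metabolome_neg")) {
      n_missing <- sum(is.na(datasets[[tag]]$values))
      datasets[[tag]] <- knn_impute(datasets[[tag]], k = config$k)
      logf(sprintf("stage impute [%s]: imputed %d entries with k = %d",
                   tag, n_missing, config$k))
    }

    stage <- "diffstat"
    differential <- NULL
    if (config$run_diffstat) {
      differential <- list()
      for (tag in c("metabolome_pos", "metabolome_neg")) {
        bio <- subset_omics(datasets[[tag]], samples = intersect(
          biological_samples(metadata), sample_ids(datasets[[tag]])))
        differential[[tag]] <- differential_analysis(
          bio, metadata, config$diff_group_a, config$diff_group_b,
          ci_level = config$ci_level, n_boot = config$n_boot,
          seed = config$seed, q_threshold = config$q_threshold)
        p <- file.path(config$out, paste0("differential_", tag, ".tsv"))
        utils::write.table(differential[[tag]], p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        artifacts[paste0("differential_", tag)] <- p
        logf(sprintf("stage diffstat [%s]: %d significant at q < %g (%s vs %s)",
                     tag, sum(differential[[tag]]$q_bh < config$q_threshold),
                     config$q_threshold, config$diff_group_a,
                     config$diff_group_b))
      }
    } else logf("stage diffstat: skipped")

    stage <- "variance_select"
    if (config$log2_transcripts) {
      tx <- datasets$transcriptome
      datasets$transcriptome <- omics_matrix(log2(tx$values + 1),
                                             "transcriptome")
    }
    selected <- lapply(datasets, variance_select,
                       top_fraction = config$top_fraction,
                       metadata = metadata)
    logf(sprintf("stage variance_select: kept %s analytes (top %g%%)",
                 paste(vapply(selected, nrow, integer(1)), collapse = "/"),
                 100 * config$top_fraction))

    stage <- "combine"
    combined <- combine_and_scale(selected, metadata)

    stage <- "network"
    if (identical(config$beta, "auto")) {
      pick <- pick_soft_power(combined, r2_target = config$r2_target,
                              network_sign = config$network_sign)
      beta <- pick$beta
      logf(sprintf("stage network: scale-free fit selected beta = %d", beta))
    } else {
      beta <- as.integer(config$beta)
      logf(sprintf("stage network: fixed beta = %d", beta))
    }
    params <- network_params(beta = beta, network_sign = config$network_sign,
                             min_module_size = config$min_module_size,
                             merge_cut_height = config$merge_cut_height,
                             cut_height = config$cut_height,
                             deep_split = config$deep_split)
    adj <- adjacency_matrix(combined, beta = beta,
                            network_sign = config$network_sign)
    tom <- topological_overlap(adj)
    if (config$write_tom) {
      p <- file.path(config$out, "tom.tsv")
      utils::write.table(
        data.frame(analyte_id = rownames(tom), tom, check.names = FALSE),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts["tom"] <- p
    }

    stage <- "modules"
    partition <- detect_modules(tom, params, combined)
    n_mod <- length(setdiff(unique(partition$module), "grey"))
    logf(sprintf("stage modules: %d modules, %d analytes grey", n_mod,
                 sum(partition$module == "grey")))
    p <- file.path(config$out, "module_partition.tsv")
    utils::write.table(partition, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts["module_partition"] <- p

    stage <- "eigengenes"
    eigengenes <- module_eigengenes(combined, partition)
    p <- file.path(config$out, "eigengenes.tsv")
    utils::write.table(
      data.frame(module = rownames(eigengenes$scores),
                 var_explained = eigengenes$var_explained,
                 eigengenes$scores, check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts["eigengenes"] <- p

    stage <- "associate"
    associations <- associate_modules(eigengenes, metadata,
                                      alpha = config$alpha)
    logf(sprintf("stage associate: %d module(s) of interest (%s)",
                 sum(associations$flagged_of_interest),
                 paste(associations$module[associations$flagged_of_interest],
                       collapse = ", ")))
    p <- file.path(config$out, "module_associations.tsv")
    utils::write.table(associations, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts["module_associations"] <- p

    stage <- "enrich"
    enrichment <- NULL
    if (config$run_enrich) {
      sets <- read_gmt(config$gmt)
      universe <- partition$analyte_id
      flagged <- associations$module[associations$flagged_of_interest]
      enrichment <- do.call(rbind, lapply(flagged, function(m) {
        members <- partition$analyte_id[partition$module == m]
        cbind(module = m, overrepresentation(members, sets, universe))
      }))
      p <- file.path(config$out, "enrichment.tsv")
      utils::write.table(enrichment, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      artifacts["enrichment"] <- p
      logf(sprintf("stage enrich: %d flagged module(s) x %d set(s)",
                   length(flagged), length(sets)))
    } else logf("stage enrich: skipped")

    stage <- "evaluate"
    recovery <- NULL
    if (config$run_evaluate) {
      truth <- read_truth(config$truth_partition, config$truth_activities)
      recovery <- recovery_report(truth, partition, eigengenes,
                                  associations)
      p <- file.path(config$out, "recovery.json")
      jsonlite::write_json(
        lapply(unclass(recovery), function(x)
          if (is.null(x)) NA else unname(x)),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
      artifacts["recovery"] <- p
      logf(sprintf("stage evaluate: ARI %.3f, background rejection %.3f",
                   recovery$ari, recovery$background_rejection))
    } else logf("stage evaluate: skipped")

    list(metadata = metadata, datasets = datasets, filter_reports = reports,
         differential = differential, selected = selected,
         combined = combined, beta = beta, adjacency = adj, tom = tom,
         partition = partition, eigengenes = eigengenes,
         associations = associations, enrichment = enrichment,
         recovery = recovery)
  }, error = function(e) {
    marker <- file.path(config$out, "FAILED")
    writeLines(paste0("stage ", stage, ": ", conditionMessage(e)), marker)
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })

  cfg_path <- file.path(config$out, "resolved_config.json")
  jsonlite::write_json(unclass(config)[!vapply(unclass(config), is.null,
                                               logical(1))],
                       cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  artifacts["resolved_config"] <- cfg_path
  manifest <- data.frame(artifact = names(artifacts),
                         path = basename(unname(artifacts)),
                         md5 = unname(tools::md5sum(unname(artifacts))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       pretty = TRUE)
  logf(sprintf("pipeline complete in %.1f s; %d artifacts",
               as.numeric(difftime(Sys.time(), t0, units = "secs")),
               length(artifacts)))
  res$artifacts <- artifacts
  invisible(res)
}

#' Read ground-truth sidecar files
#'
#' @param partition_path `truth_partition.tsv` from [write_cohort()]
#' @param activities_path optional `truth_activities.tsv`
#' @return a truth list as in [simulate_cohort()]`$truth`
#' @export
read_truth <- function(partition_path, activities_path = NULL) {
  part <- utils::read.delim(partition_path, sep = "\t",
                            stringsAsFactors = FALSE)
  truth <- list(partition = part)
  if (!is.null(activities_path)) {
    act <- utils::read.delim(activities_path, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    truth$module_traits <- stats::setNames(act$module_trait, act$module_id)
    m <- as.matrix(act[, !(names(act) %in% c("module_id", "module_trait")),
                       drop = FALSE])
    rownames(m) <- act$module_id
    truth$activities <- m
  }
  truth
}
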