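test_that("simulate_cohort is deterministic and per-dataset streams are independent", {
  a <- simulate_cohort(small_sim_config(seed = 11))
  b <- simulate_cohort(small_sim_config(seed = 11))
  expect_identical(a, b)
  c <- simulate_cohort(small_sim_config(seed = 12))
  expect_false(identical(a$datasets$transcriptome$values,
                         c$datasets$transcriptome$values))
  # resizing one dataset leaves the others untouched
  d <- simulate_cohort(small_sim_config(seed = 11, n_metabolites_neg = 60))
  expect_identical(a$datasets$transcriptome$values,
                   d$datasets$transcriptome$values)
  expect_identical(a$datasets$metabolome_pos$values,
                   d$datasets$metabolome_pos$values)
})

test_that("cohort dimensions, positivity and metadata counts match the design", {
  cfg <- small_sim_config(seed = 3)
  co <- simulate_cohort(cfg)
  md <- co$metadata
  expect_equal(sum(!md$is_qc), 4 * cfg$n_per_group)
  expect_equal(sum(md$is_qc), cfg$n_qc)
  expect_equal(as.integer(sort(table(paste(md$diet, md$exercise)[!md$is_qc]))),
               rep(cfg$n_per_group, 4))
  expect_equal(sort(md$run_order), seq_len(nrow(md)))
  # transcriptome: complete, biological columns only
  tx <- co$datasets$transcriptome
  expect_equal(ncol(tx$values), 4 * cfg$n_per_group)
  expect_false(anyNA(tx$values))
  for (tag in c("metabolome_pos", "metabolome_neg")) {
    v <- co$datasets[[tag]]$values
    expect_equal(ncol(v), 4 * cfg$n_per_group + cfg$n_qc)
    expect_true(all(v > 0, na.rm = TRUE))
    expect_gt(sum(is.na(v)), 0)
  }
  # ground truth covers every analyte exactly once
  expect_equal(nrow(co$truth$partition),
               cfg$n_transcripts + cfg$n_metabolites_pos +
                 cfg$n_metabolites_neg)
  expect_false(anyDuplicated(
    paste(co$truth$partition$dataset, co$truth$partition$analyte_id)) > 0)
})

test_that("noiseless single-module cohort is rank one on the latent scale", {
  cfg <- sim_config(n_per_group = 4, n_qc = 4, n_transcripts = 12,
                    n_metabolites_pos = 12, n_metabolites_neg = 12,
                    n_modules = 1, module_size_range = c(6, 6),
                    noise_sd = 0, detection_quantile = 0, mcar_rate = 0,
                    seed = 5)
  co <- simulate_cohort(cfg)
  bio <- biological_samples(co$metadata)
  tr <- co$truth$partition
  for (tag in names(co$datasets)) {
    mem <- tr$analyte_id[tr$dataset == tag & tr$module_id == "M1"]
    v <- co$datasets[[tag]]$values[mem, bio]
    # intensities are monotone transforms of one latent activity:
    # rank correlations are exactly +/-1, Pearson close to 1
    sp <- stats::cor(t(v), method = "spearman")
    expect_equal(abs(sp), matrix(1, length(mem), length(mem),
                                 dimnames = dimnames(sp)))
    pe <- stats::cor(t(log(v)))
    expect_equal(abs(pe), matrix(1, length(mem), length(mem),
                                 dimnames = dimnames(pe)), tolerance = 1e-12)
  }
})

test_that("null cohort Wilcoxon rejection rate sits at the nominal level", {
  # Monte-Carlo over seeds: no diet/exercise effect anywhere, exact test
  # at n = 6 vs 6; the discrete exact null makes P(p <= 0.05) ~ 0.041
  rejections <- 0L
  total <- 0L
  for (s in 1:40) {
    cfg <- sim_config(n_per_group = 6, n_qc = 4, n_transcripts = 2,
                      n_metabolites_pos = 50, n_metabolites_neg = 2,
                      n_modules = 1, module_size_range = c(1, 1),
                      diet_effect = 0, exercise_effect = 0,
                      detection_quantile = 0, mcar_rate = 0, seed = 1000 + s)
    co <- simulate_cohort(cfg)
    m <- subset_omics(co$datasets$metabolome_pos,
                      samples = biological_samples(co$metadata))
    p <- wilcoxon_mw(m, co$metadata, "CON_pre", "HFD_pre")
    rejections <- rejections + sum(p <= 0.05)
    total <- total + length(p)
  }
  rate <- rejections / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.041), 0.009 + 2 * se)
})

test_that("realized QC RSD tracks its per-feature target", {
  co <- simulate_cohort(sim_config(n_per_group = 4, n_qc = 16,
                                   n_transcripts = 10,
                                   n_metabolites_pos = 200,
                                   n_metabolites_neg = 10, n_modules = 1,
                                   module_size_range = c(2, 2),
                                   detection_quantile = 0, mcar_rate = 0,
                                   seed = 21))
  v <- co$datasets$metabolome_pos$values[, qc_samples(co$metadata)]
  realized <- 100 * apply(v, 1, stats::sd) / rowMeans(v)
  target <- co$truth$qc_target_rsd
  target <- target$target_rsd[target$dataset == "metabolome_pos"]
  expect_gt(stats::cor(realized, target, method = "spearman"), 0.9)
})

test_that("censored fraction grows monotonically with detection_quantile", {
  fracs <- vapply(c(0, 0.05, 0.15, 0.3), function(dq) {
    co <- simulate_cohort(small_sim_config(seed = 9, mcar_rate = 0,
                                           detection_quantile = dq))
    mean(is.na(co$datasets$metabolome_pos$values))
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  expect_equal(fracs[1], 0)
})

test_that("invalid configurations are rejected with parameter errors", {
  expect_error(sim_config(n_per_group = 0), "count")
  expect_error(sim_config(detection_quantile = 1), "detection_quantile")
  expect_error(sim_config(detection_quantile = 0.6, mcar_rate = 0.5),
               "must be < 1")
  expect_error(sim_config(module_size_range = c(10, 5)), "ordered")
  expect_error(sim_config(n_transcripts = 10, n_modules = 3,
                          module_size_range = c(4, 4)), "exceeds")
})

test_that("write_cohort round-trips matrices, metadata and truth", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(small_sim_config(seed = 2))
  paths <- write_cohort(co, dir)
  m <- read_matrix(paths[["metabolome_pos"]], "metabolome_pos")
  expect_equal(m$values, co$datasets$metabolome_pos$values)
  md <- read_metadata(paths[["metadata"]])
  expect_equal(as.data.frame(md), as.data.frame(co$metadata))
  truth <- read_truth(paths[["truth_partition"]],
                      paths[["truth_activities"]])
  expect_equal(truth$partition, co$truth$partition)
  expect_equal(truth$activities, co$truth$activities)
  expect_equal(truth$module_traits, co$truth$module_traits)
})
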