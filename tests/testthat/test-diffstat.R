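test_that("Wilcoxon exact path equals full enumeration", {
  md <- design_metadata(3)
  v <- rbind(c(1, 2, 3, 4, 5, 6))
  # put 1,2,3 in CON_pre and 4,5,6 in HFD_pre
  colnames(v) <- c(group_samples(md, "CON_pre"), group_samples(md, "HFD_pre"))
  rownames(v) <- "a1"
  m <- omics_matrix(v, "metabolome_pos")
  p <- wilcoxon_mw(m, md, "CON_pre", "HFD_pre")
  expect_equal(unname(p), 0.1)
  expect_equal(unname(p), oracle_wilcoxon(1:3, 4:6))
  # random tie-free data across a spread of group sizes
  set.seed(1)
  for (na in 2:5) for (nb in c(2, 5)) {
    mdx <- design_metadata(max(na, nb))
    sa <- group_samples(mdx, "CON_pre")[1:na]
    sb <- group_samples(mdx, "HFD_pre")[1:nb]
    x <- sample(seq_len(50), na + nb)  # distinct integers: no ties
    vv <- matrix(x, 1, dimnames = list("a1", c(sa, sb)))
    mm <- omics_matrix(vv, "metabolome_pos")
    mdy <- mdx[mdx$sample_id %in% c(sa, sb), ]
    expect_equal(unname(wilcoxon_mw(mm, mdy, "CON_pre", "HFD_pre")),
                 oracle_wilcoxon(x[1:na], x[na + 1:nb]),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles identical groups and tied data", {
  md <- design_metadata(3)
  sa <- group_samples(md, "CON_pre")
  sb <- group_samples(md, "HFD_pre")
  v <- matrix(rep(c(1, 2, 3), 2), 1, dimnames = list("a1", c(sa, sb)))
  m <- omics_matrix(v, "metabolome_pos")
  expect_equal(unname(wilcoxon_mw(m, md, "CON_pre", "HFD_pre")), 1)
  # constant unequal groups separate fully under the tie-corrected normal path
  v2 <- matrix(rep(c(5, 9), each = 3), 1, dimnames = list("a1", c(sa, sb)))
  m2 <- omics_matrix(v2, "metabolome_pos")
  expect_lt(unname(wilcoxon_mw(m2, md, "CON_pre", "HFD_pre")), 0.1)
  expect_error(wilcoxon_mw(m, md[c(1, 4, 7), ], "CON_pre", "HFD_pre"),
               ">= 2")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (rep_ in 1:20) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"))  # independent implementation
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("fold change sign convention, CIs and antisymmetry hold", {
  md <- design_metadata(3)
  sa <- group_samples(md, "CON_pre")
  sb <- group_samples(md, "HFD_pre")
  v <- rbind(c(rep(100, 3), rep(200, 3)),   # doubling -> +2
             c(rep(200, 3), rep(100, 3)),   # halving  -> -2
             c(rep(50, 3), rep(50, 3)))     # constant -> +1, zero-width CI
  dimnames(v) <- list(c("up2", "down2", "flat"), c(sa, sb))
  m <- omics_matrix(v, "metabolome_pos")
  fc <- fold_change(m, md, "CON_pre", "HFD_pre", n_boot = 200, seed = 1)
  expect_equal(fc$fold_change, c(2, -2, 1))
  expect_equal(fc$ci_low[3], 1)
  expect_equal(fc$ci_high[3], 1)
  expect_true(all(fc$ci_low <= fc$fold_change + 1e-12 &
                    fc$fold_change <= fc$ci_high + 1e-12))
  rev_ <- fold_change(m, md, "HFD_pre", "CON_pre", n_boot = 200, seed = 1)
  expect_equal(rev_$fold_change[1:2], -fc$fold_change[1:2])
  zero <- omics_matrix(matrix(c(0, 0, 0, 1, 1, 1), 1,
                              dimnames = list("z", c(sa, sb))),
                       "metabolome_pos")
  expect_error(fold_change(zero, md, "CON_pre", "HFD_pre"), "zero group mean")
})

test_that("differential_analysis assembles the per-analyte record", {
  set.seed(5)
  md <- design_metadata(6)
  sa <- group_samples(md, "CON_pre")
  sb <- group_samples(md, "HFD_pre")
  up <- stats::rlnorm(6, 5) ; upb <- up * 1000  # fully separated groups
  v <- rbind(c(up, upb), matrix(stats::rlnorm(24, 5), 2))
  dimnames(v) <- list(c("hit", "null1", "null2"), c(sa, sb))
  m <- omics_matrix(v, "metabolome_pos")
  res <- differential_analysis(m, md, "CON_pre", "HFD_pre", n_boot = 200,
                               seed = 3)
  expect_s3_class(res, "differential_result")
  expect_true(all(res$q_bh >= res$p_raw - 1e-15))
  expect_true(all(abs(res$fold_change) >= 1))
  expect_equal(res$direction[1], "up")
  expect_equal(res$p_raw[1], 2 / choose(12, 6), tolerance = 1e-12)
})

test_that("class rollup computes per-class percentages by direction", {
  res <- data.frame(
    analyte_id = sprintf("a%03d", 1:300),
    fold_change = c(rep(2, 145), rep(-2, 88), rep(1, 67)),
    q_bh = c(rep(0.01, 233), rep(0.5, 67)),
    stringsAsFactors = FALSE)
  ann <- stats::setNames(c(rep("lipid", 75), rep("amino", 30)),
                         sprintf("a%03d", 1:105))
  roll <- class_rollup(res, ann)
  up_lipid <- roll[roll$direction == "up" & roll$class == "lipid", ]
  expect_equal(up_lipid$n, 75)
  expect_equal(up_lipid$percent, 100 * 75 / 145, tolerance = 1e-12)
  expect_equal(sum(roll$n[roll$direction == "up"]), 145)
  expect_equal(sum(roll$n[roll$direction == "down"]), 88)
  # annotations only cover the up block; all down hits are unknown
  expect_equal(roll[roll$direction == "down" & roll$class == "unknown", "n"],
               88)
  expect_equal(roll[roll$direction == "up" & roll$class == "amino", "n"], 30)
  empty <- class_rollup(res[res$q_bh > 0.1, ], ann)
  expect_equal(nrow(empty), 0)
})

test_that("planted diet-responsive class dominates the significant set", {
  # strong diet effect, all diet-module metabolites share one class
  cfg <- sim_config(n_per_group = 6, n_qc = 6, n_transcripts = 60,
                    n_metabolites_pos = 150, n_metabolites_neg = 60,
                    n_modules = 2, module_size_range = c(25, 25),
                    diet_effect = 4, exercise_effect = 0, noise_sd = 0.3,
                    detection_quantile = 0, mcar_rate = 0, seed = 31)
  co <- simulate_cohort(cfg)
  md <- co$metadata
  m <- subset_omics(co$datasets$metabolome_pos,
                    samples = biological_samples(md))
  res <- differential_analysis(m, md, "CON_pre", "HFD_pre", n_boot = 200,
                               seed = 31)
  tr <- co$truth$partition
  diet_ids <- tr$analyte_id[tr$dataset == "metabolome_pos" &
                              tr$module_trait == "diet"]
  ann <- stats::setNames(rep("planted_diet", length(diet_ids)), diet_ids)
  roll <- class_rollup(res, ann)
  sig <- res$analyte_id[res$q_bh < 0.05]
  expect_gt(length(sig), 0)
  share_sig <- roll$n[roll$class == "planted_diet"] / length(sig)
  share_planted <- length(diet_ids) / nrow(tr[tr$dataset == "metabolome_pos", ])
  expect_gte(sum(share_sig), share_planted)
})
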