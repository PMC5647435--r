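test_that("variance selection keeps the most variable analytes with a stable tie-break", {
  md <- design_metadata(3)
  set.seed(9)
  v <- matrix(stats::rlnorm(120), 10, 12)
  m <- as_omics(v, md)
  sel <- variance_select(m, 0.2)
  vars <- apply(v, 1, stats::var)
  expect_setequal(analyte_ids(sel),
                  rownames(m$values)[order(-vars)][1:2])
  # a constant analyte is never selected while positive variance remains
  v2 <- v; v2[1, ] <- 7
  sel2 <- variance_select(as_omics(v2, md), 0.2)
  expect_false("m_001" %in% analyte_ids(sel2))
  # all equal variance: first ceil(0.2 n) by id order
  v3 <- matrix(rep(stats::rlnorm(12), each = 10), 10, 12)
  sel3 <- variance_select(as_omics(v3, md), 0.25)
  expect_equal(sort(analyte_ids(sel3)), c("m_001", "m_002", "m_003"))
  expect_error(variance_select(as_omics(v, md), 0.05), "fewer than 2")
})

test_that("combine_and_scale standardises rows and is idempotent", {
  md <- design_metadata(3)
  m1 <- as_omics(matrix(stats::rlnorm(60), 5, 12), md, "transcriptome", "tx")
  m2 <- as_omics(matrix(stats::rlnorm(48), 4, 12), md, "metabolome_pos", "mp")
  cmb <- combine_and_scale(list(transcriptome = m1, metabolome_pos = m2), md)
  expect_equal(nrow(cmb$values), 9)
  expect_equal(cmb$dataset, rep(c("transcriptome", "metabolome_pos"), c(5, 4)))
  expect_lt(max(abs(rowMeans(cmb$values))), 1e-10)
  expect_lt(max(abs(apply(cmb$values, 1, stats::sd) - 1)), 1e-10)
  # idempotence on an already scaled matrix (shifted to stay non-negative)
  pre <- cmb$values[1:5, ] + 10
  rescaled <- combine_and_scale(
    list(transcriptome = omics_matrix(pre, "transcriptome")), md)
  expect_equal(rescaled$values, cmb$values[1:5, ], tolerance = 1e-12)
  m3 <- as_omics(matrix(stats::rlnorm(40), 5, 8), design_metadata(2),
                 "metabolome_neg", "mn")
  expect_error(
    combine_and_scale(list(transcriptome = m1, metabolome_neg = m3), md),
    "differ")
})

test_that("adjacency follows the soft-threshold definitions", {
  # cor(c(1,2,3), c(1,3,2)) is exactly 0.5
  v <- rbind(a = c(1, 2, 3), b = c(1, 3, 2), c = c(3, 2, 1))
  colnames(v) <- paste0("s", 1:3)
  adj <- adjacency_matrix(v, beta = 6)
  expect_equal(adj["a", "b"], 0.5^6)
  expect_equal(adj["a", "c"], 1)          # cor -1, unsigned
  expect_equal(diag(adj), c(a = 1, b = 1, c = 1))
  expect_equal(adj, t(adj))
  signed <- adjacency_matrix(v, beta = 2, network_sign = "signed")
  expect_equal(signed["a", "b"], 0.75^2)
  expect_equal(signed["a", "c"], 0)       # cor -1 -> (1-1)/2 = 0
  expect_equal(unname(connectivity(adj)), unname(rowSums(adj) - 1))
})

test_that("TOM matches hand computation and the triple-loop oracle", {
  a <- matrix(c(1, 1, 1,
                1, 1, 0,
                1, 0, 1), 3, 3)
  tom <- topological_overlap(a)
  expect_equal(tom[2, 3], 0.5)   # (L=1 + a=0) / (min(1,1) + 1 - 0)
  expect_equal(diag(tom), rep(1, 3))
  # complete graph: all overlap maximal
  full <- matrix(1, 4, 4)
  expect_equal(topological_overlap(full), matrix(1, 4, 4))
  # empty graph: no overlap off-diagonal
  empty <- diag(5)
  expect_equal(topological_overlap(empty), diag(5))
  set.seed(3)
  for (rep_ in 1:10) {
    adj <- random_adjacency(10)
    expect_lt(max(abs(topological_overlap(adj) - oracle_tom(adj))), 1e-12)
  }
  bad <- random_adjacency(4); bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(topological_overlap(bad), "symmetric")
  tom_r <- topological_overlap(random_adjacency(15))
  expect_true(all(tom_r >= 0 & tom_r <= 1 + 1e-12))
})

test_that("scale-free fit recognises power-law connectivity", {
  set.seed(11)
  # exact discrete power law k ~ x^{-2.5}
  k <- round(stats::runif(3000)^(-1 / 1.5))
  k <- k[k <= 1000]
  expect_gt(scale_free_fit(k)$fit, 0.8)
  expect_lt(scale_free_fit(k)$slope, 0)
  # increasing-frequency profile gets a negative signed fit
  k2 <- rep(1:10, times = 1:10)
  expect_lt(suppressWarnings(scale_free_fit(k2))$fit, 0)
  expect_true(is.na(scale_free_fit(rep(3, 10))$fit))
})

test_that("pick_soft_power honours the target and degenerate contracts", {
  set.seed(4)
  md <- design_metadata(5)
  v <- matrix(stats::rlnorm(600), 30, 20)
  m <- as_omics(v, md)
  cmb <- combine_and_scale(list(metabolome_pos = m), md)
  pick <- pick_soft_power(cmb, r2_target = 0.8)
  fits <- pick$table$fit
  hit <- which(!is.na(fits) & fits >= 0.8)
  if (length(hit)) expect_equal(pick$beta, pick$table$beta[hit[1]])
  else expect_equal(pick$beta, pick$table$beta[which.max(fits)])
  # r2_target = 0 returns the smallest admissible power
  pick0 <- suppressWarnings(pick_soft_power(cmb, r2_target = 0))
  first_ok <- which(!is.na(fits) & fits >= 0)[1]
  expect_equal(pick0$beta, pick$table$beta[first_ok])
  # perfectly correlated data: identical connectivity, default path
  flat <- matrix(rep(stats::rlnorm(20), each = 12), 12, 20)
  flat <- flat + outer(seq_len(12) * 1e-9, rep(1, 20))  # break exact sd 0
  cmb2 <- combine_and_scale(list(metabolome_pos = as_omics(flat, md)), md)
  expect_warning(pick2 <- pick_soft_power(cmb2), "degenerate|argmax")
  expect_true(pick2$beta %in% 1:20)
  expect_error(pick_soft_power(cmb$values[1:5, ]), ">= 10")
})

test_that("detect_modules recovers planted blocks exactly and rejects noise", {
  tom <- block_tom(c(25, 20, 30))
  params <- network_params(beta = 6, min_module_size = 10)
  part <- detect_modules(tom, params)
  expect_equal(length(setdiff(unique(part$module), "grey")), 3)
  truth <- rep(c("b1", "b2", "b3"), c(25, 20, 30))
  expect_equal(adjusted_rand(stats::setNames(truth, part$analyte_id),
                             stats::setNames(part$module, part$analyte_id)),
               1)
  # colour labels follow decreasing block size
  expect_equal(unname(part$module[1]), "blue")       # size 25
  expect_equal(unname(part$module[26]), "brown")     # size 20
  expect_equal(unname(part$module[46]), "turquoise") # size 30
  # blocks below min_module_size go grey
  part2 <- detect_modules(block_tom(c(25, 5)),
                          network_params(min_module_size = 10))
  expect_equal(sum(part2$module == "grey"), 5)
  # no structure: everything grey
  none <- detect_modules(diag(40), network_params(min_module_size = 5))
  expect_true(all(none$module == "grey"))
  expect_warning(
    tiny <- detect_modules(block_tom(c(4, 4)), network_params()),
    "min_module_size")
  expect_true(all(tiny$module == "grey"))
})

test_that("module labels are stable under analyte permutation", {
  tom <- block_tom(c(22, 14, 18))
  params <- network_params(min_module_size = 10)
  part <- detect_modules(tom, params)
  set.seed(8)
  perm <- sample(nrow(tom))
  part_p <- detect_modules(tom[perm, perm], params)
  a <- stats::setNames(part$module, part$analyte_id)
  b <- stats::setNames(part_p$module, part_p$analyte_id)
  expect_equal(a[names(b)], b)
})
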