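test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "asmip_sim_config")
  expect_error(sim_config(frac_alternative = 1.2), "frac_alternative")
  expect_error(sim_config(noise_sd = -1), "SDs")
  expect_error(sim_config(dilution_factors = c(1, 0.1, 0.01)), "increasing")
  expect_error(sim_config(n_unused_features = 1), "unused")
  expect_error(sim_config(alt_tissue_range = c(1, 5), n_tissues = 5),
               "proper subset")
})

test_that("simulate_truth honours labels, reference, and alternative counts", {
  # no-alternative case: every delta 0, all junctions constitutive
  t0 <- simulate_truth(sim_config(n_genes = 3, frac_alternative = 0, seed = 5))
  expect_true(all(t0$deltas$delta == 0))
  expect_true(all(t0$junctions$status == "constitutive"))

  # exactly ceiling(frac * n) alternatives per gene, by enumeration
  tr <- simulate_truth(sim_config(n_genes = 50, junctions_per_gene = c(10, 10),
                                  frac_alternative = 0.3, seed = 2))
  per_gene <- tr$junctions[, sum(status == "alternative"), by = gene_id]$V1
  expect_true(all(per_gene == 3L))

  # reference delta always 0; alternative junctions shift somewhere
  expect_true(all(tr$deltas[tissue_id == "REF", delta] == 0))
  const <- tr$junctions[status == "constitutive"]
  expect_true(all(merge(tr$deltas, const,
                        by = c("gene_id", "junction_id"))$delta == 0))
  alt_any <- merge(tr$deltas, tr$junctions[status == "alternative"],
                   by = c("gene_id", "junction_id"))
  expect_true(all(alt_any[, any(delta != 0), by = .(gene_id, junction_id)]$V1))

  # all-alternative genes are rejected: no constitutive baseline left
  expect_error(simulate_truth(sim_config(frac_alternative = 1)),
               "constitutive")
})

test_that("renderers are bit-identical under the same seed", {
  cfg <- sim_config(n_genes = 3, junctions_per_gene = c(4, 6), seed = 11)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$truth$probe_effects, b$truth$probe_effects)
  expect_identical(a$seq, b$seq)
  expect_identical(a$array, b$array)
  expect_identical(a$qpcr, b$qpcr)
})

test_that("sequencing counts follow the Poisson depth model", {
  # flat truth: theta = 0 everywhere -> counts ~ Poisson(depth)
  cfg <- sim_config(n_genes = 10, junctions_per_gene = c(10, 10),
                    frac_alternative = 0, probe_effect_sd = 0,
                    tissue_baseline_range = 0, noise_sd = 0,
                    seq_depth_scale = 100, seed = 7)
  x <- render_sequencing(simulate_truth(cfg), cfg)
  expect_true(all(x$value >= 0))
  expect_true(all(x$value == round(x$value)))
  se <- 10 / sqrt(nrow(x))
  expect_lt(abs(mean(x$value) - 100), 3 * se)

  # zero depth -> all counts zero
  cfg0 <- sim_config(n_genes = 2, seq_depth_scale = 0, seed = 1)
  expect_true(all(render_sequencing(simulate_truth(cfg0), cfg0)$value == 0))
})

test_that("array rendering saturates, adds background, and is linear in dilution", {
  # noiseless arrays: ratios of background-corrected intensities across the
  # three dilutions equal the dilution ratios exactly for in-range probes
  cfg <- sim_config(n_genes = 4, junctions_per_gene = c(5, 8), noise_sd = 0,
                    array_background_sd = 0, seed = 3)
  arr <- render_array(simulate_truth(cfg), cfg)
  expect_true(all(arr$value >= 0))
  expect_true(all(arr$value <= cfg$array_saturation))
  pr <- arr[is_unused_feature == FALSE]
  wide <- dcast(pr, gene_id + junction_id + tag + tissue_id ~ dilution,
                value.var = "value")
  ok <- wide[high < cfg$array_saturation &
               low > cfg$array_background_mean + 1]
  expect_gt(nrow(ok), 10)
  ok[, `:=`(r1 = (mid - cfg$array_background_mean) /
                 (low - cfg$array_background_mean),
            r2 = (high - cfg$array_background_mean) /
                 (mid - cfg$array_background_mean))]
  expect_equal(ok$r1, rep(10, nrow(ok)), tolerance = 1e-6)
  expect_equal(ok$r2, rep(10, nrow(ok)), tolerance = 1e-6)

  # strong signal clamps at the saturation ceiling exactly
  cfg2 <- sim_config(n_genes = 2, noise_sd = 0, array_background_sd = 0,
                     array_gain = 1e9, seed = 3)
  arr2 <- render_array(simulate_truth(cfg2), cfg2)
  expect_true(all(arr2[is_unused_feature == FALSE, value] ==
                    cfg2$array_saturation))

  # unused features carry no junction key; probes carry exactly one
  expect_true(all(is.na(arr[is_unused_feature == TRUE, junction_id])))
  expect_true(all(!is.na(arr[is_unused_feature == FALSE, junction_id])))
  expect_equal(arr[is_unused_feature == TRUE, .N,
                   by = .(tissue_id, dilution)][, unique(N)],
               cfg$n_unused_features)
})

test_that("qPCR rendering has slope -1 in theta and whole-primer-set dropout", {
  cfg <- sim_config(n_genes = 3, junctions_per_gene = c(4, 6), noise_sd = 0,
                    qpcr_dropout_prob = 0, seed = 9)
  truth <- simulate_truth(cfg)
  q <- render_qpcr(truth, cfg)
  th <- truth_theta(truth)
  m <- merge(q, th, by = c("gene_id", "junction_id", "tag", "tissue_id"))
  # Ct = intercept - theta exactly when noiseless
  expect_equal(m$value, cfg$qpcr_ct_intercept - m$theta, tolerance = 1e-12)

  # total dropout -> empty table
  cfg1 <- sim_config(n_genes = 2, qpcr_dropout_prob = 1, seed = 1)
  expect_equal(nrow(render_qpcr(simulate_truth(cfg1), cfg1)), 0L)

  # dropout 0.5: fraction of junctions with both primer sets ~ 0.25
  cfg5 <- sim_config(n_genes = 50, junctions_per_gene = c(8, 8),
                     qpcr_dropout_prob = 0.5, seed = 21)
  q5 <- render_qpcr(simulate_truth(cfg5), cfg5)
  both <- q5[, uniqueN(tag), by = .(gene_id, junction_id)][V1 == 2, .N]
  frac <- both / 400
  expect_lt(abs(frac - 0.25), 0.07)  # ~3 binomial SE
})

test_that("conservation: tissue-vs-reference offsets reduce to baselines when noiseless", {
  cfg <- sim_config(n_genes = 3, frac_alternative = 0, noise_sd = 0, seed = 13)
  truth <- simulate_truth(cfg)
  th <- truth_theta(truth)
  ref <- th[tissue_id == "REF", .(gene_id, junction_id, tag, ref = theta)]
  d <- merge(th[tissue_id != "REF"], ref,
             by = c("gene_id", "junction_id", "tag"))
  avg <- d[, .(got = mean(theta - ref)), by = .(gene_id, junction_id, tag)]
  bl <- truth$baselines
  expected <- bl[tissue_id != "REF", .(want = mean(t_base)), by = gene_id]
  expected <- merge(expected, bl[tissue_id == "REF",
                                 .(gene_id, ref_t = t_base)], by = "gene_id")
  m <- merge(avg, expected, by = "gene_id")
  expect_equal(m$got, m$want - m$ref_t, tolerance = 1e-12)
})
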