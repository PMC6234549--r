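test_that("cohort generation is deterministic and matches the default design", {
  a <- generate_cohort(effect_config(), seed = 33)
  b <- generate_cohort(effect_config(), seed = 33)
  expect_identical(a, b)
  expect_length(a$subjects, 15L)
  grp <- vapply(a$subjects, `[[`, "", "group")
  gen <- vapply(a$subjects, `[[`, "", "genotype")
  expect_equal(sum(grp == "MS"), 8L)
  expect_equal(sum(grp == "HC"), 7L)
  expect_equal(sum(grp == "MS" & gen == "HAB"), 4L)
  expect_equal(sum(grp == "HC" & gen == "HAB"), 3L)
  # lesions only in patients, with volumes inside the configured range
  for (s in a$subjects) {
    has_lesion <- "t2_lesion" %in% names(s$regions)
    expect_equal(has_lesion, s$group == "MS")
    if (has_lesion) {
      v <- s$regions$t2_lesion$volume_cm3
      expect_gte(v, 3.6); expect_lte(v, 60.6)
    }
  }
  expect_error(generate_cohort(effect_config(n_ms_hab = -1)), "counts")
})

test_that("true effects are realised: genotype ratios, V_T homogeneity, lesions", {
  coh <- generate_cohort(effect_config(), seed = 12)
  tr <- cohort_truth(coh)
  hc <- tr[tr$group == "HC", ]
  rb <- ratio_of_group_means(hc$bpnd_true[hc$genotype == "HAB"],
                             hc$region[hc$genotype == "HAB"],
                             hc$bpnd_true[hc$genotype == "MAB"],
                             hc$region[hc$genotype == "MAB"])
  rv <- ratio_of_group_means(tr$vt_true[tr$genotype == "HAB"],
                             tr$region[tr$genotype == "HAB"],
                             tr$vt_true[tr$genotype == "MAB"],
                             tr$region[tr$genotype == "MAB"])
  expect_equal(rb$mean_ratio, 1.6, tolerance = 0.05)
  expect_equal(rv$mean_ratio, 1.6, tolerance = 0.05)
  # within-subject V_T spread < 15%; lesion BP_ND above NAWM at matched V_T
  for (s in coh$subjects) {
    vts <- vapply(s$regions, `[[`, 0, "vt_true")
    expect_lt(diff(range(vts)) / min(vts), 0.15)
    if (s$group == "MS") {
      les <- s$regions$t2_lesion
      naw <- s$regions$nawm
      expect_gt(les$bpnd_true, naw$bpnd_true)
      expect_gte(les$vt_true / naw$vt_true, 0.9)
      expect_lte(les$vt_true / naw$vt_true, 1.1)
    }
  }
})

test_that("a null configuration produces no genotype or group effect", {
  cfg <- effect_config(genotype_vt_ratio = 1, genotype_bpnd_ratio = 1,
                       ms_hab_bpnd_increase = 0, lesion_bpnd_multiplier = 1)
  tr <- cohort_truth(generate_cohort(cfg, seed = 8))
  r <- ratio_of_group_means(tr$vt_true[tr$genotype == "HAB"],
                            tr$region[tr$genotype == "HAB"],
                            tr$vt_true[tr$genotype == "MAB"],
                            tr$region[tr$genotype == "MAB"])
  expect_equal(r$mean_ratio, 1, tolerance = 0.05)
})

test_that("noiseless fits reproduce the generated effects to optimiser tolerance", {
  coh <- generate_cohort(effect_config(noise_level = 0), seed = 3)
  tr <- cohort_truth(coh)
  res <- fit_cohort(coh, opts = fit_options(seed = 30),
                    subjects = vapply(coh$subjects, `[[`, "", "id")[
                      vapply(coh$subjects, `[[`, "", "group") == "HC"])
  m <- merge(res, tr[, c("subject", "region", "vt_true", "bpnd_true")],
             by = c("subject", "region"))
  expect_lt(max(abs(m$vt / m$vt_true - 1)), 1e-6)
  expect_lt(max(abs(m$bpnd / m$bpnd_true - 1)), 1e-5)
  fitted <- genotype_contrast(res, "bpnd", subjects = "hc")
  hc <- tr[tr$group == "HC", ]
  truth <- ratio_of_group_means(hc$bpnd_true[hc$genotype == "HAB"],
                                hc$region[hc$genotype == "HAB"],
                                hc$bpnd_true[hc$genotype == "MAB"],
                                hc$region[hc$genotype == "MAB"])
  expect_equal(fitted$mean_ratio, truth$mean_ratio, tolerance = 1e-5)
})

test_that("frame noise follows the count-statistics variance model", {
  sch <- default_frame_schedule()
  tac <- model_tac(model_spec("2T4k", TRUE),
                   kinetic_params(K1 = 0.12, k2 = 0.16, k3 = 0.05, k4 = 0.04,
                                  vb = 0.05), feng_fixture(), sch)
  expect_identical(add_noise(tac, sch, 0), tac)
  # empirical SD of one frame over 1000 replicates vs the formula
  lam <- log(2) / 109.77
  raw <- sqrt(pmax(tac, 0) * exp(lam * frame_mid(sch, "min")) / (sch$dur_s / 60))
  s <- tac[which.max(tac)] / raw[which.max(tac)]
  reps <- vapply(1:1000, function(i) add_noise(tac, sch, 0.05, seed = i)[10], 0)
  expect_equal(sd(reps), 0.05 * raw[10] * s, tolerance = 0.05)
  # longer frames are less noisy at equal activity
  flat <- rep(10, 19)
  sds <- vapply(1:500, function(i) add_noise(flat, sch, 0.05, seed = 2000 + i), flat)
  expect_lt(sd(sds[19, ]), sd(sds[1, ]))
  # halving the noise level halves the empirical residual SD
  r1 <- vapply(1:100, function(i) add_noise(tac, sch, 0.06, seed = 3000 + i) - tac, tac)
  r2 <- vapply(1:100, function(i) add_noise(tac, sch, 0.03, seed = 4000 + i) - tac, tac)
  expect_equal(sd(r1) / sd(r2), 2, tolerance = 0.1)
})

test_that("ROI aggregation is a volume-weighted mean", {
  expect_equal(aggregate_rois(list(c(0, 2), c(4, 6)), c(1, 1)), c(2, 4))
  expect_equal(aggregate_rois(list(c(0, 0), c(4, 8)), c(1e-9, 1)), c(4, 8),
               tolerance = 1e-6)
  expect_equal(aggregate_rois(list(c(0, 0), c(4, 4)), c(1, 3)), c(3, 3))
  expect_error(aggregate_rois(list(1:3, 1:2), c(1, 1)), "schedule")
  expect_error(aggregate_rois(list(1:3, 1:3), c(1, 0)), "positive")
})

test_that("the outlier toggle removes one patient's lesion elevation", {
  coh <- generate_cohort(effect_config(outlier_patient = TRUE), seed = 5)
  tr <- cohort_truth(coh)
  ms <- tr[tr$group == "MS", ]
  wide <- merge(ms[ms$region == "nawm", c("subject", "bpnd_true")],
                ms[ms$region == "t2_lesion", c("subject", "bpnd_true")],
                by = "subject", suffixes = c("_nawm", "_les"))
  ratios <- wide$bpnd_true_les / wide$bpnd_true_nawm
  expect_equal(sort(ratios)[1], 1, tolerance = 1e-9)
  expect_true(all(sort(ratios)[-1] > 2))
})
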