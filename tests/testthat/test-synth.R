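# Synthetic cohort generator: determinism, invariants, response model.

test_that("generated plans are deterministic per (seed, plan index)", {
  cfg <- cohort_config(n_plans = 2, n_control_points = 14, leaf_pairs = 12,
                       seed = 31)
  p1 <- generate_plan(cfg, 1)
  p1b <- generate_plan(cfg, 1)
  expect_identical(p1, p1b)
  p2 <- generate_plan(cfg, 2)
  expect_false(identical(p1$arcs[[1]]$control_points[[2]]$bankA,
                         p2$arcs[[1]]$control_points[[2]]$bankA))
})

test_that("generated arcs satisfy every plan invariant and the speed caps", {
  for (seed in 1:5) {
    cfg <- cohort_config(n_plans = 1, n_control_points = 40, leaf_pairs = 20,
                         seed = seed)
    plan <- generate_plan(cfg, 1)
    expect_silent(validate_plan(plan))
    for (arc in plan$arcs) {
      f <- kinematic_features(arc)
      expect_lt(f[["MaxLS_A"]], 20)
      expect_lt(f[["MaxLS_B"]], 20)
      expect_lt(f[["MaxLA_A"]], 200)
      expect_lt(f[["MaxLA_B"]], 200)
    }
  }
})

test_that("gpr response follows the planted linear form", {
  cfg <- cohort_config(n_plans = 2, n_control_points = 10, leaf_pairs = 12,
                       fluence_spacing = 2, seed = 5)
  coh <- generate_cohort(cfg)
  # zero coefficients, zero noise: gpr equals the intercept exactly
  cfg0 <- cohort_config(noise_sd = c(gpr_2_2 = 0, gpr_3_2 = 0),
                        gpr_coef = list(gpr_2_2 = c(LS0_4_B = 0),
                                        gpr_3_2 = c(LS0_4_B = 0)),
                        seed = 5)
  gpr0 <- gpr_response(coh$features, cfg0)
  expect_true(all(gpr0$gpr_2_2 == 93.50))
  expect_true(all(gpr0$gpr_3_2 == 96.53))
  # zero noise with known coefficients equals the hand-computed linear form
  cfg1 <- cohort_config(noise_sd = c(gpr_2_2 = 0, gpr_3_2 = 0),
                        gpr_coef = list(gpr_2_2 = c(MeanLS_A = 1.5),
                                        gpr_3_2 = c(MeanLS_A = 0.5)),
                        seed = 5)
  gpr1 <- gpr_response(coh$features, cfg1)
  z <- scale(coh$features$MeanLS_A)[, 1]
  expect_equal(gpr1$gpr_2_2, pmin(pmax(93.50 - 1.5 * z, 0), 100))
  # unknown feature names in the coefficient vector are rejected
  cfg_bad <- cohort_config(gpr_coef = list(gpr_2_2 = c(NotAFeature = 1),
                                           gpr_3_2 = c(LS0_4_B = 1)))
  expect_error(gpr_response(coh$features, cfg_bad), "NotAFeature")
})

test_that("all-static plans have zero mean leaf speed", {
  cfg <- cohort_config(n_plans = 1, n_control_points = 10, leaf_pairs = 12,
                       speed_bin_weights = c(1, 0, 0, 0, 0), seed = 2)
  # weights degenerate to the lowest bin; scale speeds to zero via max_speed
  plan <- generate_plan(cfg, 1)
  arc <- plan$arcs[[1]]
  f <- kinematic_features(arc)
  expect_lt(f[["MeanLS_A"]], 4)        # all samples in the 0-4 bin
  expect_equal(unname(f["LS0_4_A"]), 1)
})

test_that("cohort QA table is byte-identical on re-run with the same seed", {
  cfg <- cohort_config(n_plans = 3, n_control_points = 10, leaf_pairs = 12,
                       n_outliers = 1, fluence_spacing = 2, seed = 17)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  p1 <- tempfile(); p2 <- tempfile()
  on.exit(unlink(c(p1, p2)))
  write_qa_table(c1$qa, p1); write_qa_table(c2$qa, p2)
  expect_identical(readBin(p1, raw(), file.info(p1)$size),
                   readBin(p2, raw(), file.info(p2)$size))
  expect_identical(c1$truth, c2$truth)
})

test_that("outlier planting depresses all arcs of the chosen plans", {
  cfg <- cohort_config(n_plans = 6, n_control_points = 10, leaf_pairs = 12,
                       n_outliers = 2, fluence_spacing = 2, seed = 23)
  coh <- generate_cohort(cfg)
  expect_length(coh$truth$outlier_plans, 2)
  out <- coh$qa$plan_id %in% coh$truth$outlier_plans
  expect_true(max(coh$qa$gpr_2_2[out]) < min(coh$qa$gpr_2_2[!out]))
  expect_true(max(coh$qa$gpr_3_2[out]) < min(coh$qa$gpr_3_2[!out]))
  # with no outliers requested the truth record lists none
  cfg0 <- cohort_config(n_plans = 3, n_control_points = 10, leaf_pairs = 12,
                        fluence_spacing = 2, seed = 23)
  expect_length(generate_cohort(cfg0)$truth$outlier_plans, 0)
})

test_that("mean synthetic GPR sits near the configured intercepts", {
  cfg <- cohort_config(n_plans = 25, n_control_points = 16, leaf_pairs = 16,
                       fluence_spacing = 2, seed = 41)
  coh <- generate_cohort(cfg)
  expect_lt(abs(mean(coh$qa$gpr_3_2) - 96.53), 1.90)  # within 1 SD
  expect_lt(abs(mean(coh$qa$gpr_2_2) - 93.50), 2.49)
})
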