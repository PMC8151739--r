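test_that("generators are pure functions of config and seed", {
  cfg <- generator_config()
  m1 <- generate_pressure_matrix("supine", cfg, seed = 9)
  m2 <- generate_pressure_matrix("supine", cfg, seed = 9)
  expect_identical(m1$values, m2$values)
  expect_false(identical(m1$values,
                         generate_pressure_matrix("supine", cfg, seed = 10)$values))
  c1 <- generate_trial_cohort(cfg, "lateral", seed = 4)
  c2 <- generate_trial_cohort(cfg, "lateral", seed = 4)
  expect_identical(lapply(c1, function(t) t$matrix$values),
                   lapply(c2, function(t) t$matrix$values))
  expect_identical(vapply(c1, function(t) t$comfort$total, numeric(1)),
                   vapply(c2, function(t) t$comfort$total, numeric(1)))
})

test_that("noise-free templates are reproducible with in-band magnitudes", {
  cfg <- generator_config()
  t1 <- generate_pressure_matrix("supine", cfg, seed = 1, noise_sd_kpa = 0)
  t2 <- generate_pressure_matrix("supine", cfg, seed = 99, noise_sd_kpa = 0)
  expect_identical(t1$values, t2$values)  # severity 0, no noise: seed-free
  pk <- peak_pressure(t1)
  expect_gte(pk, 7.5); expect_lte(pk, 9.2)
  # the lateral peak sits in the temporal zone (central rows)
  tl <- generate_pressure_matrix("lateral", cfg, seed = 1, noise_sd_kpa = 0)
  peak_cell <- which(tl$values == max(tl$values), arr.ind = TRUE)
  expect_gt(peak_cell[1, 1], 10); expect_lt(peak_cell[1, 1], 24)
  # order-of-magnitude bands for the contact average
  expect_gt(average_pressure(t1), 0.8); expect_lt(average_pressure(t1), 4)
})

test_that("cohorts follow the 7 x 6 design with comfort tied to closeness", {
  cfg <- generator_config()
  cohort <- generate_trial_cohort(cfg, "supine", seed = 2)
  expect_length(cohort, 42)
  expect_true(all(vapply(cohort, function(t) t$emg_valid, logical(1))))
  totals <- vapply(cohort, function(t) t$comfort$total, numeric(1))
  pillow <- vapply(cohort, function(t) t$pillow_id, character(1))
  # the undistorted pillow scores best on average, the worst pillow worst
  expect_gt(mean(totals[pillow == "P1"]), mean(totals[pillow == "P7"]))
  # in expectation (averaged over cohorts) P1 is the best pillow
  by_pillow <- rowMeans(vapply(1:5, function(s) {
    co <- generate_trial_cohort(cfg, "supine", seed = 100 + s)
    tapply(vapply(co, function(t) t$comfort$total, numeric(1)),
           vapply(co, function(t) t$pillow_id, character(1)), mean)
  }, numeric(cfg$n_pillows)))
  expect_equal(names(which.max(by_pillow)), "P1")
})

test_that("expert panels recover the sensitivity ranking and magnitudes", {
  ref <- reference_partition_weights()$weights
  clean <- generate_expert_panel(1, ref, noise = 0, seed = 1)
  w <- fahp_weights(to_complementary(clean[[1]]))$weights
  expect_equal(names(sort(w, decreasing = TRUE)),
               c("B3", "B2", "B1", "A1", "B4", "A2", "A3"))
  # equal sensitivities give uniform weights
  eq <- generate_expert_panel(1, c(a = 1, b = 1, c = 1), noise = 0, seed = 1)
  expect_equal(unname(fahp_weights(to_complementary(eq[[1]]))$weights),
               rep(1 / 3, 3), tolerance = 1e-12)
  # Monte-Carlo weight recovery: 100 replicate panels of 10 noisy experts
  errs <- vapply(1:100, function(rep_i) {
    panel <- generate_expert_panel(10, ref, noise = 0.5, seed = 1000 + rep_i)
    agg <- aggregate_experts(lapply(panel, function(jm)
      fahp_weights(to_complementary(jm))))
    mean(abs(agg$weights[names(ref)] - ref))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("contour nodes scale with physique and calibrations round-trip", {
  ms <- generate_contour_nodes("MS", seed = 3)
  ml <- generate_contour_nodes("ML", seed = 3)
  fs <- generate_contour_nodes("FS", seed = 3)
  expect_true(all(ml$depth_mm >= ms$depth_mm))
  expect_true(all(fs$depth_mm <= ms$depth_mm))
  expect_true(all(ms$depth_mm >= 0 & ms$depth_mm <= 110))
  expect_setequal(names(ms$depth_mm),
                  c("A1", "A2", "A3", "B1", "B2", "B3", "B4"))
  # noiseless generated calibration inverts fit_power_law exactly
  cal <- generate_calibration(a = 3.1, b = -0.8)
  expect_equal(cal$fitted_a, 3.1, tolerance = 1e-9)
  expect_equal(cal$fitted_b, -0.8, tolerance = 1e-9)
  # the packaged reference table loads as a valid calibration
  ref <- reference_elastic_calibration()
  expect_s3_class(ref, "elastic_calibration")
  expect_equal(nrow(ref$pairs), 6)
  expect_equal(ref$pairs$diameter_mm, seq(6, 21, by = 3))
})

test_that("synthetic ideal matrices keep the mean gradient in the comfort band", {
  cfg <- generator_config()
  for (seed in c(1, 2, 42)) {
    for (post in c("supine", "lateral")) {
      im <- synthetic_ideal_matrix(post, cfg, seed = seed)
      gv <- mean_gradient(im$matrix, "pointwise")
      expect_gte(gv, 0.2); expect_lte(gv, 0.4)
    }
  }
})
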