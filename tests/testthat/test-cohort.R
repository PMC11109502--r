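test_that("the normative surface declines with ring and age", {
  expect_equal(normative_sensitivity(3, 3, 45), 33)
  expect_equal(normative_sensitivity(21, 3, 45), 31.5)   # ring 3
  expect_equal(normative_sensitivity(3, 3, 65), 31)
  expect_equal(normative_sensitivity(-9, 15, 45), 33 - 0.5 * 2)
  expect_error(normative_sensitivity(3, 3, 110), "age")
  # clamping
  expect_gte(normative_sensitivity(21, 21, 100), 20)
})

test_that("defect templates depress the affected region only", {
  cf <- hvf_common_frame()
  base <- data.frame(x_deg = cf$x_deg, y_deg = cf$y_deg,
                     truth_db = normative_sensitivity(cf$x_deg, cf$y_deg, 52))
  set.seed(4)
  hemi <- apply_vfd_template(base, list(side = "left", vfd_type = "hemianopia"))
  left <- hemi$x_deg < 0
  expect_true(all(hemi$truth_db[left] < 18))
  expect_true(all(hemi$truth_db[left & abs(hemi$x_deg) > 3] <= 8))
  expect_equal(hemi$truth_db[!left], base$truth_db[!left])

  quad <- apply_vfd_template(base, list(side = "right", vfd_type = "quadrantanopia",
                                        quadrant = "UR"))
  ur <- quad$x_deg > 0 & quad$y_deg > 0
  lr <- quad$x_deg > 0 & quad$y_deg < 0
  expect_true(all(quad$truth_db[ur] < 18))
  expect_equal(quad$truth_db[lr], base$truth_db[lr])
})

test_that("measured exams reduce to the truth when noise vanishes", {
  cf <- hvf_common_frame()
  truth <- data.frame(x_deg = cf$x_deg, y_deg = cf$y_deg, truth_db = 25)
  e <- measure_exam(truth, age = 45, eye = "OD", visit = "baseline",
                    patient_id = "P1", noise_sd_db = 0)
  expect_equal(nrow(e$values), 52)
  expect_true(all(e$values$sensitivity_db == 25))
  # nasal extension points take the nearest tested truth
  expect_equal(e$values$sensitivity_db[e$values$x_deg == -27], c(25, 25))
})

test_that("deep-defect points land in the worst probability category", {
  cf <- hvf_common_frame()
  truth <- data.frame(x_deg = cf$x_deg, y_deg = cf$y_deg,
                      truth_db = normative_sensitivity(cf$x_deg, cf$y_deg, 52))
  set.seed(9)
  truth <- apply_vfd_template(truth, list(side = "left", vfd_type = "hemianopia"))
  e <- measure_exam(truth, 52, "OD", "baseline", "P1", noise_sd_db = 0)
  deep <- e$values$x_deg < -3 & e$values$x_deg >= -21
  expect_true(all(e$values$td_prob_pct[deep] == 0.5))
  expect_true(all(e$values$td_prob_pct[e$values$x_deg > 0] == 100))
})

test_that("probability categories are calibrated against the normative SD", {
  # truth equal to the norm: about 5% of points should flag below the
  # 5th-percentile quantile (any category other than within-normal-limits)
  cf <- hvf_common_frame()
  truth <- data.frame(x_deg = cf$x_deg, y_deg = cf$y_deg,
                      truth_db = normative_sensitivity(cf$x_deg, cf$y_deg, 45))
  set.seed(123)
  flags <- replicate(250, {
    e <- measure_exam(truth, 45, "OD", "baseline", "P1",
                      noise_sd_db = 3, norm_sd_db = 3)
    mean(e$values$td_prob_pct < 100)
  })
  n_pts <- 250 * 52
  se <- sqrt(0.05 * 0.95 / n_pts)
  expect_lt(abs(mean(flags) - 0.05), 4 * se)
})

test_that("repeat measurements show additive test-retest variance", {
  cf <- hvf_common_frame()
  truth <- data.frame(x_deg = cf$x_deg, y_deg = cf$y_deg, truth_db = 25)
  set.seed(1)
  d <- replicate(100, {
    e1 <- measure_exam(truth, 45, "OD", "baseline", "P1", noise_sd_db = 3)
    e2 <- measure_exam(truth, 45, "OD", "week12", "P1", noise_sd_db = 3)
    e2$values$sensitivity_db - e1$values$sensitivity_db
  })
  expect_equal(sd(d), 3 * sqrt(2), tolerance = 0.05)
})

test_that("permuted blocks balance every complete block", {
  set.seed(6)
  seq8 <- permuted_block_randomize(8, 4)
  for (k in 1:2)
    expect_equal(sum(seq8[1:(4 * k)] == "NV"), 2 * k)
  seq79 <- permuted_block_randomize(79, 4)
  expect_lte(abs(sum(seq79 == "NV") - sum(seq79 == "NV-C")), 2)
  set.seed(10); s1 <- permuted_block_randomize(20, 4)
  set.seed(10); s2 <- permuted_block_randomize(20, 4)
  expect_identical(s1, s2)
  expect_error(permuted_block_randomize(10, 3), "block_size")
})

test_that("cohorts are reproducible and sized by the configuration", {
  cfg <- cohort_config(seed = 77, n_per_arm = c("NV" = 8, "NV-C" = 6),
                       dropout = c("NV" = 0, "NV-C" = 0))
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$truths, c2$truths)
  expect_identical(c1$meta, c2$meta)
  expect_equal(length(c1$exams), 14 * 4)  # 2 eyes x 2 visits, no dropout
  expect_equal(as.vector(table(factor(c1$meta$arm, c("NV", "NV-C")))), c(8, 6))
  c3 <- generate_cohort(cohort_config(seed = 78, n_per_arm = c("NV" = 8, "NV-C" = 6),
                                      dropout = c("NV" = 0, "NV-C" = 0)))
  expect_false(identical(c1$truths$truth_db, c3$truths$truth_db))

  # dropouts lose their follow-up exams only
  cfg_drop <- cohort_config(seed = 3, n_per_arm = c("NV" = 10, "NV-C" = 10),
                            dropout = c("NV" = 1, "NV-C" = 1))
  cd <- generate_cohort(cfg_drop)
  expect_true(all(cd$meta$dropped))
  expect_equal(length(cd$exams), 20 * 2)
})

test_that("generated demographics follow the configured mix", {
  cfg <- cohort_config(seed = 14, n_per_arm = c("NV" = 150, "NV-C" = 150),
                       dropout = c("NV" = 0, "NV-C" = 0))
  co <- generate_cohort(cfg)
  m <- co$meta
  n <- nrow(m)
  expect_equal(n, 300)
  # binomial tolerance: 4 standard errors
  tol <- function(p) 4 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(m$vfd_side == "left") - 0.56), tol(0.56))
  expect_lt(abs(mean(m$vfd_type == "hemianopia") - 0.533), tol(0.533))
  expect_true(all(m$age >= 19 & m$age <= 80))
  expect_equal(mean(m$age), 52, tolerance = 0.1)
  expect_true(all(is.na(m$vfd_quadrant) == (m$vfd_type == "hemianopia")))
})

test_that("programmed effects propagate to the scored improved area", {
  # noise off: improvement equals the truth-map gain exactly
  p_imp <- 3 / (26 * pnorm((8 - 6) / 2))  # aim for ~3 improved points
  cfg <- cohort_config(seed = 31, n_per_arm = c("NV" = 100, "NV-C" = 100),
                       noise_sd_db = 0, dropout = c("NV" = 0, "NV-C" = 0),
                       p_hemianopia = 1,  # 26 improvable points per patient
                       effect = list(
                         "NV" = list(p_improve = p_imp, gain_mean_db = 8, gain_sd_db = 2),
                         "NV-C" = list(p_improve = p_imp, gain_mean_db = 8, gain_sd_db = 2)))
  co <- generate_cohort(cfg)
  fields <- integrate_cohort(co$exams)
  out <- score_cohort(fields, co$meta)
  expect_equal(mean(out$improved_area_hemi_deg2), 108, tolerance = 0.12)
})
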