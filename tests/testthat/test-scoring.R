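ul_locs <- function() region_members(region_quadrant("UL"))

# field whose left hemifield (or UL quadrant) is defective
defective_field <- function(region = region_hemifield("left"), pid = "P1",
                            visit = "baseline", defect_sens = 5) {
  cf <- hvf_common_frame()
  in_def <- paste(cf$x_deg, cf$y_deg) %in%
    with(region_members(region), paste(x_deg, y_deg))
  sens <- ifelse(in_def, defect_sens, 30)
  make_field(sens, pid = pid, visit = visit,
             td = sens - 30, prob = ifelse(in_def, 0.5, 100))
}

test_that("defect masks apply the strict <5% probability rule", {
  f <- make_field(30)
  f <- poke(f, -3, 3, "td_prob_pct", 2)
  f <- poke(f, -9, 3, "td_prob_pct", 5)
  m <- region_members(defect_mask(f))
  expect_equal(nrow(m), 1)                   # category 2 is in, 5 is out
  expect_equal(c(m$x_deg, m$y_deg), c(-3, 3))
  expect_equal(nrow(region_members(defect_mask(make_exam(eye = "BIN")))), 0)
})

test_that("defects classify by majority hemifield and quadrant occupancy", {
  left_hemi <- region_mask(region_members(region_hemifield("left")))
  cls <- classify_vfd(left_hemi)
  expect_equal(cls$side, "left")
  expect_equal(cls$vfd_type, "hemianopia")

  ul_only <- region_mask(ul_locs())
  cls <- classify_vfd(ul_only)
  expect_equal(cls$vfd_type, "quadrantanopia")
  expect_equal(cls$quadrant, "UL")

  # 2 of 13 lower points is under the 25% occupancy bar: still UL quadrantanopia
  ll2 <- head(region_members(region_quadrant("LL")), 2)
  cls <- classify_vfd(region_mask(rbind(ul_locs(), ll2)))
  expect_equal(cls$vfd_type, "quadrantanopia")
  expect_equal(cls$quadrant, "UL")
  # 4 of 13 (>= 25%) tips it to hemianopia
  ll4 <- head(region_members(region_quadrant("LL")), 4)
  expect_equal(classify_vfd(region_mask(rbind(ul_locs(), ll4)))$vfd_type,
               "hemianopia")

  expect_error(classify_vfd(region_mask(hvf_common_frame()[0, ])), "empty")
  balanced <- rbind(head(ul_locs(), 2),
                    head(region_members(region_quadrant("UR")), 2))
  expect_error(classify_vfd(region_mask(balanced)), "lateralize")
})

test_that("improved area counts 36 deg2 per point above the gain threshold", {
  pre <- defective_field()
  hemi <- region_hemifield("left")
  # exactly 2 points gain +6 dB -> 72 deg2; 3 points -> 108
  post2 <- poke(poke(pre, -3, 3, "sensitivity_db", 11), -9, 3, "sensitivity_db", 11)
  post2 <- hvf_exam("P1", "BIN", "week12", post2$values)
  expect_equal(improved_area(pre, post2, hemi), 72)
  post3 <- poke(post2, -15, 3, "sensitivity_db", 11)
  post3 <- hvf_exam("P1", "BIN", "week12", post3$values)
  expect_equal(improved_area(pre, post3, hemi), 108)
  expect_equal(improved_area(pre, post3, region_whole()), 108)

  # a uniform +5.9 dB gain is below threshold everywhere
  up <- pre$values; up$sensitivity_db <- pmin(up$sensitivity_db + 5.9, 50)
  expect_equal(improved_area(pre, hvf_exam("P1", "BIN", "week12", up), hemi), 0)

  # 5 points gaining +10 dB from a 4 dB baseline -> 180
  pre5 <- defective_field(defect_sens = 4)
  locs <- head(region_members(hemi), 5)
  v <- pre5$values
  i <- match(paste(locs$x_deg, locs$y_deg), paste(v$x_deg, v$y_deg))
  v$sensitivity_db[i] <- v$sensitivity_db[i] + 10
  expect_equal(improved_area(pre5, hvf_exam("P1", "BIN", "week12", v), hemi), 180)
})

test_that("points already at the normal ceiling do not count as improvable", {
  pre <- make_field(c(rep(30, 26), rep(10, 26)))
  post_v <- pre$values
  post_v$sensitivity_db <- post_v$sensitivity_db + 8
  post_v$sensitivity_db <- pmin(post_v$sensitivity_db, 50)
  post <- hvf_exam("P1", "BIN", "week12", post_v)
  expect_equal(improved_area(pre, post, region_whole()), 26 * 36)
  expect_equal(improved_area(pre, post, region_whole(), normal_cap = NULL), 52 * 36)
})

test_that("improved area is monotone in its threshold and nested by region", {
  set.seed(33)
  for (rep in 1:10) {
    pre <- make_field(runif(52, 0, 28))
    post <- hvf_exam("P1", "BIN", "week12",
                     within(pre$values,
                            sensitivity_db <- pmin(sensitivity_db + runif(52, 0, 12), 50)))
    hemi <- region_hemifield(sample(c("left", "right"), 1))
    a_whole <- improved_area(pre, post, region_whole())
    expect_gte(a_whole, improved_area(pre, post, hemi))
    expect_gte(improved_area(pre, post, region_whole(), delta_db = 4), a_whole)
    expect_lte(improved_area(pre, post, region_whole(), delta_db = 8), a_whole)
  }
})

test_that("MTD is the regional mean and shifts linearly", {
  f <- make_field(10, td = -20)
  expect_equal(mtd(f, region_whole()), -20)
  cf <- hvf_common_frame()
  f2 <- make_field(10, td = ifelse(cf$x_deg < 0, -30, -10))
  expect_equal(mtd(f2, region_whole()), -20)
  expect_equal(mtd(f2, region_hemifield("left")), -30)
  shift <- f2; shift$values$td_db <- shift$values$td_db + 4.5
  expect_equal(mtd(shift, region_whole()), mtd(f2, region_whole()) + 4.5)
})

test_that("score_patient assembles outcomes on the classified hemifield", {
  pre <- defective_field()
  # unchanged follow-up: nothing improves, nobody responds
  same <- hvf_exam("P1", "BIN", "week12", pre$values)
  rec <- score_patient(pre, same, arm = "NV")
  expect_equal(rec$improved_area_hemi_deg2, 0)
  expect_equal(rec$mtd_delta_hemi, 0)
  expect_false(rec$responder_hemi)
  expect_equal(rec$vfd_side, "left")
  expect_equal(rec$vfd_type, "hemianopia")

  # +8 dB at 3 defective-hemifield points: 108 deg2 in both regions,
  # and the hemifield MTD delta is the mean gain over all 26 points
  v <- pre$values
  i <- match(c("-3,3", "-9,3", "-15,3"), paste(v$x_deg, v$y_deg, sep = ","))
  v$sensitivity_db[i] <- v$sensitivity_db[i] + 8
  v$td_db[i] <- v$td_db[i] + 8
  rec <- score_patient(pre, hvf_exam("P1", "BIN", "week12", v), arm = "NV")
  expect_equal(rec$improved_area_hemi_deg2, 108)
  expect_equal(rec$improved_area_whole_deg2, 108)
  expect_equal(rec$mtd_delta_hemi, 3 * 8 / 26)
  expect_equal(rec$mtd_delta_whole, 3 * 8 / 52)
  expect_true(rec$responder_hemi)
})

test_that("noise-only fields reproduce the closed-form null improved area", {
  # per-point change is N(0, sd*sqrt(2)); P(gain >= 6) with sd = 3 gives
  # about 2.0 improved points per 26-point hemifield
  sd <- 3
  p <- pnorm(6 / (sd * sqrt(2)), lower.tail = FALSE)
  expected_points <- 26 * p
  set.seed(2024)
  n_pat <- 600
  hemi <- region_hemifield("left")
  counts <- vapply(seq_len(n_pat), function(i) {
    pre <- make_field(pmin(pmax(20 + rnorm(52, 0, sd), 0), 50))
    post <- make_field(pmin(pmax(20 + rnorm(52, 0, sd), 0), 50), visit = "week12")
    improved_area(pre, post, hemi) / 36
  }, numeric(1))
  mc_se <- sqrt(26 * p * (1 - p) / n_pat)
  expect_lt(abs(mean(counts) - expected_points), 3.5 * mc_se)
})

test_that("programmed improvements are recovered exactly without noise", {
  cfg <- cohort_config(seed = 5, n_per_arm = c("NV" = 6, "NV-C" = 6),
                       noise_sd_db = 0,
                       dropout = c("NV" = 0, "NV-C" = 0))
  cohort <- generate_cohort(cfg)
  fields <- integrate_cohort(cohort$exams)
  outcomes <- score_cohort(fields, cohort$meta)
  for (j in seq_len(nrow(outcomes))) {
    tr <- cohort$truths[cohort$truths$patient_id == outcomes$patient_id[j], ]
    expect_equal(outcomes$improved_area_whole_deg2[j],
                 36 * sum(tr$gain_db >= 6 & tr$truth_db < 30))
  }
})
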