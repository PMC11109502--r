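# Fixture builders and independent oracles used across the suite.

# Uniform field values over a frame
flat_values <- function(frame, sens = 30, td = 0, prob = 100) {
  data.frame(x_deg = frame$x_deg, y_deg = frame$y_deg,
             sensitivity_db = rep_len(sens, nrow(frame)),
             td_db = rep_len(td, nrow(frame)),
             td_prob_pct = rep_len(prob, nrow(frame)))
}

make_exam <- function(pid = "P1", eye = "OD", visit = "baseline",
                      sens = 30, td = 0, prob = 100) {
  frame <- if (eye == "BIN") hvf_common_frame() else hvf_native_frame(eye)
  hvf_exam(pid, eye, visit, flat_values(frame, sens, td, prob))
}

# Binocular field straight from a sensitivity vector on the common frame
make_field <- function(sens, pid = "P1", visit = "baseline",
                       td = sens - 30, prob = 100) {
  make_exam(pid, "BIN", visit, sens = sens, td = td, prob = prob)
}

# Modify one location of an exam's values
poke <- function(exam, x, y, col, value) {
  i <- which(exam$values$x_deg == x & exam$values$y_deg == y)
  stopifnot(length(i) == 1L)
  exam$values[[col]][i] <- value
  hvf_exam(exam$patient_id, exam$eye, exam$visit, exam$values)
}

# ---- Independent oracles ----------------------------------------------

# Two-sided Fisher p by full enumeration of the hypergeometric family
# with fixed margins, probability-mass rule.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(ks, function(k) {
    choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[ks == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled (untied) sample to the two groups.
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  m <- length(a)
  r <- rank(pooled)
  combs <- utils::combn(length(pooled), m)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * length(b) / 2
  p <- if (w_obs > mu) mean(w_all >= w_obs) else mean(w_all <= w_obs)
  min(1, 2 * p)
}

# Null outcome table for calibration studies: both arms drawn from the
# same generator (binomial improved-point counts, normal MTD changes).
null_outcomes <- function(n1 = 40, n2 = 35, p_point = pnorm(-6 / (3 * sqrt(2)))) {
  n <- n1 + n2
  pre_h <- rnorm(n, -20, 9)
  d_h <- rnorm(n, 0, 2)
  pre_w <- rnorm(n, -10, 5)
  d_w <- rnorm(n, 0, 1.5)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    arm = rep(c("NV", "NV-C"), c(n1, n2)),
    vfd_side = "left", vfd_type = "hemianopia",
    improved_area_hemi_deg2 = 36 * rbinom(n, 26, p_point),
    improved_area_whole_deg2 = 36 * rbinom(n, 52, p_point),
    mtd_pre_hemi = pre_h, mtd_post_hemi = pre_h + d_h, mtd_delta_hemi = d_h,
    mtd_pre_whole = pre_w, mtd_post_whole = pre_w + d_w, mtd_delta_whole = d_w,
    responder_hemi = d_h > 0, responder_whole = d_w > 0
  )
}
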