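# The trial's statistical battery: normality-gated parametric /
# nonparametric tests, 2x2 categorical tests, the analysis report, and
# participant-flow arithmetic.

#' @noRd
.test_result <- function(test_name, statistic, p_value, n, sidedness = "two.sided") {
  stopifnot(is.finite(p_value), p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = p_value, n = n, sidedness = sidedness),
            class = "vfd_test_result")
}

#' @export
print.vfd_test_result <- function(x, ...) {
  cat("<", x$test_name, "> statistic = ", signif(x$statistic, 4),
      ", p ", format_p(x$p_value), ", n = ", paste(x$n, collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Format a p-value in clinical-table style
#'
#' Two decimals (three below .01), with `<.001` and `>.99` for the
#' extremes.
#'
#' @param p Numeric p-value(s) in \[0, 1\].
#' @return Character vector like `".03"`, `".005"`, `"<.001"`, `">.99"`.
#' @export
format_p <- function(p) {
  out <- sub("^0", "", sprintf("%.2f", p))
  small <- p < 0.01
  out[small] <- sub("^0", "", sprintf("%.3f", p[small]))
  out[p < 0.001] <- "<.001"
  out[p > 0.99] <- ">.99"
  out
}

#' Normality gate for test selection
#'
#' Applies a Shapiro-Wilk test and routes to a parametric test when
#' normality is not rejected (p >= `alpha`), nonparametric otherwise. For
#' paired comparisons the gate is applied to the paired differences.
#'
#' @param x Numeric sample (n >= 3, non-degenerate).
#' @param alpha Gate level; default 0.05.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
shapiro_wilk_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("normality gate needs at least 3 observations")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  if (stats::shapiro.test(x)$p.value >= alpha) "parametric" else "nonparametric"
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1, upper-tail p.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @return A `vfd_test_result`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- .check_2x2(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in 2x2 table")
  res <- stats::chisq.test(counts, correct = FALSE)
  .test_result("pearson_chi_square", res$statistic, res$p.value, sum(counts))
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided by the probability-mass rule: with the margins fixed, the
#' p-value sums the hypergeometric probabilities of every table whose
#' probability does not exceed the observed table's.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @return A `vfd_test_result`; `statistic` is the sample odds ratio (with
#'   0/0 cells yielding `NaN` handled as by [stats::fisher.test()]).
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- .check_2x2(counts)
  res <- stats::fisher.test(counts)
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  .test_result("fisher_exact", or, res$p.value, sum(counts))
}

.check_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("empty table")
  counts
}

#' Rank and t tests
#'
#' Two-sided comparisons used throughout the analysis. `mann_whitney_u()`
#' compares two independent samples: the exact null distribution is
#' enumerated for small untied samples (both n <= 8), otherwise the
#' normal approximation with tie correction is used.
#' `wilcoxon_signed_rank()` compares paired samples after dropping zero
#' differences (an all-zero difference vector is an error). `paired_t()`
#' and `independent_t()` are the parametric counterparts (Welch variant
#' for the independent test).
#'
#' @param a,b Independent numeric samples (n >= 2 each).
#' @param pre,post Paired numeric samples of equal length.
#' @return A `vfd_test_result`.
#' @name rank_and_t_tests
NULL

#' @rdname rank_and_t_tests
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  .test_result("mann_whitney_u", res$statistic, res$p.value,
               c(length(a), length(b)))
}

#' @rdname rank_and_t_tests
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2L)
  d <- post - pre
  d <- d[d != 0]  # Wilcoxon's rule: zero differences carry no sign
  if (length(d) == 0L) stop("all paired differences are zero")
  exact <- length(d) <= 8L && !anyDuplicated(abs(d))
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = FALSE))
  .test_result("wilcoxon_signed_rank", res$statistic, res$p.value, length(d))
}

#' @rdname rank_and_t_tests
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2L)
  if (stats::sd(post - pre) == 0) stop("degenerate paired differences")
  res <- stats::t.test(post, pre, paired = TRUE)
  .test_result("paired_t", res$statistic, res$p.value, length(pre))
}

#' @rdname rank_and_t_tests
#' @export
independent_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) stop("degenerate samples")
  res <- stats::t.test(a, b)
  .test_result("independent_t", res$statistic, res$p.value,
               c(length(a), length(b)))
}

# ---- Trial-level analysis ---------------------------------------------

#' Analyse a scored two-arm trial
#'
#' Reproduces the outcome-analysis structure of a two-arm visual-training
#' trial, per region (defective hemifield, whole field):
#' \itemize{
#'   \item between-arm comparison of improved areas (Mann-Whitney U);
#'   \item within-arm pre/post MTD, paired t when the Shapiro-Wilk gate
#'     accepts normality of the paired differences, Wilcoxon signed-rank
#'     otherwise;
#'   \item between-arm comparison of MTD changes, independent t when both
#'     arms' changes pass the gate, Mann-Whitney otherwise;
#'   \item responder counts and percentages (strictly positive MTD
#'     change).
#' }
#'
#' @param outcomes Per-patient outcome data frame ([score_cohort()]).
#' @param arms Labels of the two arms, in (treatment, control) order.
#' @param gate_alpha Level of the normality gate.
#' @return A list of class `vfd_trial_report`.
#' @export
analyze_trial <- function(outcomes, arms = c("NV", "NV-C"), gate_alpha = 0.05) {
  stopifnot(is.data.frame(outcomes), length(arms) == 2L)
  g1 <- outcomes[outcomes$arm == arms[1], ]
  g2 <- outcomes[outcomes$arm == arms[2], ]
  if (nrow(g1) < 2L || nrow(g2) < 2L)
    stop("need at least 2 patients per arm")

  one_region <- function(suffix) {
    area_col <- paste0("improved_area_", if (suffix == "hemi") "hemi" else "whole", "_deg2")
    pre_col <- paste0("mtd_pre_", suffix)
    post_col <- paste0("mtd_post_", suffix)
    delta_col <- paste0("mtd_delta_", suffix)
    resp_col <- paste0("responder_", suffix)

    within <- lapply(list(g1, g2), function(g) {
      gate <- shapiro_wilk_gate(g[[delta_col]], alpha = gate_alpha)
      test <- if (gate == "parametric") paired_t(g[[pre_col]], g[[post_col]])
              else wilcoxon_signed_rank(g[[pre_col]], g[[post_col]])
      list(gate = gate, mtd_pre = mean(g[[pre_col]]),
           mtd_post = mean(g[[post_col]]), test = test)
    })
    names(within) <- arms

    gates <- vapply(list(g1, g2), function(g)
      shapiro_wilk_gate(g[[delta_col]], alpha = gate_alpha), character(1))
    between_delta <- if (all(gates == "parametric"))
      independent_t(g1[[delta_col]], g2[[delta_col]])
    else mann_whitney_u(g1[[delta_col]], g2[[delta_col]])

    responders <- data.frame(
      arm = arms,
      n = c(nrow(g1), nrow(g2)),
      responders = c(sum(g1[[resp_col]]), sum(g2[[resp_col]])),
      pct = 100 * c(sum(g1[[resp_col]]) / nrow(g1), sum(g2[[resp_col]]) / nrow(g2))
    )

    list(
      improved_area = list(
        mean = stats::setNames(c(mean(g1[[area_col]]), mean(g2[[area_col]])), arms),
        sd = stats::setNames(c(stats::sd(g1[[area_col]]), stats::sd(g2[[area_col]])), arms),
        between = mann_whitney_u(g1[[area_col]], g2[[area_col]])
      ),
      mtd_within = within,
      mtd_between_delta = between_delta,
      responders = responders
    )
  }

  structure(list(
    arms = arms,
    n = stats::setNames(as.list(c(nrow(g1), nrow(g2))), arms),
    regions = list(hemifield = one_region("hemi"), whole = one_region("whole"))
  ), class = "vfd_trial_report")
}

#' @export
print.vfd_trial_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}

#' Render a trial report
#'
#' @param report A `vfd_trial_report`.
#' @return `report_markdown()`: character vector of Markdown lines;
#'   `report_json()`: a JSON string.
#' @name report_render
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "vfd_trial_report"))
  lines <- c(
    "# Trial outcome report",
    "",
    sprintf("Arms: %s (n = %d) vs %s (n = %d)",
            report$arms[1], report$n[[1]], report$arms[2], report$n[[2]]),
    "")
  for (rn in names(report$regions)) {
    r <- report$regions[[rn]]
    lines <- c(lines,
      sprintf("## %s", rn), "",
      "| quantity | value | test | p |",
      "|---|---|---|---|",
      sprintf("| improved area (deg2) | %s | %s | %s |",
              paste(sprintf("%.1f", r$improved_area$mean), collapse = " vs "),
              r$improved_area$between$test_name,
              format_p(r$improved_area$between$p_value)),
      vapply(report$arms, function(a) {
        w <- r$mtd_within[[a]]
        sprintf("| MTD %s pre/post | %.2f / %.2f | %s | %s |",
                a, w$mtd_pre, w$mtd_post, w$test$test_name,
                format_p(w$test$p_value))
      }, character(1)),
      sprintf("| MTD change between arms | - | %s | %s |",
              r$mtd_between_delta$test_name,
              format_p(r$mtd_between_delta$p_value)),
      sprintf("| responders %s | %d/%d (%.1f%%) | - | - |",
              r$responders$arm, r$responders$responders, r$responders$n,
              r$responders$pct),
      "")
  }
  lines
}

#' @rdname report_render
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "vfd_trial_report"))
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                   force = TRUE, pretty = TRUE)
}

#' Participant-flow summary
#'
#' Completion arithmetic and the dropout comparison of a two-arm flow
#' diagram.
#'
#' @param randomized Length-2 vector of randomized counts per arm.
#' @param dropped Length-2 vector of dropouts per arm.
#' @param arms Arm labels.
#' @return List with `completed` per arm, `completion_pct` (overall,
#'   rounded to 1 decimal), and `dropout_test` (Fisher exact on dropped
#'   vs completed by arm).
#' @export
flow_summary <- function(randomized, dropped, arms = c("NV", "NV-C")) {
  stopifnot(length(randomized) == 2L, length(dropped) == 2L)
  if (any(randomized < 0) || any(dropped < 0)) stop("negative counts")
  if (any(dropped > randomized)) stop("dropped exceeds randomized")
  completed <- randomized - dropped
  tab <- rbind(c(dropped[1], completed[1]), c(dropped[2], completed[2]))
  list(
    arms = arms,
    randomized = stats::setNames(randomized, arms),
    completed = stats::setNames(completed, arms),
    completion_pct = round(100 * sum(completed) / sum(randomized), 1),
    dropout_test = fisher_exact_2x2(tab)
  )
}
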