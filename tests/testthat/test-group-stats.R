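# Statistical battery: normality gate, exact nonparametric nulls against
# enumeration oracles, chi-squared conventions, partial Spearman, FDR, and
# the full comparison driver.

test_that("normality gate is calibrated and detects skew", {
  hits <- vapply(1:10, function(s) {
    set.seed(s); normality_test(rnorm(500))$p_value > 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
  set.seed(1)
  expect_lt(normality_test(rexp(500))$p_value, 0.01)
  expect_error(normality_test(c(1, 2)), "at least 4")
  expect_error(normality_test(rep(2, 10)), "zero-variance")
})

test_that("Mann-Whitney exact path reproduces hand-enumerated p-values", {
  res <- compare_between(c(1, 2, 3), c(4, 5, 6), force_test = "mann-whitney")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)        # 2/20 arrangements as extreme

  same <- compare_between(c(1, 2, 3), c(1, 2, 3), force_test = "mann-whitney")
  expect_equal(same$p_value, 1)

  # property: exact path equals full enumeration for all combined n <= 8
  for (trial in 1:10) {
    set.seed(trial + 50)
    n_a <- sample(3:4, 1); n_b <- sample(3:4, 1)
    a <- sample(seq_len(20), n_a); b <- sample(setdiff(seq_len(20), a), n_b)
    res <- compare_between(a, b, force_test = "mann-whitney")
    expect_equal(res$p_value, enumerate_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("between-group type-I error is calibrated at the study arm sizes", {
  alpha_hits <- 0
  n_sim <- 1000
  for (i in seq_len(n_sim)) {
    set.seed(i)
    p <- compare_between(rnorm(41), rnorm(34),
                         force_test = "mann-whitney")$p_value
    alpha_hits <- alpha_hits + (p < 0.05)
  }
  expect_gte(alpha_hits / n_sim, 0.03)
  expect_lte(alpha_hits / n_sim, 0.07)
})

test_that("Wilcoxon signed-rank matches its exact null and handles zeros", {
  res <- compare_within(c(0, 0, 0), c(1, 2, 3))
  expect_equal(res$p_value, 0.25)        # 2 * (1/2^3)

  deg <- compare_within(c(1, 2, 3), c(1, 2, 3))
  expect_equal(deg$p_value, 1)
  expect_match(deg$flag, "degenerate")

  # exact null distribution sums to one and matches the enumeration oracle
  for (n in c(5, 8, 10)) {
    null_tab <- enumerate_signrank_null(n)
    expect_equal(sum(null_tab), 1)
    vs <- as.numeric(names(null_tab))
    expect_equal(as.numeric(null_tab),
                 dsignrank(vs, n), tolerance = 1e-12)
  }
})

test_that("paired type-I error is calibrated at the LID arm size", {
  hits <- 0
  n_sim <- 1000
  for (i in seq_len(n_sim)) {
    set.seed(i + 4000)
    off <- rnorm(41); on <- off + rnorm(41)
    hits <- hits + (compare_within(off, on)$p_value < 0.05)
  }
  expect_gte(hits / n_sim, 0.03)
  expect_lte(hits / n_sim, 0.07)
})

test_that("chi-squared reproduces the demographic worked example", {
  res <- chi_square_counts(rbind(c(22, 19), c(21, 13)))
  expect_equal(res$df, 1)
  expect_lt(abs(res$p_value - 0.49), 0.02)

  flat <- chi_square_counts(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  extreme <- chi_square_counts(rbind(c(20, 0), c(0, 20)))
  expect_lt(extreme$p_value, 1e-8)
  expect_error(chi_square_counts(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("partial Spearman is rank-invariant and collapses under collinearity", {
  set.seed(6)
  x <- rnorm(30)
  res <- partial_spearman(x, x^3)
  expect_equal(res$rho, 1)

  # no covariates equals plain Spearman exactly
  y <- rnorm(30)
  expect_equal(partial_spearman(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)

  col <- partial_spearman(x, y, covariates = data.frame(c1 = x))
  expect_lt(abs(col$rho), 0.3)

  expect_error(partial_spearman(rep(1, 30), y), "constant")
})

test_that("severity link is recovered by adjusted correlation at study size", {
  hits <- 0
  for (s in 1:10) {
    cfg <- scenario_config(seed = 900 + s)
    coh <- simulate_cohort(cfg, timecourses = FALSE)
    lid <- coh$subjects[coh$subjects$group == "LID", ]
    occ <- coh$ground_truth$occupancy_on_target[lid$id]
    res <- partial_spearman(lid$aims, occ,
                            lid[, c("age_at_onset", "ledd", "disease_duration")])
    hits <- hits + (res$rho > 0 && res$p_value < 0.05)
  }
  expect_gte(hits, 8)
})

test_that("BH adjustment matches its step-up definition", {
  adj <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_equal(adj$adjusted, rep(0.05, 5))
  expect_true(all(adj$significant))

  single <- fdr_adjust(0.03)
  expect_equal(single$adjusted, 0.03)
  expect_false(any(fdr_adjust(rep(1, 6))$significant))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")

  # brute-force equivalence of the rejection set
  for (trial in 1:20) {
    set.seed(trial)
    p <- runif(sample(3:9, 1))
    adj <- fdr_adjust(p, alpha = 0.05)
    ord <- order(p)
    thresh <- which(p[ord] <= 0.05 * seq_along(p) / length(p))
    reject <- logical(length(p))
    if (length(thresh)) reject[ord[seq_len(max(thresh))]] <- TRUE
    expect_equal(adj$significant, reject)
    expect_true(all(diff(adj$adjusted[ord]) >= -1e-12))
  }
})

test_that("the full battery finds planted contrasts and reports structure", {
  cfg <- scenario_config(seed = 321)
  coh <- simulate_cohort(cfg, timecourses = FALSE)
  met <- cohort_temporal_metrics(coh$ground_truth$paths, coh$session_table,
                                 cfg$n_states)
  res <- run_full_comparison(met, coh$subjects)
  expect_equal(nrow(res$comparisons), (2 * 5 + 1) * 4)
  expect_true(all(res$comparisons$p_value >= 0 & res$comparisons$p_value <= 1))
  # planted LID@ON state-1 occupancy elevation
  s1 <- subset(res$comparisons, metric == "fractional_windows" & state == 1 &
                 contrast == "LID vs NoLID @ ON")
  expect_lt(s1$p_value, 0.05)
  # no planted OFF differences: state-1 OFF contrast should not be tiny
  s1off <- subset(res$comparisons, metric == "fractional_windows" & state == 1 &
                    contrast == "LID vs NoLID @ OFF")
  expect_gt(s1off$p_value, 0.001)
  # severity correlation rows: 2 metrics x 5 states + transitions
  expect_equal(nrow(res$correlations), 11)
  sev <- subset(res$correlations, metric == "fractional_windows" & state == 2)
  expect_gt(sev$rho, 0)

  # a subject missing one phase is dropped with a warning
  met2 <- met[!(met$subject == met$subject[1] & met$phase == "ON"), ]
  expect_warning(run_full_comparison(met2, coh$subjects), "both phases")
})

test_that("null scenario keeps the pre-FDR hit rate near its nominal level", {
  cfg <- scenario_config(seed = 555)
  # erase all planted group/phase structure
  cfg$dwell_mean_windows[] <- 80
  cfg$occupancy_logits[] <- log(1 / cfg$n_states)
  coh <- simulate_cohort(cfg, timecourses = FALSE)
  met <- cohort_temporal_metrics(coh$ground_truth$paths, coh$session_table,
                                 cfg$n_states)
  res <- run_full_comparison(met, coh$subjects)
  expect_lte(mean(res$comparisons$p_value < 0.05), 0.10)
})
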