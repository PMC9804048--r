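# The statistical battery: normality gate, between-group and paired
# nonparametric tests, chi-squared for categorical tables, covariate-adjusted
# Spearman correlation, and Benjamini-Hochberg FDR control.

#' Lilliefors-type normality test
#'
#' One-sample Kolmogorov-Smirnov test against a normal distribution with
#' parameters estimated from the sample.
#'
#' @param sample numeric vector, n >= 4.
#' @return list(statistic, p_value, n).
#' @export
normality_test <- function(sample) {
  x <- as.numeric(sample)
  if (length(x) < 4) stop("need at least 4 observations for the normality test")
  if (sd(x) == 0) stop("zero-variance sample")
  fit <- nortest::lillie.test(x)
  list(statistic = unname(fit$statistic), p_value = fit$p.value, n = length(x))
}

comparison_result <- function(test, statistic, p_value, n, flag = NA_character_) {
  list(test = test, statistic = unname(statistic), p_value = p_value,
       n = n, flag = flag)
}

#' Between-group comparison
#'
#' Two-sample t test when both arms pass the normality gate (p > alpha on
#' each), otherwise a two-sided Mann-Whitney U test (exact when the combined
#' sample is small and untied, normal approximation with tie correction
#' otherwise). `force_test` overrides the gate.
#'
#' @param a,b numeric vectors for the two arms.
#' @param force_test `NULL` (gate decides), `"t"`, or `"mann-whitney"`.
#' @param normality_alpha gate level.
#' @param exact_max combined-n bound for the exact Mann-Whitney null.
#' @return list(test, statistic, p_value, n = c(n_a, n_b), flag).
#' @export
compare_between <- function(a, b, force_test = NULL, normality_alpha = 0.05,
                            exact_max = 20L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty arm")
  test <- force_test
  if (is.null(test)) {
    normal <- length(a) >= 4 && length(b) >= 4 && sd(a) > 0 && sd(b) > 0 &&
      normality_test(a)$p_value > normality_alpha &&
      normality_test(b)$p_value > normality_alpha
    test <- if (normal) "t" else "mann-whitney"
  }
  if (test == "t") {
    fit <- t.test(a, b)
    comparison_result("t", fit$statistic, fit$p.value, c(length(a), length(b)))
  } else {
    exact <- (length(a) + length(b)) <= exact_max && !any(duplicated(c(a, b)))
    fit <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
    comparison_result("mann-whitney", fit$statistic, fit$p.value,
                      c(length(a), length(b)))
  }
}

#' Paired within-group comparison (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test on paired values; zero differences are
#' dropped, the exact null is used for small untied samples and the normal
#' approximation otherwise. All-zero differences yield a degenerate result
#' with p = 1.
#'
#' @param off,on paired numeric vectors of equal length.
#' @param exact_max bound on nonzero-difference count for the exact null.
#' @return list(test, statistic, p_value, n, flag).
#' @export
compare_within <- function(off, on, exact_max = 15L) {
  off <- as.numeric(off); on <- as.numeric(on)
  if (length(off) != length(on)) stop("paired samples must have equal length")
  d <- on - off
  nz <- d[d != 0]
  if (!length(nz))
    return(comparison_result("wilcoxon-signed-rank", 0, 1, length(off),
                             flag = "degenerate: all differences zero"))
  if (length(nz) < 3) stop("need at least 3 nonzero differences")
  exact <- length(nz) <= exact_max && !any(duplicated(abs(nz)))
  fit <- suppressWarnings(wilcox.test(on, off, paired = TRUE, exact = exact,
                                      correct = !exact))
  comparison_result("wilcoxon-signed-rank", fit$statistic, fit$p.value,
                    length(off))
}

#' Pearson chi-squared test of a 2x2 table
#'
#' Uncorrected (no continuity correction), df = 1.
#'
#' @param tab 2x2 count matrix.
#' @return list(statistic, p_value, df).
#' @export
chi_square_counts <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table")
  fit <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter))
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' Rank-transforms all variables, removes the covariate ranks from the ranks
#' of `x` and `y` by least squares, and correlates the residuals. The p-value
#' uses the t approximation with `n - 2 - n_covariates` degrees of freedom.
#' With no covariates this equals the plain Spearman coefficient.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame/matrix of covariates.
#' @return list(rho, p_value, n, df, flag).
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (sd(x) == 0 || sd(y) == 0) stop("constant variable")
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= ncov + 2) stop("too few observations for partial correlation")
  rx <- rank(x); ry <- rank(y)
  flag <- NA_character_
  if (ncov > 0) {
    C <- apply(as.matrix(covariates), 2, rank)
    rx <- residuals(lm(rx ~ C))
    ry <- residuals(lm(ry ~ C))
    if (sd(rx) < 1e-10 || sd(ry) < 1e-10) {
      return(list(rho = 0, p_value = 1, n = n, df = n - 2L - ncov,
                  flag = "degenerate: variable fully explained by covariates"))
    }
  }
  rho <- cor(rx, ry)
  df <- n - 2L - ncov
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * pt(-abs(tval), df)
  list(rho = rho, p_value = p, n = n, df = df, flag = flag)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with significance flags at `adjusted p <= alpha`.
#'
#' @param p vector of p-values.
#' @param alpha significance level.
#' @return list(adjusted, significant).
#' @export
fdr_adjust <- function(p, alpha = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, significant = adj <= alpha)
}

#' Full group-comparison battery over a temporal-metrics table
#'
#' Emits the four contrast families — LID vs NoLID within each phase
#' (Mann-Whitney by default via the normality gate) and OFF vs ON within each
#' group (Wilcoxon signed-rank) — for fractional windows and mean dwell time
#' per state, plus the number of transitions, and the severity (AIMS)
#' correlations in the LID group's ON phase (partial Spearman adjusting for
#' age at onset, LEDD and disease duration, FDR-corrected across states
#' within each metric).
#'
#' Subjects missing either phase are dropped from paired tests with a
#' warning.
#'
#' @param metrics long-form table from [cohort_temporal_metrics()].
#' @param subjects subject table with id, group, aims, age_at_onset, ledd,
#'   disease_duration.
#' @param alpha significance level for the FDR flags.
#' @param force_between optional forced test for between-group contrasts
#'   (see [compare_between()]).
#' @return list(comparisons, correlations) of data.frames.
#' @export
run_full_comparison <- function(metrics, subjects, alpha = 0.05,
                                force_between = NULL) {
  k <- max(metrics$state)
  complete <- vapply(split(metrics$phase, metrics$subject),
                     function(ph) all(c("OFF", "ON") %in% ph), logical(1))
  dropped <- names(complete)[!complete]
  if (length(dropped)) {
    warning("dropping subjects without both phases: ",
            paste(dropped, collapse = ", "))
    metrics <- metrics[!metrics$subject %in% dropped, ]
  }
  grab <- function(group, phase, state, var) {
    sel <- metrics$group == group & metrics$phase == phase &
      (is.na(state) | metrics$state == state)
    if (is.na(state)) {
      m <- metrics[sel & metrics$state == 1L, ]
    } else m <- metrics[sel, ]
    setNames(m[[var]], m$subject)
  }
  comp_rows <- list()
  add_comp <- function(metric, state, contrast, res) {
    comp_rows[[length(comp_rows) + 1L]] <<- data.frame(
      metric = metric, state = if (is.na(state)) NA_integer_ else state,
      contrast = contrast, test = res$test, statistic = res$statistic,
      p_value = res$p_value, n = paste(res$n, collapse = "/"),
      flag = res$flag, stringsAsFactors = FALSE)
  }
  specs <- expand.grid(metric = c("fractional_windows", "mean_dwell"),
                       state = seq_len(k), stringsAsFactors = FALSE)
  specs <- rbind(specs, data.frame(metric = "n_transitions", state = NA_integer_))
  degenerate <- function(e) comparison_result("degenerate", NA_real_,
                                              NA_real_, NA_integer_,
                                              flag = conditionMessage(e))
  for (i in seq_len(nrow(specs))) {
    met <- specs$metric[i]; s <- specs$state[i]
    for (ph in c("OFF", "ON")) {
      res <- tryCatch(
        compare_between(grab("LID", ph, s, met), grab("NoLID", ph, s, met),
                        force_test = force_between),
        error = degenerate)
      add_comp(met, s, paste0("LID vs NoLID @ ", ph), res)
    }
    for (g in c("LID", "NoLID")) {
      off <- grab(g, "OFF", s, met); on <- grab(g, "ON", s, met)
      on <- on[names(off)]
      res <- tryCatch(compare_within(off, on), error = degenerate)
      add_comp(met, s, paste0("OFF vs ON @ ", g), res)
    }
  }
  comparisons <- do.call(rbind, comp_rows)

  lid <- subjects[subjects$group == "LID" & subjects$id %in% metrics$subject, ]
  covars <- lid[, c("age_at_onset", "ledd", "disease_duration")]
  cor_rows <- list()
  safe_spearman <- function(x, y, covariates) {
    tryCatch(partial_spearman(x, y, covariates),
             error = function(e) list(rho = NA_real_, p_value = NA_real_,
                                      n = length(x), flag = conditionMessage(e)))
  }
  for (met in c("fractional_windows", "mean_dwell")) {
    res_list <- lapply(seq_len(k), function(s) {
      y <- grab("LID", "ON", s, met)[lid$id]
      safe_spearman(lid$aims, y, covars)
    })
    pvec <- vapply(res_list, `[[`, numeric(1), "p_value")
    adj <- list(adjusted = rep(NA_real_, k), significant = rep(NA, k))
    if (any(!is.na(pvec))) {
      sub <- fdr_adjust(pvec[!is.na(pvec)], alpha)
      adj$adjusted[!is.na(pvec)] <- sub$adjusted
      adj$significant[!is.na(pvec)] <- sub$significant
    }
    for (s in seq_len(k)) {
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        metric = met, state = s, rho = res_list[[s]]$rho,
        p_value = res_list[[s]]$p_value, p_adjusted = adj$adjusted[s],
        significant = adj$significant[s], n = res_list[[s]]$n,
        covariates = "age_at_onset+ledd+disease_duration",
        stringsAsFactors = FALSE)
    }
  }
  tr <- grab("LID", "ON", NA, "n_transitions")[lid$id]
  res_tr <- safe_spearman(lid$aims, tr, covars)
  cor_rows[[length(cor_rows) + 1L]] <- data.frame(
    metric = "n_transitions", state = NA_integer_, rho = res_tr$rho,
    p_value = res_tr$p_value, p_adjusted = res_tr$p_value,
    significant = res_tr$p_value <= alpha, n = res_tr$n,
    covariates = "age_at_onset+ledd+disease_duration",
    stringsAsFactors = FALSE)
  list(comparisons = comparisons, correlations = do.call(rbind, cor_rows))
}
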