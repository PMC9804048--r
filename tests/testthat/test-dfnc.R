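# Taper construction, windowed regularized FC, penalty selection, L1 k-means
# against a brute-force oracle, elbow selection, and top-connection
# extraction.

test_that("taper is symmetric, mass-preserving and degenerates to a rectangle", {
  w <- make_taper(window_spec(30L, 3, 1L))
  expect_equal(as.numeric(w), rev(as.numeric(w)), tolerance = 1e-12)
  expect_lt(abs(sum(w) - 30) / 30, 0.01)
  expect_equal(which.max(w), length(w) %/% 2 + length(w) %% 2, tolerance = 1)
  expect_true(all(w > 0))

  w0 <- make_taper(window_spec(30L, 1e-6, 1L))
  inner <- w0[(attr(w0, "pad") + 1):(attr(w0, "pad") + 30)]
  expect_equal(unname(inner), rep(1, 30), tolerance = 1e-10)
})

test_that("window count identity holds over a grid of (T, width, step)", {
  for (T_ in c(60, 127, 230, 500)) for (w in c(20, 30, 45)) for (s in c(1, 2, 5)) {
    expect_equal(count_windows(T_, w, s), floor((T_ - w) / s) + 1)
  }
  cfg <- small_scenario(n_timepoints = 230L)
  tc <- simulate_timecourses(simulate_state_path(cfg, "LID", "OFF", 1), cfg, 2)
  wfc <- windowed_fc(tc, window_spec(30L, 3, 1L), penalty = 0.1)
  expect_equal(nrow(wfc$z), 201)
  expect_equal(ncol(wfc$z), choose(ncol(tc), 2))
})

test_that("identical components hit the positive clamp in every window", {
  set.seed(2)
  x <- rnorm(120)
  tc <- cbind(x, x, rnorm(120))
  wfc <- windowed_fc(tc, window_spec(30L, 3, 1L), penalty = 0)
  expect_equal(unname(wfc$z[, "1_2"]), rep(atanh(1 - 1e-7), nrow(wfc$z)))
})

test_that("stationary data yields windows that vary less than pairs differ", {
  cfg <- scenario_config(n_states = 2L, n_timepoints = 230L)
  cfg$dwell_mean_windows["LID", "OFF", 1] <- 1e6
  cfg$occupancy_logits["LID", "OFF", ] <- c(20, -20)
  path <- simulate_state_path(cfg, "LID", "OFF", seed = 4)
  expect_true(all(path == 1L))
  tc <- simulate_timecourses(path, cfg, seed = 5)
  wfc <- windowed_fc(tc, penalty = 0.1)
  across_window_sd <- mean(apply(wfc$z, 2, sd))
  across_pair_spread <- sd(colMeans(wfc$z))
  expect_lt(across_window_sd, across_pair_spread)
})

test_that("unpenalized windowed FC equals the tapered sample correlation", {
  set.seed(7)
  tc <- matrix(rnorm(100 * 4), 100, 4)
  spec <- window_spec(30L, 3, 1L)
  wfc <- windowed_fc(tc, spec, penalty = 0)
  taper <- make_taper(spec)
  S <- dfncstates:::window_cov_cpp(tc, 1L, attr(taper, "pad"), as.numeric(taper))
  r <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  expect_equal(unname(wfc$z[1, "1_2"]), atanh(r), tolerance = 1e-6)
})

test_that("penalty selection returns singletons directly and is deterministic", {
  cfg <- small_scenario()
  tc <- simulate_timecourses(simulate_state_path(cfg, "LID", "OFF", 1), cfg, 2)
  expect_equal(select_glasso_penalty(tc, config = glasso_config(penalty_grid = 0.3)),
               0.3)
  cfgg <- glasso_config(penalty_grid = c(0.02, 0.1, 0.5), n_repetitions = 10L)
  p1 <- select_glasso_penalty(tc, config = cfgg, seed = 9)
  p2 <- select_glasso_penalty(tc, config = cfgg, seed = 9)
  expect_identical(as.numeric(p1), as.numeric(p2))
})

test_that("penalty selection drives truly-absent edges toward zero", {
  # diagonal truth: selected penalty should leave off-diagonals tiny
  cfg <- scenario_config(n_states = 2L, n_timepoints = 400L,
                         state_covariances = list(diag(22), diag(22)))
  tc <- simulate_timecourses(simulate_state_path(cfg, "LID", "OFF", 3), cfg, 4)
  pen <- select_glasso_penalty(tc, config = glasso_config(
    penalty_grid = c(0.01, 0.05, 0.15, 0.4), n_repetitions = 20L), seed = 2)
  wfc <- windowed_fc(tc, penalty = as.numeric(pen))
  expect_lt(median(abs(wfc$z)), 0.05)
})

test_that("L1 k-means matches brute-force partitions and known medians", {
  # median centroid for a single cluster
  km1 <- cluster_states(matrix(c(1, 2, 9), 3, 1), 1, n_restarts = 3, seed = 1)
  expect_equal(unname(km1$centroids[1, 1]), 2)
  expect_equal(km1$cost, 8)

  # separable clouds are recovered exactly
  set.seed(12)
  cloud <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
                 matrix(rnorm(40, 5, 0.2), 20, 2))
  km2 <- cluster_states(cloud, 2, n_restarts = 10, seed = 3)
  lab <- km2$assignments$state
  expect_true(all(lab[1:20] == lab[1]) && all(lab[21:40] == lab[21]) &&
                lab[1] != lab[21])

  # exhaustive-minimum comparison on small random sets
  for (trial in 1:6) {
    set.seed(trial)
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    km <- cluster_states(x, k, n_restarts = 60, seed = trial)
    expect_equal(km$cost, brute_force_l1_cost(x, k), tolerance = 1e-8)
  }
})

test_that("k-means cost decreases monotonically and states sort by occurrence", {
  set.seed(8)
  x <- matrix(rnorm(400 * 6), 400, 6)
  km <- cluster_states(x, 3, n_restarts = 5, seed = 2)
  expect_true(all(diff(km$cost_trace) <= 1e-9))
  expect_true(all(diff(km$occurrence$count) <= 0))
  expect_equal(sum(km$occurrence$percentage), 100)
  expect_error(cluster_states(x[1:2, ], 3, seed = 1), "exceeds")
})

test_that("relabeling sessions does not change the fitted centroids", {
  cfg <- small_scenario(n_states = 3L, n_subjects = c(LID = 2L, NoLID = 2L))
  coh <- simulate_cohort(cfg)
  wfc <- lapply(coh$sessions, function(s)
    windowed_fc(s$timecourses, penalty = 0.1))
  m1 <- cluster_states(wfc, 3, n_restarts = 10, seed = 5)
  m2 <- cluster_states(rev(wfc), 3, n_restarts = 10, seed = 5)
  agree <- adjusted_rand_index(
    m1$assignments$state[order(m1$assignments$session, m1$assignments$window)],
    m2$assignments$state[order(m2$assignments$session, m2$assignments$window)])
  expect_equal(agree, 1)
})

test_that("elbow selection needs three candidates and flags flat curves", {
  expect_error(elbow_select_k(matrix(rnorm(100), 50, 2), k_range = 2:3),
               "at least 3")
  # strictly linear validity curve: constant drops, no bend
  expect_error(elbow_from_validity(seq(1, 0.3, length.out = 8), 2:9), "elbow")
  # a clean bend at k = 5 is found
  curve <- c(1, 0.8, 0.6, 0.4, 0.39, 0.38, 0.375, 0.37)
  expect_equal(elbow_from_validity(curve, 2:9)$selected_k, 5)
})

test_that("top connections follow the ceiling rule and tag signs", {
  v <- numeric(choose(22, 2))
  v[1:20] <- seq(1, 0.05, length.out = 20) * rep(c(1, -1), 10)
  tc <- top_connections(v, 0.05)
  expect_equal(nrow(tc), 12)          # ceil(0.05 * 231)
  expect_equal(tc$value[1], 1)
  expect_setequal(unique(tc$sign), c("positive", "negative"))
  expect_equal(nrow(top_connections(v, 1)), 231)
  z <- top_connections(numeric(10), 0.5, n_components = 5)
  expect_true(all(z$sign == "zero"))
})
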