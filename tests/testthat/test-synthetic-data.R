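# Synthetic cohort generator: configuration validation, semi-Markov path
# statistics, state-conditional sampling, and cohort-level planted structure.

test_that("configuration validation rejects degenerate designs", {
  expect_error(scenario_config(n_states = 1L), "n_states")
  expect_error(scenario_config(network_partition = c("A", "B")), "partition")
  bad_cov <- replicate(5, diag(22), simplify = FALSE)
  bad_cov[[2]][1, 2] <- 0.5          # asymmetric
  expect_error(scenario_config(state_covariances = bad_cov), "symmetric")
  nonpd <- replicate(5, {m <- matrix(0.99, 22, 22); diag(m) <- 1; m},
                     simplify = FALSE)
  nonpd[[1]][1, 2] <- -0.99          # breaks positive-definiteness
  nonpd[[1]][2, 1] <- -0.99
  expect_error(scenario_config(state_covariances = nonpd), "positive-definite")
})

test_that("state covariances are valid correlation matrices for any k", {
  part <- default_network_partition()
  for (k in c(2L, 3L, 5L, 7L)) {
    covs <- make_state_covariances(part, k)
    expect_length(covs, k)
    for (S in covs) {
      expect_equal(diag(S), rep(1, 22))
      expect_equal(S, t(S))
      expect_gt(min(eigen(S, TRUE, TRUE)$values), 0)
    }
  }
})

test_that("degenerate limit: overwhelming preference and dwell pin the path", {
  cfg <- scenario_config(n_states = 2L)
  cfg$dwell_mean_windows["LID", "OFF", 1] <- 1e6
  cfg$occupancy_logits["LID", "OFF", ] <- c(20, -20)
  path <- simulate_state_path(cfg, "LID", "OFF", seed = 5)
  expect_equal(path, rep(1L, cfg$n_timepoints))
})

test_that("completed run lengths match configured dwell means within 10%", {
  # long sessions so that completed runs sample the generative run-length
  # distribution without the length bias a 230-timepoint window imposes
  cfg <- scenario_config(n_timepoints = 20000L, seed = 7)
  d <- cfg$dwell_mean_windows["LID", "ON", ]
  runs <- vector("list", cfg$n_states)
  for (i in seq_len(60)) {
    path <- simulate_state_path(cfg, "LID", "ON", seed = 10000 + i)
    r <- rle(path)
    keep <- seq_len(length(r$lengths) - 1L)      # drop censored terminal run
    for (s in seq_len(cfg$n_states)) {
      sel <- keep[r$values[keep] == s]
      runs[[s]] <- c(runs[[s]], r$lengths[sel])
    }
  }
  for (s in seq_len(cfg$n_states)) {
    expect_gt(length(runs[[s]]), 50)
    expect_lt(abs(mean(runs[[s]]) - d[s]) / d[s], 0.10)
  }
})

test_that("empirical occupancy matches the closed-form stationary occupancy", {
  cfg <- scenario_config(seed = 3)
  occ_expected <- stationary_occupancy(cfg, "NoLID", "ON")
  counts <- numeric(cfg$n_states)
  for (i in seq_len(600)) {
    path <- simulate_state_path(cfg, "NoLID", "ON", seed = 20000 + i)
    counts <- counts + tabulate(path, cfg$n_states)
  }
  occ_emp <- counts / sum(counts)
  expect_lt(max(abs(occ_emp - occ_expected)), 0.02)
})

test_that("time courses follow the state-conditional covariance", {
  # identity covariances: off-diagonal sample correlations stay near 0
  cfg <- scenario_config(state_covariances = replicate(5, diag(22),
                                                       simplify = FALSE))
  rs <- vapply(1:8, function(seed) {
    path <- simulate_state_path(cfg, "LID", "OFF", seed = seed)
    tc <- simulate_timecourses(path, cfg, seed = 100 + seed)
    cor(tc[, 1], tc[, 2])
  }, numeric(1))
  expect_lt(max(abs(rs)), 0.2)       # each within sampling noise at T = 230
  expect_lt(mean(abs(rs)), 0.1)
  # single state with a planted r12 = 0.8
  S <- diag(22); S[1, 2] <- S[2, 1] <- 0.8
  cfg2 <- scenario_config(n_states = 2L,
                          state_covariances = list(S, diag(22)))
  cfg2$dwell_mean_windows["LID", "OFF", 1] <- 1e6
  cfg2$occupancy_logits["LID", "OFF", ] <- c(20, -20)
  path <- simulate_state_path(cfg2, "LID", "OFF", seed = 11)
  tc <- simulate_timecourses(path, cfg2, seed = 12)
  expect_lt(abs(cor(tc[, 1], tc[, 2]) - 0.8), 0.1)
})

test_that("time-course generation is deterministic in the seed", {
  cfg <- small_scenario()
  path <- simulate_state_path(cfg, "LID", "ON", seed = 1)
  expect_identical(simulate_timecourses(path, cfg, seed = 5),
                   simulate_timecourses(path, cfg, seed = 5))
  expect_false(identical(simulate_timecourses(path, cfg, seed = 5),
                         simulate_timecourses(path, cfg, seed = 6)))
})

test_that("cohorts pair phases, share subject effects and plant severity", {
  cfg <- small_scenario(n_states = 5L, n_subjects = c(LID = 4L, NoLID = 3L))
  coh <- simulate_cohort(cfg, timecourses = FALSE)
  expect_equal(nrow(coh$subjects), 7)
  expect_equal(nrow(coh$session_table), 14)
  for (id in coh$subjects$id)
    expect_setequal(coh$session_table$phase[coh$session_table$subject == id],
                    c("OFF", "ON"))
  expect_true(all(!is.na(coh$subjects$aims[coh$subjects$group == "LID"])))
  expect_true(all(is.na(coh$subjects$aims[coh$subjects$group == "NoLID"])))
  expect_true(all(lengths(coh$ground_truth$paths) == cfg$n_timepoints))
})

test_that("severity link: null slope gives no correlation, strong link a high one", {
  base <- scenario_config(n_subjects = c(LID = 250L, NoLID = 2L), seed = 31,
                          severity_link = list(target_state = 2L, slope = 0,
                                               noise_sd = 4, intercept = 9))
  coh <- simulate_cohort(base, timecourses = FALSE)
  lid <- coh$subjects$group == "LID"
  occ <- coh$ground_truth$occupancy_on_target[coh$subjects$id[lid]]
  expect_lt(abs(cor(coh$subjects$aims[lid], occ, method = "spearman")), 0.12)

  strong <- scenario_config(n_subjects = c(LID = 250L, NoLID = 2L), seed = 32,
                            severity_link = list(target_state = 2L, slope = 60,
                                                 noise_sd = 0.5, intercept = 0.3))
  coh2 <- simulate_cohort(strong, timecourses = FALSE)
  lid2 <- coh2$subjects$group == "LID"
  occ2 <- coh2$ground_truth$occupancy_on_target[coh2$subjects$id[lid2]]
  expect_gt(cor(coh2$subjects$aims[lid2], occ2, method = "spearman"), 0.8)
})

test_that("planted motion violators are flagged downstream at the planted rate", {
  cfg <- small_scenario(n_subjects = c(LID = 50L, NoLID = 50L),
                        motion_model = list(translation_sd = 0.02,
                                            rotation_sd = 4e-4,
                                            violator_scale = 8,
                                            violation_frac = 0.2),
                        seed = 77)
  coh <- simulate_cohort(cfg, timecourses = FALSE)
  rep <- qc_report(coh)
  flagged <- unique(rep$subject[rep$decision == "exclude"])
  expect_equal(sort(flagged),
               sort(coh$subjects$id[coh$subjects$motion_violator]))
  expect_gt(length(flagged), 100 * 0.2 - 12)    # ~binomial(100, .2)
  expect_lt(length(flagged), 100 * 0.2 + 12)
})

test_that("written cohorts are byte-identical under a fixed seed", {
  cfg <- small_scenario(n_subjects = c(LID = 2L, NoLID = 2L))
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 4)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("voxel mixing is exactly invertible without noise", {
  cfg <- small_scenario(n_components = 4L,
                        network_partition = c("A", "A", "B", "B"))
  path <- simulate_state_path(cfg, "LID", "OFF", seed = 2)
  tc <- simulate_timecourses(path, cfg, seed = 3)
  maps <- make_spatial_maps(4L, dims = c(8L, 8L, 4L), seed = 4)
  vox <- simulate_voxel_data(tc, maps, snr = Inf)
  rec <- vox %*% t(maps) %*% solve(maps %*% t(maps))
  expect_lt(max(abs(rec - unclass(tc))), 1e-8)
  expect_error(simulate_voxel_data(tc, maps[1:3, ]), "mismatch")
})
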