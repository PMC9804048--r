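# Shared fixtures: small scenarios for fast unit tests, and independent
# brute-force oracles for clustering and the nonparametric exact nulls.

small_scenario <- function(n_states = 3L, n_subjects = c(LID = 3L, NoLID = 3L),
                           n_timepoints = 120L, seed = 42L, ...) {
  scenario_config(n_states = n_states, n_subjects = n_subjects,
                  n_timepoints = n_timepoints, seed = seed, ...)
}

# exhaustive minimum L1 k-means cost over all k-partitions of the rows of x
brute_force_l1_cost <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  assign_next <- function(labels, i, used) {
    if (i > n) {
      if (used < k) return()
      cost <- 0
      for (c in seq_len(k)) {
        rows <- x[labels == c, , drop = FALSE]
        if (nrow(rows) == 0) return()
        med <- apply(rows, 2, median)
        cost <- cost + sum(abs(sweep(rows, 2, med)))
      }
      best <<- min(best, cost)
      return()
    }
    for (c in seq_len(min(used + 1L, k))) {
      labels[i] <- c
      assign_next(labels, i + 1L, max(used, c))
    }
  }
  assign_next(integer(n), 1L, 0L)
  best
}

# exact two-sided Mann-Whitney p by enumeration of all group arrangements
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_stat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(seq_len(n_a))
  combos <- combn(length(pooled), n_a)
  us <- apply(combos, 2, u_stat)
  mu <- n_a * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# exact Wilcoxon signed-rank null: distribution of V over all sign patterns
enumerate_signrank_null <- function(n) {
  r <- seq_len(n)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  table(vs) / 2^n
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
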