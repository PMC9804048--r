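# Tapered sliding-window regularized connectivity and k-means (city-block)
# state identification.

#' Sliding-window specification
#'
#' @param width_tr window width, TR (timepoints).
#' @param gaussian_sigma_tr standard deviation of the Gaussian taper, TR.
#' @param step_tr step between consecutive windows, TR.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(width_tr = 30L, gaussian_sigma_tr = 3,
                        step_tr = 1L) {
  stopifnot(width_tr >= 2, gaussian_sigma_tr > 0, step_tr >= 1)
  structure(list(width_tr = as.integer(width_tr),
                 gaussian_sigma_tr = gaussian_sigma_tr,
                 step_tr = as.integer(step_tr)),
            class = "window_spec")
}

#' Graphical-LASSO configuration
#'
#' @param penalty_grid candidate L1 penalties; a single value is used as-is
#'   without cross-validation.
#' @param n_repetitions random train/held-out window splits for penalty
#'   selection.
#' @param cv_fraction fraction of windows held out per split.
#' @return object of class `glasso_config`.
#' @export
glasso_config <- function(penalty_grid = exp(seq(log(0.01), log(1), length.out = 8)),
                          n_repetitions = 100L, cv_fraction = 0.2) {
  stopifnot(length(penalty_grid) >= 1, all(penalty_grid >= 0),
            n_repetitions >= 1, cv_fraction > 0, cv_fraction < 1)
  structure(list(penalty_grid = penalty_grid,
                 n_repetitions = as.integer(n_repetitions),
                 cv_fraction = cv_fraction),
            class = "glasso_config")
}

#' Tapered window weights
#'
#' A rectangle of `width_tr` ones convolved with a unit-mass discrete Gaussian
#' kernel (sigma = `gaussian_sigma_tr`, truncated at 3.5 sigma), giving a
#' symmetric taper whose weights sum to `width_tr` and whose support extends
#' `pad` timepoints beyond each side of the nominal window span.
#'
#' @param spec a [window_spec()].
#' @return numeric weight vector with attribute `pad`.
#' @export
make_taper <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  pad <- max(1L, as.integer(ceiling(3.5 * spec$gaussian_sigma_tr)))
  g <- dnorm(seq(-pad, pad), sd = spec$gaussian_sigma_tr)
  g <- g / sum(g)
  w <- numeric(spec$width_tr + 2L * pad)
  for (u in seq_len(spec$width_tr)) {
    w[u:(u + 2L * pad)] <- w[u:(u + 2L * pad)] + g
  }
  attr(w, "pad") <- pad
  w
}

#' Sparse inverse-covariance (graphical LASSO) estimate
#'
#' Friedman-style block coordinate descent. At `rho = 0` the unpenalized
#' sample covariance is returned unchanged.
#'
#' @param S sample covariance matrix.
#' @param rho L1 penalty.
#' @param max_sweeps,tol convergence controls.
#' @return list(w = regularized covariance, theta = precision matrix).
#' @export
graphical_lasso <- function(S, rho, max_sweeps = 100L, tol = 1e-4) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), rho >= 0)
  glasso_cpp(S, rho, max_sweeps, tol)
}

#' Windowed regularized functional connectivity of one session
#'
#' For each window position: tapered weighted covariance, graphical-LASSO
#' regularization at the session's penalty, conversion to correlation, and
#' Fisher z of the vectorized upper triangle.
#'
#' @param tc `T x n_components` time-course matrix.
#' @param spec a [window_spec()].
#' @param penalty L1 penalty; either a number, or a [glasso_config()] whose
#'   grid is resolved by [select_glasso_penalty()] (single-value grids are
#'   used directly).
#' @param seed seed for penalty selection splits.
#' @return object of class `windowed_fc`: `z` (`n_windows x n_pairs`),
#'   `penalty`, `spec`, pair labels.
#' @export
windowed_fc <- function(tc, spec = window_spec(), penalty = 0.1, seed = 1L) {
  X <- unclass(tc)
  T_ <- nrow(X)
  p <- ncol(X)
  if (T_ < spec$width_tr) stop("session shorter than window width")
  if (inherits(penalty, "glasso_config")) {
    penalty <- if (length(penalty$penalty_grid) == 1L) penalty$penalty_grid
      else select_glasso_penalty(tc, spec, penalty, seed = seed)
  }
  taper <- make_taper(spec)
  Z <- windowed_fc_cpp(X, spec$width_tr, spec$step_tr, attr(taper, "pad"),
                       as.numeric(taper), penalty)
  if (any(!is.finite(Z)))
    stop("non-finite windowed connectivity (zero-variance component within a window?)")
  colnames(Z) <- pair_labels(p)
  structure(list(z = Z, penalty = penalty, spec = spec,
                 n_components = p,
                 tr_seconds = attr(tc, "tr_seconds")),
            class = "windowed_fc")
}

#' Select the graphical-LASSO penalty for one session
#'
#' Repeatedly splits the session's windows into train/held-out sets; each
#' repetition fits the graphical LASSO to one randomly drawn train-window
#' covariance (the single-window setting in which the penalty is actually
#' used) and scores it by Gaussian log-likelihood against the mean held-out
#' covariance. Returns the grid value with the highest mean held-out
#' log-likelihood (ties broken toward the smaller penalty).
#'
#' @param tc `T x n_components` time-course matrix.
#' @param spec a [window_spec()].
#' @param config a [glasso_config()].
#' @param seed split seed (deterministic contract).
#' @return selected penalty (scalar). The score curve is attached as
#'   attribute `scores`.
#' @export
select_glasso_penalty <- function(tc, spec = window_spec(),
                                  config = glasso_config(), seed = 1L) {
  grid <- config$penalty_grid
  if (length(grid) == 1L) return(grid)
  X <- unclass(tc)
  taper <- make_taper(spec)
  pad <- attr(taper, "pad")
  n_win <- count_windows(nrow(X), spec$width_tr, spec$step_tr)
  if (n_win < 2) stop("need at least 2 windows for penalty selection")
  covs <- lapply(seq_len(n_win), function(i) {
    window_cov_cpp(X, (i - 1L) * spec$step_tr + 1L, pad, as.numeric(taper))
  })
  n_hold <- max(1L, round(config$cv_fraction * n_win))
  scores <- matrix(0, config$n_repetitions, length(grid))
  with_seed(seed, {
    for (r in seq_len(config$n_repetitions)) {
      hold <- sample.int(n_win, n_hold)
      S_tr <- covs[[sample(setdiff(seq_len(n_win), hold), 1)]]
      S_te <- Reduce(`+`, covs[hold]) / n_hold
      for (j in seq_along(grid)) {
        fit <- glasso_cpp(S_tr, grid[j])
        scores[r, j] <- gauss_loglik_cpp(fit$theta, S_te)
      }
    }
  })
  mean_scores <- colMeans(scores)
  sel <- grid[which.max(mean_scores)]
  attr(sel, "scores") <- setNames(mean_scores, signif(grid, 3))
  sel
}

# Stack a list of windowed_fc objects (or plain matrices) into one matrix
# with a session/window index.
stack_windows <- function(wfc_list) {
  if (inherits(wfc_list, "windowed_fc")) wfc_list <- list(session = wfc_list)
  if (is.matrix(wfc_list)) wfc_list <- list(session = wfc_list)
  if (is.null(names(wfc_list)))
    names(wfc_list) <- paste0("session", seq_along(wfc_list))
  mats <- lapply(wfc_list, function(w) if (inherits(w, "windowed_fc")) w$z else w)
  idx <- data.frame(
    session = rep(names(mats), vapply(mats, nrow, 1L)),
    window = unlist(lapply(mats, function(m) seq_len(nrow(m))), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  list(x = do.call(rbind, mats), index = idx)
}

#' Cluster windowed connectivity into recurring states
#'
#' k-means under city-block (L1) distance: windows are assigned to the
#' centroid at minimal L1 distance (ties to the lowest state index) and
#' centroids are updated as element-wise medians, the L1-optimal location.
#' The algorithm restarts `n_restarts` times from random window draws and
#' keeps the lowest-cost solution. States are renumbered by descending total
#' occurrence.
#'
#' @param wfc_list named list of [windowed_fc()] objects (or matrices), or a
#'   single one.
#' @param k number of states.
#' @param n_restarts random initializations.
#' @param seed seed for the initial draws.
#' @param max_iter,tol per-restart convergence controls.
#' @return object of class `state_model`: `k`, `centroids` (`k x n_pairs`),
#'   `assignments` (session, window, state), `cost`, `cost_trace`,
#'   `occurrence` (counts and percentages).
#' @export
cluster_states <- function(wfc_list, k, n_restarts = 500L, seed = 1L,
                           max_iter = 200L, tol = 1e-6) {
  st <- stack_windows(wfc_list)
  n <- nrow(st$x)
  if (k > n) stop("k (", k, ") exceeds number of windows (", n, ")")
  init <- with_seed(seed, {
    t(replicate(n_restarts, sample.int(n, k)))
  })
  if (k == 1L) init <- matrix(init, ncol = 1L)
  fit <- kmeans_l1_cpp(st$x, k, init - 1L, max_iter, tol)
  assign <- as.integer(fit$assignments)
  counts <- tabulate(assign, nbins = k)
  ord <- order(-counts, seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  assign <- relabel[assign]
  centroids <- fit$centroids[ord, , drop = FALSE]
  colnames(centroids) <- colnames(st$x)
  counts <- counts[ord]
  structure(list(
    k = k,
    centroids = centroids,
    assignments = data.frame(st$index, state = assign,
                             stringsAsFactors = FALSE),
    cost = fit$cost,
    cost_trace = as.numeric(fit$cost_trace),
    occurrence = data.frame(state = seq_len(k), count = counts,
                            percentage = 100 * counts / sum(counts))
  ), class = "state_model")
}

#' Elbow selection of the number of states
#'
#' Computes the cluster validity index `I(k)` = (mean within-cluster L1
#' distance) / (mean between-centroid L1 distance) over `k_range` and places
#' the elbow at the interior `k` where the index's improvement collapses:
#' the `k` maximizing the drop ratio
#' `(I(k-1) - I(k)) / max(I(k) - I(k+1), delta)`, with `delta` a small
#' fraction of the curve's range guarding against division by noise-level
#' drops. A curve with no discernible bend (near-constant drops, as in a
#' strictly linear index) is an error.
#'
#' @inheritParams cluster_states
#' @param k_range integer vector of candidate k (length >= 3).
#' @param min_ratio smallest drop ratio accepted as a bend.
#' @return list(selected_k, k, validity, drop_ratio).
#' @export
elbow_select_k <- function(wfc_list, k_range = 2:9, n_restarts = 20L,
                           seed = 1L, max_iter = 200L, tol = 1e-6,
                           min_ratio = 1.5) {
  k_range <- sort(as.integer(k_range))
  if (length(k_range) < 3)
    stop("k_range must contain at least 3 values (elbow undefined)")
  st <- stack_windows(wfc_list)
  validity <- vapply(k_range, function(k) {
    sm <- cluster_states(st$x, k, n_restarts = n_restarts,
                         seed = derive_seed(seed, "elbow", k),
                         max_iter = max_iter, tol = tol)
    within <- sm$cost / nrow(st$x)
    cd <- as.matrix(stats::dist(sm$centroids, method = "manhattan"))
    between <- mean(cd[upper.tri(cd)])
    within / between
  }, numeric(1))
  out <- elbow_from_validity(validity, k_range, min_ratio)
  out
}

#' Locate the elbow of a cluster-validity curve
#'
#' The drop-ratio rule behind [elbow_select_k()], exposed so synthetic curves
#' can be scored directly.
#'
#' @param validity validity index values, one per `k_range` entry.
#' @param k_range candidate cluster counts (sorted, length >= 3).
#' @param min_ratio smallest drop ratio accepted as a bend.
#' @param min_drop_frac smallest drop entering a candidate k, as a fraction
#'   of the curve's range — bends reached by noise-level drops, or after the
#'   curve has already turned non-monotone, are not candidates.
#' @return list(selected_k, k, validity, drop_ratio).
#' @export
elbow_from_validity <- function(validity, k_range, min_ratio = 1.5,
                                min_drop_frac = 0.05) {
  stopifnot(length(validity) == length(k_range), length(k_range) >= 3)
  drops <- -diff(validity)                       # drop entering each interior k
  rng <- max(diff(range(validity)), 1e-12)
  delta <- 0.01 * rng
  interior <- seq_len(length(k_range) - 2L)      # k_range[interior + 1]
  ratio <- drops[interior] / pmax(drops[interior + 1L], delta)
  ok <- drops[interior] >= max(delta, min_drop_frac * rng) &
    vapply(interior, function(i) all(drops[seq_len(i)] > 0), logical(1))
  ratio[!ok] <- -Inf
  if (!any(is.finite(ratio)) || max(ratio) < min_ratio)
    stop("validity curve has no discernible elbow")
  sel <- k_range[interior[which.max(ratio)] + 1L]
  list(selected_k = sel, k = k_range,
       validity = setNames(validity, k_range),
       drop_ratio = setNames(ratio, k_range[interior + 1L]))
}

#' Strongest connections of a state centroid
#'
#' The `ceiling(fraction * n_pairs)` component pairs with the largest absolute
#' connectivity, tagged by sign.
#'
#' @param centroid numeric vector over component pairs (one row of a state
#'   model's `centroids`).
#' @param fraction fraction of pairs to keep, in (0, 1].
#' @param n_components number of components (inferred from the pair count
#'   when omitted).
#' @return data.frame (comp_a, comp_b, value, sign), strongest first.
#' @export
top_connections <- function(centroid, fraction = 0.05, n_components = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  v <- as.numeric(centroid)
  n_pairs <- length(v)
  if (is.null(n_components))
    n_components <- round((1 + sqrt(1 + 8 * n_pairs)) / 2)
  pid <- pair_index(n_components)
  m <- ceiling(fraction * n_pairs)
  ord <- order(-abs(v), seq_len(n_pairs))[seq_len(m)]
  data.frame(
    comp_a = pid[ord, "row"],
    comp_b = pid[ord, "col"],
    value = v[ord],
    sign = ifelse(v[ord] > 0, "positive", ifelse(v[ord] < 0, "negative", "zero"))
  )
}
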