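# Simplified group spatial ICA with back-reconstruction, spectral component
# selection, template-based network assignment, time-course postprocessing,
# and static functional connectivity.

#' Component selection criteria
#'
#' Components are kept when their time-course spectrum is dominated by
#' low-frequency power (ratio of integrated power below `lf_band_hz[2]` to the
#' `hf_band_hz` band) and shows a high dynamic range. Network labels are
#' assigned by maximal absolute spatial correlation with template maps.
#'
#' @param lf_band_hz low-frequency band, Hz.
#' @param hf_band_hz high-frequency band, Hz.
#' @param min_lf_ratio selection threshold on the power ratio.
#' @param min_dynamic_range selection threshold on the dynamic range of the
#'   unit-sum-normalized spectrum.
#' @param template_maps optional `n_templates x n_voxels` matrix with
#'   rownames as network labels.
#' @return object of class `ic_selection_criteria`.
#' @export
ic_selection_criteria <- function(lf_band_hz = c(0, 0.1),
                                  hf_band_hz = c(0.15, 0.25),
                                  min_lf_ratio = 10,
                                  min_dynamic_range = 0.05,
                                  template_maps = NULL) {
  structure(list(lf_band_hz = lf_band_hz, hf_band_hz = hf_band_hz,
                 min_lf_ratio = min_lf_ratio,
                 min_dynamic_range = min_dynamic_range,
                 template_maps = template_maps),
            class = "ic_selection_criteria")
}

# Welch-averaged periodogram: mean of Hann-windowed segment periodograms with
# 50% overlap. Returns frequency (Hz) and power density.
welch_psd <- function(x, fs, nperseg = 64L) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(win^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- abs(fft(seg))^2 / (u * fs)
    acc <- acc + p[seq_len(nf)]
  }
  list(freq = (seq_len(nf) - 1) * fs / nperseg, power = acc / length(starts))
}

#' Spectral selection metrics of a component time course
#'
#' @param timecourse numeric vector (length >= 64).
#' @param tr_seconds sampling interval, seconds.
#' @param criteria an [ic_selection_criteria()].
#' @return list(lf_ratio, dynamic_range, freq, power). `lf_ratio` is `Inf`
#'   when the high-frequency band holds exactly zero power; `dynamic_range`
#'   is max power minus minimum power above the spectral peak, on the
#'   unit-sum-normalized spectrum.
#' @export
spectral_metrics <- function(timecourse, tr_seconds,
                             criteria = ic_selection_criteria()) {
  if (length(timecourse) < 64) stop("time course too short for spectral metrics")
  ps <- welch_psd(as.numeric(timecourse), fs = 1 / tr_seconds)
  pw <- ps$power / sum(ps$power)
  in_band <- function(b) ps$freq >= b[1] & ps$freq <= b[2]
  lf <- sum(pw[in_band(criteria$lf_band_hz)])
  hf <- sum(pw[in_band(criteria$hf_band_hz)])
  lf_ratio <- if (hf == 0) Inf else lf / hf
  ipk <- which.max(pw)
  dynamic_range <- if (ipk < length(pw)) max(pw) - min(pw[(ipk + 1):length(pw)])
    else 0
  list(lf_ratio = lf_ratio, dynamic_range = dynamic_range,
       freq = ps$freq, power = pw)
}

#' Postprocessing configuration for component time courses
#'
#' @param detrend remove a linear trend.
#' @param despike replace median-absolute-deviation outliers (|z| > `spike_z`)
#'   by spline interpolation over their neighbours.
#' @param spike_z robust z threshold for spike flagging.
#' @param regress_motion remove the six realignment regressors by least
#'   squares.
#' @param lowpass_hz zero-phase Butterworth low-pass cutoff, Hz (`NULL` to
#'   skip).
#' @param filter_order Butterworth order (applied forward and backward).
#' @return object of class `postprocess_config`.
#' @export
postprocess_config <- function(detrend = TRUE, despike = TRUE, spike_z = 4,
                               regress_motion = TRUE, lowpass_hz = 0.1,
                               filter_order = 5L) {
  structure(list(detrend = detrend, despike = despike, spike_z = spike_z,
                 regress_motion = regress_motion, lowpass_hz = lowpass_hz,
                 filter_order = as.integer(filter_order)),
            class = "postprocess_config")
}

despike_mad <- function(x, z = 4) {
  med <- median(x)
  s <- median(abs(x - med)) * 1.4826
  if (s == 0) return(x)
  bad <- which(abs(x - med) / s > z)
  if (!length(bad)) return(x)
  good <- setdiff(seq_along(x), bad)
  x[bad] <- spline(good, x[good], xout = bad, method = "natural")$y
  x
}

#' Postprocess a component time course
#'
#' In order: linear detrend, median-based despiking, least-squares removal of
#' the six motion regressors, zero-phase Butterworth low-pass.
#'
#' @param tc numeric vector.
#' @param motion `T x 6` realignment matrix (required when
#'   `config$regress_motion`).
#' @param config a [postprocess_config()].
#' @param tr_seconds sampling interval, seconds.
#' @return cleaned numeric vector.
#' @export
postprocess_timecourse <- function(tc, motion = NULL,
                                   config = postprocess_config(),
                                   tr_seconds = 2) {
  x <- as.numeric(tc)
  t_ <- seq_along(x)
  if (config$detrend) x <- residuals(lm(x ~ t_))
  if (config$despike) x <- despike_mad(x, config$spike_z)
  if (config$regress_motion) {
    if (is.null(motion)) stop("motion regressors required")
    motion <- as.matrix(motion)
    if (nrow(motion) != length(x))
      stop("motion length (", nrow(motion), ") does not match time course (",
           length(x), ")")
    x <- residuals(lm(x ~ motion))
  }
  if (!is.null(config$lowpass_hz)) {
    nyq <- 1 / (2 * tr_seconds)
    if (config$lowpass_hz >= nyq) stop("low-pass cutoff must be below Nyquist")
    bf <- signal::butter(config$filter_order, config$lowpass_hz / nyq,
                         type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  x
}

#' Postprocess all components of a session
#'
#' @param tc_matrix `T x n_components` matrix.
#' @inheritParams postprocess_timecourse
#' @return matrix of cleaned time courses.
#' @export
postprocess_session <- function(tc_matrix, motion = NULL,
                                config = postprocess_config(),
                                tr_seconds = attr(tc_matrix, "tr_seconds") %||% 2) {
  out <- apply(unclass(tc_matrix), 2, postprocess_timecourse, motion = motion,
               config = config, tr_seconds = tr_seconds)
  attr(out, "tr_seconds") <- tr_seconds
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Static functional connectivity (Fisher z)
#'
#' Pairwise Pearson correlations of a session's cleaned component time
#' courses, Fisher-z transformed with `|r|` clamped at `1 - 1e-7`. The
#' diagonal is `NA` (undefined).
#'
#' @param tc_matrix `T x n_components` matrix.
#' @return symmetric `n x n` z matrix with `NA` diagonal.
#' @export
static_fc <- function(tc_matrix) {
  X <- unclass(tc_matrix)
  if (ncol(X) < 2) stop("need at least 2 components")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0] %||% which(sds == 0)
    stop("zero-variance component: ", paste(bad, collapse = ", "))
  }
  Z <- fisher_z(cor(X))
  diag(Z) <- NA_real_
  Z
}

# ---------------------------------------------------------------------------
# Group spatial ICA (simplified): subject-level PCA reduction, temporal
# concatenation, group PCA, fixed-point (FastICA-style) rotation with
# symmetric decorrelation; component order selection and stability clustering
# are configuration, not estimation.

pca_reduce <- function(X, k, session = "") {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = k, nv = 0)
  if (sum(sv$d > 1e-10 * sv$d[1]) < k)
    stop("rank deficiency in session ", session)
  t(sv$u[, seq_len(k), drop = FALSE]) %*% Xc
}

fastica_rotation <- function(Z, seed, n_restarts = 5L, max_iter = 500L,
                             tol = 1e-8) {
  k <- nrow(Z)
  v <- ncol(Z)
  best <- NULL
  best_score <- -Inf
  for (r in seq_len(n_restarts)) {
    W <- with_seed(derive_seed(seed, "ica_init", r),
                   matrix(rnorm(k * k), k, k))
    sw <- svd(W)
    W <- sw$u %*% t(sw$v)
    for (it in seq_len(max_iter)) {
      WZ <- W %*% Z
      G <- tanh(WZ)
      Gp <- rowMeans(1 - G^2)
      W1 <- G %*% t(Z) / v - diag(Gp) %*% W
      sw <- svd(W1)
      W1 <- sw$u %*% t(sw$v)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) break
    }
    S <- W %*% Z
    score <- sum((colMeans(t(log(cosh(S)))) - 0.3746)^2)
    if (score > best_score) {
      best_score <- score
      best <- W
    }
  }
  best
}

#' Fit a simplified group spatial ICA
#'
#' Subject-level PCA reduction over time, temporal concatenation, group PCA to
#' `n_components`, then spatial ICA by a fixed-point contrast-maximization
#' rule (tanh nonlinearity, symmetric decorrelation) with seeded multi-restart
#' best-run selection. Component sign is fixed so each map's largest-magnitude
#' voxel is positive.
#'
#' @param sessions named list of `T x n_voxels` matrices.
#' @param n_components number of components to extract.
#' @param seed integer seed (determinism contract).
#' @param n_restarts fixed-point restarts; the run with the highest negentropy
#'   proxy is kept.
#' @return object of class `group_decomposition`: `spatial_maps`
#'   (`n_components x n_voxels`, unit-normalized), per-session data refs and
#'   names, `n_components`.
#' @export
fit_group_ica <- function(sessions, n_components, seed = 1L, n_restarts = 5L) {
  stopifnot(length(sessions) >= 1)
  if (is.null(names(sessions)))
    names(sessions) <- paste0("session", seq_along(sessions))
  T_min <- min(vapply(sessions, nrow, 1L))
  nv <- ncol(sessions[[1]])
  if (n_components > min(T_min, nv))
    stop("n_components exceeds min(timepoints, voxels)")
  reduced <- mapply(function(X, nm) pca_reduce(X, n_components, nm),
                    sessions, names(sessions), SIMPLIFY = FALSE)
  G <- do.call(rbind, reduced)
  # group-level spatial whitening
  Gc <- sweep(G, 1, rowMeans(G))
  sv <- svd(Gc, nu = n_components, nv = 0)
  Z <- t(sv$u[, seq_len(n_components), drop = FALSE]) %*% Gc
  Z <- Z / sqrt(rowMeans(Z^2))
  W <- fastica_rotation(Z, seed, n_restarts)
  S <- W %*% Z
  sign_fix <- sign(S[cbind(seq_len(n_components), max.col(abs(S)))])
  S <- S * sign_fix
  S <- S / sqrt(rowSums(S^2))
  structure(list(spatial_maps = S, sessions = sessions,
                 session_names = names(sessions),
                 n_components = n_components, seed = seed),
            class = "group_decomposition")
}

#' Back-reconstruct subject maps and time courses
#'
#' Projects one session's voxel data through the group spatial maps:
#' time courses are the least-squares fit of the session data on the maps,
#' and subject maps the least-squares fit of the data on those time courses.
#'
#' @param decomposition a [fit_group_ica()] result.
#' @param session session name (must have participated in the fit).
#' @return list(timecourses `T x k`, subject_maps `k x n_voxels`).
#' @export
back_reconstruct <- function(decomposition, session) {
  if (!session %in% decomposition$session_names)
    stop("unknown session: ", session)
  X <- decomposition$sessions[[session]]
  Xc <- sweep(X, 2, colMeans(X))
  S <- decomposition$spatial_maps
  TC <- Xc %*% t(S) %*% solve(S %*% t(S))
  A <- solve(crossprod(TC), t(TC) %*% Xc)
  list(timecourses = TC, subject_maps = A)
}

#' Select meaningful components and assign network labels
#'
#' Keeps components whose back-reconstructed time courses pass both spectral
#' thresholds (session-averaged), and labels each by the template map with the
#' highest absolute spatial correlation (ties broken by lowest template
#' index).
#'
#' @param decomposition a [fit_group_ica()] result.
#' @param criteria an [ic_selection_criteria()] with `template_maps` set.
#' @param tr_seconds sampling interval of the session time courses.
#' @return data.frame (component, lf_ratio, dynamic_range, network,
#'   template_r, kept); warns when no component passes.
#' @export
select_components <- function(decomposition, criteria, tr_seconds = 2) {
  if (is.null(criteria$template_maps)) stop("template maps required")
  k <- decomposition$n_components
  tmpl <- criteria$template_maps
  labels <- rownames(tmpl) %||% paste0("net", seq_len(nrow(tmpl)))
  lf <- dr <- numeric(k)
  for (ses in decomposition$session_names) {
    br <- back_reconstruct(decomposition, ses)
    for (j in seq_len(k)) {
      m <- spectral_metrics(br$timecourses[, j], tr_seconds, criteria)
      lf[j] <- lf[j] + min(m$lf_ratio, 1e6) / length(decomposition$session_names)
      dr[j] <- dr[j] + m$dynamic_range / length(decomposition$session_names)
    }
  }
  rmat <- abs(cor(t(decomposition$spatial_maps), t(tmpl)))
  best <- apply(rmat, 1, which.max)   # which.max takes the first (lowest) tie
  out <- data.frame(
    component = seq_len(k),
    lf_ratio = lf,
    dynamic_range = dr,
    network = labels[best],
    template_r = rmat[cbind(seq_len(k), best)],
    kept = lf >= criteria$min_lf_ratio & dr >= criteria$min_dynamic_range
  )
  if (!any(out$kept)) warning("no component passed the selection criteria")
  out
}
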