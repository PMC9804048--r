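# Synthetic cohort generator: hidden semi-Markov connectivity states driving
# multivariate-normal component time courses, paired OFF/ON sessions for two
# clinical groups, head-motion traces, and a severity score tied to the
# occupancy of one target state. Every session carries its generating ground
# truth so recovery can be scored exactly.

GROUPS <- c("LID", "NoLID")
PHASES <- c("OFF", "ON")

default_network_partition <- function() {
  sizes <- c(BG = 2L, AUD = 1L, SMN = 5L, VIS = 4L, CEN = 5L, DMN = 4L, CB = 1L)
  rep(names(sizes), sizes)
}

gp_array <- function(n_states, fill) {
  array(fill, dim = c(2L, 2L, n_states),
        dimnames = list(group = GROUPS, phase = PHASES, state = NULL))
}

# Default study design: no group differences in the drug-OFF phase; in the
# drug-ON phase the LID group favours (and dwells longer in) states 1-2 and
# avoids state 3, while the NoLID group concentrates in the weakly-connected
# final state. Selection probabilities are stored as logits.
default_dwell <- function(n_states) {
  d <- gp_array(n_states, 80)
  if (n_states >= 3) {
    d["LID", "ON", 1] <- 105
    d["LID", "ON", 2] <- 105
    d["LID", "ON", 3] <- 55
    d["NoLID", "ON", n_states] <- 100
    d["NoLID", "ON", 3] <- 60
  }
  d
}

default_occupancy_logits <- function(n_states) {
  base <- rep(1 / n_states, n_states)
  lg <- gp_array(n_states, 0)
  for (g in GROUPS) for (ph in PHASES) lg[g, ph, ] <- log(base)
  if (n_states >= 4) {
    lid_on <- c(0.26, 0.22, 0.10, rep(0.12, n_states - 4), 0.30)
    nol_on <- c(0.14, 0.14, 0.10, rep(0.14, n_states - 4), 0.48)
    lg["LID", "ON", ] <- log(lid_on / sum(lid_on))
    lg["NoLID", "ON", ] <- log(nol_on / sum(nol_on))
  }
  lg
}

#' Factor-structured state covariance matrices
#'
#' Builds `n_states` component-by-component correlation matrices over a
#' network partition using a network factor model: every component loads
#' `sqrt(base_within)` on its network's factor (giving the within-network
#' correlation floor) and, per state, a signed network-level loading on one
#' state factor. The canonical five motifs echo recurring connectivity-state
#' structure qualitatively: a visual/sensorimotor coupling state, an
#' executive-centred state, a visual-centred state with basal-ganglia
#' decoupling, an executive/default-mode state, and a weakly connected state.
#' States beyond five cycle through procedurally rotated network triplets.
#' Matrices are unit-diagonal and positive-definite by construction.
#'
#' @param partition character vector of network labels, one per component.
#' @param n_states number of states.
#' @param base_within within-network correlation floor.
#' @param weak_within within-network correlation of the weakly connected
#'   state.
#' @param loading_scale multiplier on the state-factor loadings (contrast
#'   strength dial).
#' @return list of `n_states` covariance matrices.
#' @export
make_state_covariances <- function(partition,
                                   n_states = 5L,
                                   base_within = 0.25,
                                   weak_within = 0.10,
                                   loading_scale = 1) {
  nets <- unique(partition)
  p <- length(partition)
  nm <- function(x) if (x %in% nets) x else nets[(match(x, c("BG", "AUD", "SMN", "VIS", "CEN", "DMN", "CB")) - 1L) %% length(nets) + 1L]
  ld <- function(...) {
    v <- c(...)
    setNames(v, vapply(names(v), nm, character(1)))
  }
  motifs <- list(
    ld(VIS = 0.65, SMN = 0.61, DMN = -0.42),
    ld(CEN = 0.71, SMN = 0.51, VIS = -0.51),
    ld(VIS = 0.79, BG = -0.64, DMN = -0.54, CEN = -0.30),
    ld(CEN = 0.64, DMN = 0.59, SMN = 0.37, BG = 0.27),
    numeric(0)  # weak state
  )
  pick <- switch(as.character(min(n_states, 5L)),
                 "2" = motifs[c(1, 5)],
                 "3" = motifs[c(1, 2, 5)],
                 "4" = motifs[c(1, 2, 4, 5)],
                 "5" = motifs,
                 motifs[seq_len(n_states)])
  while (length(pick) < n_states) {
    i <- length(pick) - 4L
    a <- nets[(i - 1L) %% length(nets) + 1L]
    b <- nets[i %% length(nets) + 1L]
    cc <- nets[(i + 1L) %% length(nets) + 1L]
    extra <- setNames(c(0.7, 0.5, -0.5), c(a, b, cc))
    pick[[length(pick) + 1L]] <- extra[!duplicated(names(extra))]
  }
  out <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    loads <- pick[[s]] * loading_scale
    weak <- length(loads) == 0L
    g <- sqrt(if (weak) weak_within else base_within)
    lvec <- numeric(p)
    for (net in names(loads)) lvec[partition == net] <- loads[[net]]
    if (any(g^2 + lvec^2 >= 1))
      stop("invalid loadings: g^2 + l^2 must stay below 1")
    B <- matrix(0, p, length(nets) + 1L)
    for (j in seq_along(nets)) B[partition == nets[j], j] <- g
    B[, length(nets) + 1L] <- lvec
    R <- tcrossprod(B)
    diag(R) <- 1
    out[[s]] <- R
  }
  out
}

#' Scenario configuration for the synthetic cohort generator
#'
#' Encodes the study design the pipeline assumes: 22 components in 7 networks,
#' 230-timepoint sessions at TR = 2 s, five hidden connectivity states with
#' state-specific covariance, 41 + 34 subjects scanned in two paired phases
#' (drug OFF and ON), planted occupancy/dwell contrasts, a severity covariate
#' linked to one state's ON-phase occupancy, and a random-walk motion model.
#'
#' @param n_components number of components (signals).
#' @param network_partition network label per component (7 labels by default).
#' @param n_states number of hidden states (>= 2).
#' @param n_timepoints timepoints per session after volume discarding.
#' @param tr_seconds sampling interval in seconds.
#' @param n_subjects named counts for the LID and NoLID groups.
#' @param dwell_mean_windows group x phase x state expected run length of the
#'   hidden state process, in timepoints.
#' @param occupancy_logits group x phase x state log selection preferences.
#' @param state_covariances list of component covariance matrices, one per
#'   state; defaults to [make_state_covariances()].
#' @param severity_link list(target_state, slope, noise_sd): severity (AIMS)
#'   is `slope * occupancy(target_state in ON) + intercept + noise`, floored
#'   at 0.
#' @param motion_model list(translation_sd mm, rotation_sd radians,
#'   violator_scale, violation_frac): per-step random-walk scales and the
#'   fraction of subjects planted to violate motion QC.
#' @param subject_effect_sd standard deviation of the per-subject logit
#'   perturbation shared by both phases.
#' @param seed master seed.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_components = 22L,
                            network_partition = default_network_partition(),
                            n_states = 5L,
                            n_timepoints = 230L,
                            tr_seconds = 2,
                            n_subjects = c(LID = 41L, NoLID = 34L),
                            dwell_mean_windows = default_dwell(n_states),
                            occupancy_logits = default_occupancy_logits(n_states),
                            state_covariances = NULL,
                            severity_link = list(target_state = 2L, slope = 18,
                                                 noise_sd = 4, intercept = 4.4),
                            motion_model = list(translation_sd = 0.02,
                                                rotation_sd = 4e-4,
                                                violator_scale = 8,
                                                violation_frac = 0),
                            subject_effect_sd = 0.25,
                            seed = 1L) {
  if (n_states < 2) stop("invalid config: n_states must be >= 2")
  if (length(network_partition) != n_components)
    stop("invalid config: network_partition length must equal n_components")
  if (is.null(state_covariances))
    state_covariances <- make_state_covariances(network_partition, n_states)
  if (length(state_covariances) != n_states)
    stop("invalid config: need one covariance per state")
  for (s in seq_along(state_covariances)) {
    S <- state_covariances[[s]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      stop("invalid config: state covariance ", s, " not symmetric")
    if (any(abs(diag(S) - 1) > 1e-8))
      stop("invalid config: state covariance ", s, " must have unit diagonal")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("invalid config: state covariance ", s, " not positive-definite")
  }
  if (any(dim(dwell_mean_windows) != c(2, 2, n_states)) ||
      any(dim(occupancy_logits) != c(2, 2, n_states)))
    stop("invalid config: dwell/occupancy arrays must be 2 x 2 x n_states")
  if (any(dwell_mean_windows < 1))
    stop("invalid config: dwell means must be >= 1 window")
  if (severity_link$target_state > n_states)
    stop("invalid config: severity target state out of range")
  structure(list(
    n_components = as.integer(n_components),
    network_partition = network_partition,
    n_states = as.integer(n_states),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    n_subjects = n_subjects,
    dwell_mean_windows = dwell_mean_windows,
    occupancy_logits = occupancy_logits,
    state_covariances = state_covariances,
    severity_link = severity_link,
    motion_model = motion_model,
    subject_effect_sd = subject_effect_sd,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# s_i * (1 - s_i) for softmax probabilities, computed as e_i * sum(e_{-i}) /
# sum(e)^2 with the leave-one-out sums taken directly so the result stays
# positive when one logit dominates and s_i rounds to 1
softmax_entrance <- function(x) {
  e <- exp(x - max(x))
  others <- vapply(seq_along(e), function(i) sum(e[-i]), numeric(1))
  e * others / sum(e)^2
}

#' Closed-form stationary occupancy of the hidden state process
#'
#' The generator draws geometric run lengths with configured means `d` and
#' picks the next state from selection probabilities `s` excluding the current
#' state. The entrance chain `P(i -> j) = s_j / (1 - s_i)` has stationary
#' distribution proportional to `s_i (1 - s_i)`, so long-run occupancy is
#' proportional to `s_i (1 - s_i) d_i`.
#'
#' @param config a [scenario_config()].
#' @param group `"LID"` or `"NoLID"`.
#' @param phase `"OFF"` or `"ON"`.
#' @param subject_effect optional per-state logit perturbation.
#' @return occupancy probabilities over states.
#' @export
stationary_occupancy <- function(config, group, phase, subject_effect = 0) {
  logits <- config$occupancy_logits[group, phase, ] + subject_effect
  d <- config$dwell_mean_windows[group, phase, ]
  occ <- softmax_entrance(logits) * d
  occ / sum(occ)
}

#' Simulate a hidden semi-Markov state path
#'
#' State runs have geometric lengths with the configured group/phase/state
#' mean; the next state is drawn from the selection preferences excluding the
#' current state. The initial state is drawn from the stationary occupancy
#' (geometric runs are memoryless, so this starts the process in its
#' stationary law and finite-session occupancy is unbiased).
#'
#' @inheritParams stationary_occupancy
#' @param seed integer seed (reproducibility contract).
#' @return integer vector of length `n_timepoints` with values in
#'   `1..n_states`.
#' @export
simulate_state_path <- function(config, group = "LID", phase = "OFF",
                                seed = config$seed, subject_effect = 0) {
  stopifnot(inherits(config, "scenario_config"))
  logits <- config$occupancy_logits[group, phase, ] + subject_effect
  s <- softmax(logits)
  d <- config$dwell_mean_windows[group, phase, ]
  k <- config$n_states
  T_ <- config$n_timepoints
  with_seed(seed, {
    occ <- softmax_entrance(logits) * d
    cur <- sample.int(k, 1, prob = occ / sum(occ))
    path <- integer(0)
    while (length(path) < T_) {
      len <- rgeom(1, prob = 1 / d[cur]) + 1L
      path <- c(path, rep.int(cur, len))
      nxt_prob <- s
      nxt_prob[cur] <- 0
      cur <- sample.int(k, 1, prob = nxt_prob / sum(nxt_prob))
    }
    path[seq_len(T_)]
  })
}

#' Simulate component time courses from a state path
#'
#' Each timepoint is a zero-mean multivariate normal draw with the covariance
#' of the current hidden state.
#'
#' @param path integer state path.
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return matrix `n_timepoints x n_components` with attribute `tr_seconds`,
#'   class `component_timecourses`.
#' @export
simulate_timecourses <- function(path, config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(path < 1 | path > config$n_states)) stop("invalid state path")
  p <- config$n_components
  chols <- lapply(config$state_covariances, chol)
  X <- with_seed(seed, {
    Z <- matrix(rnorm(length(path) * p), length(path), p)
    X <- matrix(0, length(path), p)
    for (s in seq_len(config$n_states)) {
      rows <- which(path == s)
      if (length(rows)) X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[s]]
    }
    X
  })
  colnames(X) <- paste0("IC", seq_len(p))
  structure(X, tr_seconds = config$tr_seconds, class = c("component_timecourses", "matrix"))
}

# Random-walk realignment trace: 3 translations (mm) + 3 rotations (radians).
simulate_motion <- function(n_timepoints, model, violator = FALSE, seed = 1L) {
  scale <- if (violator) model$violator_scale else 1
  with_seed(seed, {
    steps <- cbind(
      matrix(rnorm(3 * n_timepoints, sd = model$translation_sd * scale), ncol = 3),
      matrix(rnorm(3 * n_timepoints, sd = model$rotation_sd * scale), ncol = 3)
    )
    m <- apply(steps, 2, cumsum)
    colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    m
  })
}

#' Simulate a full paired cohort
#'
#' Generates subjects for both groups with paired OFF/ON sessions. Each subject
#' has a random preference perturbation shared by both phases; hidden state
#' paths, component time courses and motion traces are produced per session.
#' AIMS severity in the LID group is a linear (floored at zero) function of the
#' subject's ON-phase occupancy of the severity-linked state plus noise. A
#' configured fraction of subjects receives motion traces that violate QC.
#'
#' @param config a [scenario_config()].
#' @param timecourses if `FALSE`, only hidden paths / covariates / motion are
#'   generated (fast mode for statistical power studies).
#' @return object of class `cohort_dataset` with elements `subjects`
#'   (data.frame), `session_table`, `sessions` (named list of
#'   `timecourses` + `motion`), and `ground_truth`.
#' @export
simulate_cohort <- function(config, timecourses = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  n_lid <- config$n_subjects[["LID"]]
  n_nolid <- config$n_subjects[["NoLID"]]
  ids <- c(sprintf("LID%03d", seq_len(n_lid)),
           sprintf("NOL%03d", seq_len(n_nolid)))
  groups <- rep(GROUPS, c(n_lid, n_nolid))
  n <- length(ids)

  cov_seed <- derive_seed(config$seed, "covariates")
  covars <- with_seed(cov_seed, {
    data.frame(
      id = ids, group = groups,
      age_at_onset = round(rnorm(n, 54, 9), 1),
      ledd = pmax(100, round(rnorm(n, 720, 300))),
      disease_duration = round(pmax(0.5, rnorm(n, ifelse(groups == "LID", 8.3, 5.7),
                                               ifelse(groups == "LID", 4.1, 2.9))), 1),
      mmse = pmin(30, pmax(24, round(rnorm(n, 28, 1.5)))),
      stringsAsFactors = FALSE
    )
  })
  viol_seed <- derive_seed(config$seed, "violators")
  violators <- with_seed(viol_seed, {
    runif(n) < config$motion_model$violation_frac
  })

  sessions <- list()
  session_rows <- list()
  paths <- list()
  occ_on_target <- numeric(n)
  target <- config$severity_link$target_state
  for (i in seq_len(n)) {
    eff <- with_seed(derive_seed(config$seed, "subject_effect", ids[i]),
                     rnorm(config$n_states, 0, config$subject_effect_sd))
    for (ph in PHASES) {
      key <- paste(ids[i], ph, sep = "_")
      path <- simulate_state_path(config, groups[i], ph,
                                  seed = derive_seed(config$seed, "path", key),
                                  subject_effect = eff)
      paths[[key]] <- path
      tc <- if (timecourses)
        simulate_timecourses(path, config, seed = derive_seed(config$seed, "tc", key))
      else NULL
      motion <- simulate_motion(config$n_timepoints, config$motion_model,
                                violator = violators[i],
                                seed = derive_seed(config$seed, "motion", key))
      sessions[[key]] <- list(timecourses = tc, motion = motion)
      session_rows[[key]] <- data.frame(session = key, subject = ids[i],
                                        group = groups[i], phase = ph,
                                        stringsAsFactors = FALSE)
      if (ph == "ON") occ_on_target[i] <- mean(path == target)
    }
  }

  aims_seed <- derive_seed(config$seed, "aims")
  aims <- with_seed(aims_seed, {
    a <- config$severity_link$intercept +
      config$severity_link$slope * occ_on_target +
      rnorm(n, 0, config$severity_link$noise_sd)
    pmax(0, round(a, 1))
  })
  covars$aims <- ifelse(groups == "LID", aims, NA_real_)
  covars$motion_violator <- violators

  structure(list(
    subjects = covars,
    session_table = do.call(rbind, unname(session_rows)),
    sessions = sessions,
    ground_truth = list(paths = paths, config = config,
                        occupancy_on_target = setNames(occ_on_target, ids))
  ), class = "cohort_dataset")
}

#' Write a cohort to plain-text files
#'
#' Per-session component time courses and 6-parameter motion traces as TSV,
#' the subject table as TSV, and ground truth (hidden paths + key scenario
#' parameters) as JSON.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timecourses"), showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"))
  write_tsv(cohort$session_table, file.path(dir, "sessions.tsv"))
  for (key in names(cohort$sessions)) {
    ses <- cohort$sessions[[key]]
    if (!is.null(ses$timecourses))
      write_tsv(as.data.frame(unclass(ses$timecourses)),
                file.path(dir, "timecourses", paste0(key, ".tsv")))
    write_tsv(as.data.frame(ses$motion),
              file.path(dir, "motion", paste0(key, ".tsv")))
  }
  gt <- list(paths = cohort$ground_truth$paths,
             n_states = cohort$ground_truth$config$n_states,
             seed = cohort$ground_truth$config$seed)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Synthetic spatial maps on a small voxel grid
#'
#' Gaussian blobs at distinct grid locations, one per component, flattened to
#' a components-by-voxels matrix. Purely synthetic stand-ins for network
#' templates at desk scale.
#'
#' @param n_components number of maps.
#' @param dims 3D grid dimensions.
#' @param radius blob standard deviation in voxels.
#' @param seed seed for blob placement jitter.
#' @return matrix `n_components x prod(dims)` with attribute `dims`.
#' @export
make_spatial_maps <- function(n_components, dims = c(10L, 10L, 6L),
                              radius = 1.5, seed = 1L) {
  nv <- prod(dims)
  grid <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                z = seq_len(dims[3])))
  with_seed(seed, {
    # farthest-point placement keeps blobs well separated (non-collinear maps)
    candidates <- grid + matrix(runif(3 * nv, -0.4, 0.4), nv, 3)
    centers <- matrix(0, n_components, 3)
    centers[1, ] <- candidates[sample.int(nv, 1), ]
    if (n_components > 1) {
      for (i in 2:n_components) {
        dmin <- apply(candidates, 1, function(v)
          min(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - v)^2)))
        centers[i, ] <- candidates[which.max(dmin), ]
      }
    }
    M <- matrix(0, n_components, nv)
    for (i in seq_len(n_components)) {
      d2 <- rowSums(sweep(grid, 2, centers[i, ])^2)
      M[i, ] <- exp(-d2 / (2 * radius^2))
    }
    M <- M / sqrt(rowSums(M^2))
    attr(M, "dims") <- dims
    M
  })
}

#' Simulate voxel data from spatial maps and component time courses
#'
#' `voxels = timecourses %*% maps + noise`, the linear mixing model that the
#' group ICA stage inverts.
#'
#' @param timecourses `T x n_components` matrix.
#' @param spatial_maps `n_components x n_voxels` matrix.
#' @param snr signal-to-noise ratio (signal SD over noise SD); `Inf` for
#'   noise-free data.
#' @param seed integer seed.
#' @return matrix `T x n_voxels` with attribute `dims` when maps carry one.
#' @export
simulate_voxel_data <- function(timecourses, spatial_maps, snr = 10, seed = 1L) {
  if (ncol(timecourses) != nrow(spatial_maps))
    stop("map count mismatch: ", nrow(spatial_maps), " maps for ",
         ncol(timecourses), " components")
  signal <- unclass(timecourses) %*% spatial_maps
  if (is.finite(snr)) {
    noise_sd <- sd(as.vector(signal)) / snr
    if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- 1 / snr
    signal <- signal + with_seed(seed, {
      matrix(rnorm(length(signal), sd = noise_sd), nrow(signal), ncol(signal))
    })
  }
  attr(signal, "dims") <- attr(spatial_maps, "dims")
  signal
}
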