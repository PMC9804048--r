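# Head-motion quality control: initial-volume discarding, Power-style
# framewise displacement, and threshold-based session exclusion.

#' QC thresholds
#'
#' @param mean_fd_max maximum mean framewise displacement, mm.
#' @param translation_max maximum absolute translation on any axis, mm.
#' @param rotation_max maximum absolute rotation on any axis, degrees.
#' @param n_discard initial volumes removed for signal equilibration.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(mean_fd_max = 0.5, translation_max = 3,
                          rotation_max = 3, n_discard = 10L) {
  stopifnot(mean_fd_max > 0, translation_max > 0, rotation_max > 0,
            n_discard >= 0)
  structure(list(mean_fd_max = mean_fd_max, translation_max = translation_max,
                 rotation_max = rotation_max, n_discard = as.integer(n_discard)),
            class = "qc_thresholds")
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` timepoints from a time-indexed matrix or vector
#' (time courses, motion traces), e.g. 240 acquired volumes minus 10
#' equilibration scans leaves 230.
#'
#' @param series matrix (rows = timepoints) or vector.
#' @param n_discard number of initial timepoints to drop.
#' @return the shortened series, attributes preserved.
#' @export
discard_initial_volumes <- function(series, n_discard = 10L) {
  n <- if (is.matrix(series)) nrow(series) else length(series)
  if (n_discard >= n)
    stop("n_discard (", n_discard, ") must be smaller than series length (", n, ")")
  if (n_discard == 0) return(series)
  keep <- seq.int(n_discard + 1L, n)
  out <- if (is.matrix(series)) series[keep, , drop = FALSE] else series[keep]
  for (a in setdiff(names(attributes(series)), c("dim", "dimnames", "names")))
    attr(out, a) <- attr(series, a)
  out
}

#' Framewise displacement from realignment parameters
#'
#' Power-convention FD: sum of absolute backward differences of the six
#' realignment parameters, rotations (radians) converted to arc length on a
#' 50 mm sphere. Depends only on parameter differences, so it is invariant to
#' constant offsets.
#'
#' @param motion `T x 6` matrix: 3 translations (mm), 3 rotations (radians).
#' @param radius_mm rotation lever arm, mm.
#' @return FD series of length `T - 1`, mm.
#' @export
compute_framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("need at least 2 timepoints")
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  if (!all(is.finite(motion))) stop("non-finite motion parameters")
  d <- abs(diff(motion))
  rowSums(d[, 1:3, drop = FALSE]) + radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' Session-level motion exclusion decision
#'
#' Excludes a session when mean FD exceeds `mean_fd_max`, any absolute
#' translation exceeds `translation_max` (mm), or any absolute rotation
#' exceeds `rotation_max` (degrees; parameters stored in radians are converted
#' first). Thresholds are strict: boundary equality retains.
#'
#' @param motion `T x 6` realignment matrix (translations mm, rotations rad).
#' @param thresholds a [qc_thresholds()].
#' @return list(decision = "retain"/"exclude", reasons, mean_fd,
#'   max_translation, max_rotation_deg).
#' @export
apply_exclusion <- function(motion, thresholds = qc_thresholds()) {
  fd <- compute_framewise_displacement(motion)
  mean_fd <- mean(fd)
  max_trans <- max(abs(motion[, 1:3]))
  max_rot_deg <- max(abs(motion[, 4:6])) * 180 / pi
  reasons <- character(0)
  if (mean_fd > thresholds$mean_fd_max) reasons <- c(reasons, "mean-FD")
  if (max_trans > thresholds$translation_max) reasons <- c(reasons, "translation")
  if (max_rot_deg > thresholds$rotation_max) reasons <- c(reasons, "rotation")
  list(decision = if (length(reasons)) "exclude" else "retain",
       reasons = reasons, mean_fd = mean_fd, max_translation = max_trans,
       max_rotation_deg = max_rot_deg)
}

#' Cohort-level QC report
#'
#' Applies [apply_exclusion()] to every session of a cohort.
#'
#' @param cohort a [simulate_cohort()] result (or any list with
#'   `session_table` and `sessions[[key]]$motion`).
#' @param thresholds a [qc_thresholds()].
#' @return data.frame: session, subject, phase, mean_fd, max_translation,
#'   max_rotation_deg, decision, reasons.
#' @export
qc_report <- function(cohort, thresholds = qc_thresholds()) {
  rows <- lapply(seq_len(nrow(cohort$session_table)), function(i) {
    key <- cohort$session_table$session[i]
    r <- apply_exclusion(cohort$sessions[[key]]$motion, thresholds)
    data.frame(session = key,
               subject = cohort$session_table$subject[i],
               phase = cohort$session_table$phase[i],
               mean_fd = r$mean_fd,
               max_translation = r$max_translation,
               max_rotation_deg = r$max_rotation_deg,
               decision = r$decision,
               reasons = paste(r$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
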