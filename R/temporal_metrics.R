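# Temporal properties of state assignment sequences: fractional windows,
# mean dwell time, number of transitions.

#' Temporal properties of one session's state sequence
#'
#' Run-length encodes the per-window state assignments. Fractional windows is
#' the percentage of windows spent in each state; mean dwell time is the mean
#' run length (in windows) over that state's runs, with the terminal
#' (uncompleted) run counted; the number of transitions is the number of runs
#' minus one. Unvisited states report fractional 0 and dwell 0, with a
#' `visited` mask for sensitivity analyses.
#'
#' @param assignments integer vector of per-window states.
#' @param k number of states.
#' @return list(fractional_windows, mean_dwell, n_transitions, visited,
#'   n_windows); the per-state vectors have length `k`.
#' @export
temporal_properties <- function(assignments, k) {
  a <- as.integer(assignments)
  if (!length(a)) stop("empty assignment sequence")
  if (any(is.na(a)) || any(a < 1L | a > k))
    stop("state labels must be in 1..", k)
  r <- rle(a)
  n <- length(a)
  frac <- 100 * tabulate(a, nbins = k) / n
  dwell <- numeric(k)
  for (s in seq_len(k)) {
    runs <- r$lengths[r$values == s]
    dwell[s] <- if (length(runs)) mean(runs) else 0
  }
  list(fractional_windows = frac,
       mean_dwell = dwell,
       n_transitions = length(r$lengths) - 1L,
       visited = tabulate(a, nbins = k) > 0L,
       n_windows = n)
}

#' Per-session temporal metrics table for a cohort
#'
#' Applies [temporal_properties()] to every session of a state model (or to a
#' named list of assignment vectors such as ground-truth hidden paths) and
#' joins subject/group/phase labels.
#'
#' @param assignments a `state_model` from [cluster_states()], or a named
#'   list of integer sequences keyed like `session_table$session`.
#' @param session_table data.frame with columns session, subject, group,
#'   phase.
#' @param k number of states.
#' @return data.frame in long form: subject, group, phase, state,
#'   fractional_windows, mean_dwell, visited, plus session-level
#'   n_transitions repeated per state.
#' @export
cohort_temporal_metrics <- function(assignments, session_table, k) {
  seqs <- if (inherits(assignments, "state_model")) {
    split(assignments$assignments$state, assignments$assignments$session)
  } else assignments
  rows <- lapply(seq_len(nrow(session_table)), function(i) {
    key <- session_table$session[i]
    tp <- temporal_properties(seqs[[key]], k)
    data.frame(session = key,
               subject = session_table$subject[i],
               group = session_table$group[i],
               phase = session_table$phase[i],
               state = seq_len(k),
               fractional_windows = tp$fractional_windows,
               mean_dwell = tp$mean_dwell,
               visited = tp$visited,
               n_transitions = tp$n_transitions,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
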