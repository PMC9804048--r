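# Shared helpers: deterministic seed derivation, scoped RNG, pair indexing,
# Fisher z, TSV conventions.

#' Derive a child seed from a master seed and a tag
#'
#' Stage- and session-level randomness is driven by child seeds derived
#' deterministically from one master seed, so that any stage can be re-run in
#' isolation and reproduce its output bit-identically.
#'
#' @param seed master integer seed.
#' @param ... character or numeric tags identifying the consumer.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), paste, character(1), collapse = "/"),
                collapse = "/")
  h <- as.double(seed %% 2147480009L)
  for (code in utf8ToInt(tags)) h <- (h * 31 + code) %% 2147480009
  as.integer(h)
}

# Evaluate expr under a local RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Number of sliding windows for a session
#'
#' The identity `floor((T - width) / step) + 1` for a window of `width`
#' timepoints advanced by `step` over `T` timepoints.
#'
#' @param n_timepoints session length T (timepoints).
#' @param width window width (timepoints).
#' @param step step between consecutive windows (timepoints).
#' @return integer window count.
#' @export
count_windows <- function(n_timepoints, width, step = 1L) {
  stopifnot(n_timepoints >= width, step >= 1)
  as.integer(floor((n_timepoints - width) / step) + 1L)
}

# Component-pair labels for the vectorized upper triangle, in column-major
# upper-triangle order matching the C++ loop (a < b, a fastest-moving last).
pair_labels <- function(n_components) {
  idx <- which(upper.tri(diag(n_components)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  paste0(idx[, "row"], "_", idx[, "col"])
}

pair_index <- function(n_components) {
  idx <- which(upper.tri(diag(n_components)), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

#' Fisher z transform with clamping
#'
#' `atanh(r)` with `|r|` clamped at `1 - 1e-7` so that perfectly correlated
#' series map to a finite value (about 8.1).
#'
#' @param r correlation value(s).
#' @param clamp clamping bound on `|r|`.
#' @return z value(s).
#' @export
fisher_z <- function(r, clamp = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clamp), clamp))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items; 1 for
#' identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

#' Majority hidden state per sliding window
#'
#' Labels each window of a hidden state path by the state occupying most of
#' the window's nominal span (ties to the lowest state index), for scoring
#' recovered window assignments against ground truth.
#'
#' @param path integer state path.
#' @param width window width (timepoints).
#' @param step window step.
#' @return integer vector of length [count_windows()].
#' @export
majority_states <- function(path, width = 30L, step = 1L) {
  n_win <- count_windows(length(path), width, step)
  vapply(seq_len(n_win), function(i) {
    seg <- path[((i - 1L) * step + 1L):((i - 1L) * step + width)]
    tb <- tabulate(seg)
    which.max(tb)
  }, integer(1))
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
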