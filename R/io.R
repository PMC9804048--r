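# Reading a cohort back from the plain-text layout written by write_cohort():
# user-supplied data in the same formats (TSV time courses, 6-column motion
# traces, subject table, optional ground-truth JSON) load the same way.

#' Read a cohort from a directory of plain-text files
#'
#' Expects the layout produced by [write_cohort()]: `subjects.tsv`,
#' `sessions.tsv`, `timecourses/<session>.tsv` (rows = timepoints, columns =
#' components), `motion/<session>.tsv` (6 realignment columns), and optional
#' `ground_truth.json`.
#'
#' @param dir directory path.
#' @param tr_seconds sampling interval attached to the time courses.
#' @return object of class `cohort_dataset`.
#' @export
read_cohort <- function(dir, tr_seconds = 2) {
  subjects <- read_tsv(file.path(dir, "subjects.tsv"))
  session_table <- read_tsv(file.path(dir, "sessions.tsv"))
  sessions <- lapply(setNames(session_table$session, session_table$session),
                     function(key) {
    tc_path <- file.path(dir, "timecourses", paste0(key, ".tsv"))
    tc <- NULL
    if (file.exists(tc_path)) {
      tc <- as.matrix(read_tsv(tc_path))
      attr(tc, "tr_seconds") <- tr_seconds
      class(tc) <- c("component_timecourses", "matrix")
    }
    motion <- as.matrix(read_tsv(file.path(dir, "motion", paste0(key, ".tsv"))))
    list(timecourses = tc, motion = motion)
  })
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- NULL
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    ground_truth <- list(paths = as.list(gt$paths), n_states = gt$n_states,
                         seed = gt$seed)
  }
  structure(list(subjects = subjects, session_table = session_table,
                 sessions = sessions, ground_truth = ground_truth),
            class = "cohort_dataset")
}

#' Write a voxel session as a 4D NIfTI volume
#'
#' Reshapes a `T x n_voxels` matrix carrying a `dims` attribute (as produced
#' by [simulate_voxel_data()]) into an x-y-z-time array and writes it with
#' the `RNifti` package.
#'
#' @param voxels `T x n_voxels` matrix with attribute `dims`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param tr_seconds repetition time stored in the header.
#' @return `path`, invisibly.
#' @export
write_voxel_nifti <- function(voxels, path, tr_seconds = 2) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required to write NIfTI volumes")
  dims <- attr(voxels, "dims")
  if (is.null(dims)) stop("voxel matrix lacks a 'dims' attribute")
  arr <- array(t(voxels), dim = c(dims, nrow(voxels)))
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(3, 3, 3, tr_seconds)),
                     path)
  invisible(path)
}
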