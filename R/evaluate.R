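#' Region-wise detection accuracy
#'
#' Scores a classification map against the ground truth using the
#' high-amplitude-core definition: within a region, the denominator is
#' the set of voxels whose true amplitude is at least `amplitude_floor`
#' for every required task, and a voxel counts as correct when it is
#' classified with exactly the required task set. For the null region
#' (`required_tasks = character(0)`, `region = NULL`), accuracy is the
#' fraction of truly inactive voxels classified inactive.
#'
#' @param class_map Integer classification image (bit `h` set when task
#'   `tasks[h]` was accepted active), e.g. from [run_sequential()] or
#'   [run_fixed()].
#' @param truth A `ground_truth`.
#' @param region Region index into `truth$regions`, or `NULL` for the
#'   whole image (used with the null-region score).
#' @param required_tasks Character vector of tasks that must be (exactly)
#'   the classified set; empty for the null score.
#' @param amplitude_floor Minimum true amplitude (default 0.8).
#' @param tasks Task-to-bit order of `class_map` (default the truth's
#'   task names).
#' @return Accuracy as a percentage, or `NA` (with a warning) when the
#'   denominator is empty.
#' @export
detection_accuracy <- function(class_map, truth, region = NULL,
                               required_tasks = character(0),
                               amplitude_floor = 0.8,
                               tasks = names(truth$amplitude)) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!all(dim(class_map) == truth$shape))
    stop("classification map and truth are not aligned")
  sel <- if (is.null(region)) rep(TRUE, prod(truth$shape))
         else as.vector(truth$labels == region)
  amp <- lapply(truth$amplitude, as.vector)
  if (length(required_tasks) == 0) {
    cond <- Reduce(`&`, lapply(amp, function(a) a == 0))
  } else {
    if (!all(required_tasks %in% tasks))
      stop("unknown task in 'required_tasks'")
    cond <- Reduce(`&`, lapply(amp[required_tasks],
                               function(a) a >= amplitude_floor))
  }
  denom <- sel & cond
  if (!any(denom)) {
    warning("undefined accuracy: empty denominator")
    return(NA_real_)
  }
  req_code <- sum(2L^(match(required_tasks, tasks) - 1L))
  100 * sum(as.vector(class_map)[denom] == req_code, na.rm = TRUE) /
    sum(denom)
}

#' Table of region accuracies for the preset three-region layout
#'
#' Convenience wrapper reproducing the layout of the simulation result
#' tables: accuracy over the high-amplitude core of region 1 (task A),
#' region 2 (task B), region 3 (both tasks), and the null region.
#'
#' @param class_map Classification image (bits: 1 = task A, 2 = task B).
#' @param truth The preset `ground_truth` ([preset_activation_map()]).
#' @param amplitude_floor Minimum true amplitude (default 0.8); with
#'   `peak_b > 1` the floor scales with the peak.
#' @return Named numeric vector of four percentages.
#' @export
accuracy_table <- function(class_map, truth,
                           amplitude_floor = 0.8 *
                             max(unlist(truth$amplitude))) {
  c(region1_A = detection_accuracy(class_map, truth, 1, "A",
                                   amplitude_floor),
    region2_B = detection_accuracy(class_map, truth, 2, "B",
                                   amplitude_floor),
    region3_AB = detection_accuracy(class_map, truth, 3, c("A", "B"),
                                    amplitude_floor),
    null = detection_accuracy(class_map, truth, NULL, character(0)))
}

#' Scan-time savings of a sequential design
#'
#' @param sequential Volumes (or blocks) used by the sequential design.
#' @param fixed Volumes (or blocks) of the fixed benchmark (> 0).
#' @return Percentage saving, `100 (fixed - sequential) / fixed`.
#' @examples
#' scan_savings(222, 360)  # 38.3
#' @export
scan_savings <- function(sequential, fixed) {
  if (any(fixed <= 0)) stop("'fixed' must be > 0")
  100 * (fixed - sequential) / fixed
}
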