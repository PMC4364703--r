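#' Stimulus paradigm
#'
#' A paradigm is the event table of an fMRI run: stimulus onsets, durations
#' and condition labels, together with the repetition time (TR) and the
#' number of acquired volumes.
#'
#' @param events Data frame with columns `onset`, `duration`, `condition`
#'   (onset and duration in seconds). An empty data frame (or `NULL`)
#'   describes a rest-only run.
#' @param tr Repetition time in seconds.
#' @param n_volumes Number of acquired volumes (>= 1).
#' @return An object of class `paradigm`.
#' @export
paradigm <- function(events = NULL, tr, n_volumes) {
  if (is.null(events))
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         condition = character(0))
  events <- as.data.frame(events)
  required <- c("onset", "duration", "condition")
  if (!all(required %in% names(events)))
    stop("'events' must have columns onset, duration, condition")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a positive number")
  if (!is.numeric(n_volumes) || n_volumes < 1)
    stop("'n_volumes' must be >= 1")
  n_volumes <- as.integer(n_volumes)
  if (nrow(events)) {
    if (any(events$onset < 0)) stop("event onsets must be >= 0")
    if (any(events$duration <= 0)) stop("event durations must be > 0")
    for (cond in unique(events$condition)) {
      on <- events$onset[events$condition == cond]
      if (is.unsorted(on, strictly = TRUE))
        stop("onsets must be strictly increasing within condition '",
             cond, "'")
    }
    scan_end <- n_volumes * tr
    if (any(events$onset + events$duration > scan_end)) {
      warning("events extend beyond the scan; truncated at ",
              scan_end, " s")
      events$duration <- pmin(events$duration,
                              pmax(scan_end - events$onset, 0))
      events <- events[events$duration > 0, , drop = FALSE]
    }
  }
  events$condition <- as.character(events$condition)
  structure(list(events = events, tr = tr, n_volumes = n_volumes),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat("fMRI paradigm: ", x$n_volumes, " volumes, TR ", x$tr, " s, ",
      nrow(x$events), " events (",
      paste(unique(x$events$condition), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Alternating block paradigm
#'
#' Builds a block paradigm of the form `R | A | R | B | R | ...`: a leading
#' rest block, then task blocks drawn cyclically from `pattern`, each
#' followed by a rest block. Used for the two-task simulation designs
#' (4 s task, 20 s rest) and the difficulty-level runs (3 s task, 8 s
#' rest).
#'
#' @param pattern Character vector of condition labels cycled over task
#'   blocks, e.g. `c("A", "B")`.
#' @param task_s Task block duration, seconds.
#' @param rest_s Rest block duration, seconds.
#' @param tr Repetition time, seconds.
#' @param n_volumes Number of volumes; blocks are generated until the end
#'   of the scan.
#' @param rest_first Logical; start with a rest block (default `TRUE`).
#' @return A [paradigm].
#' @examples
#' p <- make_block_paradigm(c("A", "B"), task_s = 4, rest_s = 20,
#'                          tr = 2, n_volumes = 360)
#' table(p$events$condition)
#' @export
make_block_paradigm <- function(pattern, task_s, rest_s, tr, n_volumes,
                                rest_first = TRUE) {
  if (n_volumes < 1) stop("empty paradigm: 'n_volumes' must be >= 1")
  if (task_s <= 0 || rest_s < 0) stop("block durations must be positive")
  if (abs(task_s / tr - round(task_s / tr)) > 1e-8 ||
      abs(rest_s / tr - round(rest_s / tr)) > 1e-8)
    warning("block durations are not multiples of the TR")
  scan_end <- n_volumes * tr
  onset <- if (rest_first) rest_s else 0
  onsets <- numeric(0)
  conds <- character(0)
  i <- 0L
  while (onset + task_s <= scan_end) {
    onsets <- c(onsets, onset)
    conds <- c(conds, pattern[(i %% length(pattern)) + 1L])
    onset <- onset + task_s + rest_s
    i <- i + 1L
  }
  paradigm(data.frame(onset = onsets,
                      duration = rep(task_s, length(onsets)),
                      condition = conds),
           tr = tr, n_volumes = n_volumes)
}

#' Read / write BIDS-style event tables
#'
#' Events are exchanged as tab-separated tables with columns `onset`,
#' `duration`, `trial_type` (seconds).
#'
#' @param path File path.
#' @param tr,n_volumes Run geometry attached to the returned [paradigm].
#' @return `read_events()` returns a [paradigm]; `write_events()` writes
#'   the paradigm's event table and returns `path` invisibly.
#' @export
read_events <- function(path, tr, n_volumes) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset", "duration", "trial_type") %in% names(tab)))
    stop("events TSV must have columns onset, duration, trial_type")
  paradigm(data.frame(onset = tab$onset, duration = tab$duration,
                      condition = tab$trial_type),
           tr = tr, n_volumes = n_volumes)
}

#' @rdname read_events
#' @param x A [paradigm].
#' @export
write_events <- function(x, path) {
  stopifnot(inherits(x, "paradigm"))
  tab <- data.frame(onset = x$events$onset, duration = x$events$duration,
                    trial_type = x$events$condition)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
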