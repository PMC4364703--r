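#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving voxel order and geometry.
#' `read_bold()` reads a 4-D dataset (returned as an array with time
#' last), `read_mask()` a binary mask, and `write_map()` writes an
#' integer classification map, recording the code book in the header
#' description.
#'
#' @param path NIfTI-1 file path.
#' @return `read_bold()` / `read_mask()` return arrays; `write_map()`
#'   returns `path` invisibly.
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attr(a, "pixdim") <- RNifti::pixdim(img)
  a
}

#' @rdname read_bold
#' @param data 4-D array to check the mask against (optional).
#' @export
read_mask <- function(path, data = NULL) {
  m <- as.array(RNifti::readNifti(path)) != 0
  if (!is.null(data)) {
    sd <- dim(data)[seq_along(dim(m))]
    if (!all(dim(m) == sd))
      stop("geometry mismatch: mask is ", paste(dim(m), collapse = "x"),
           ", data is ", paste(sd, collapse = "x"))
  }
  m
}

#' @rdname read_bold
#' @param image Numeric/integer array to write.
#' @param codes Optional named code book recorded in the header
#'   description, e.g. `c(none = 0, taskA = 1, taskB = 2, both = 3)`.
#' @param template Optional NIfTI image or path supplying the affine.
#' @export
write_map <- function(path, image, codes = NULL, template = NULL) {
  img <- if (is.null(template)) RNifti::asNifti(image)
         else RNifti::asNifti(image, reference = template)
  if (!is.null(codes))
    img$descrip <- paste(names(codes), codes, sep = "=", collapse = ";")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' JSON run report
#'
#' Writes a machine-readable provenance and result summary of a
#' sequential run: configuration (error rates, boundaries, global stop
#' percentage, truncation), stop volume, and classification counts.
#'
#' @param run An `sprt_run`.
#' @param path Output path; `NULL` returns the report list.
#' @param seed Optional seed to record.
#' @return The report list, invisibly when written.
#' @export
write_run_report <- function(run, path = NULL, seed = NULL) {
  stopifnot(inherits(run, "sprt_run"))
  counts <- table(factor(run$class_map[run$mask_index]))
  report <- list(
    package = "seqactivate",
    version = as.character(utils::packageVersion("seqactivate")),
    seed = seed,
    config = list(alpha = run$bounds$alpha, beta = run$bounds$beta,
                  n_tests = run$bounds$n_tests,
                  A = run$bounds$A, B = run$bounds$B,
                  truncation = run$truncation,
                  g_percent = run$g_percent,
                  hypotheses = vapply(run$hypotheses, `[[`,
                                      character(1), "label")),
    stop_volume = run$stop_volume,
    n_voxels = length(run$mask_index),
    n_decided = sum(rowSums(run$verdicts == "continue") == 0),
    class_counts = as.list(stats::setNames(as.integer(counts),
                                           names(counts))))
  if (is.null(path)) return(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(report)
}
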