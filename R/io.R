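# Plain-text readers/writers for the pipeline's inputs and outputs.

#' Write / read a photometry session as delimited text
#'
#' The trace file holds columns `time_s`, `f465`, `f405` (tab-separated);
#' the sidecar `<path>.events` holds the event log (`time_s`, `kind`,
#' `trial_id`, `excluded`).
#'
#' @param session A [photometry_session()].
#' @param path Trace file path.
#' @return `write_photometry_session` returns `path` invisibly;
#'   `read_photometry_session` returns a `photometry_session`.
#' @export
write_photometry_session <- function(session, path) {
  stopifnot(inherits(session, "photometry_session"))
  utils::write.table(
    data.frame(time_s = session$time_s, f465 = session$f_signal,
               f405 = session$f_iso),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(session$events, paste0(path, ".events"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_photometry_session
#' @param fs_hz Sampling rate; inferred from the median time step when
#'   `NULL`.
#' @export
read_photometry_session <- function(path, fs_hz = NULL) {
  d <- utils::read.delim(path)
  ev_path <- paste0(path, ".events")
  events <- if (file.exists(ev_path)) utils::read.delim(ev_path) else NULL
  if (!is.null(events) && !nrow(events)) events <- NULL
  if (is.null(fs_hz)) fs_hz <- 1 / stats::median(diff(d$time_s))
  photometry_session(d$time_s, d$f465, d$f405, fs_hz, events)
}

#' Write / read a behavioral event log
#'
#' Tab-separated columns `timestamp_s`, `event_type`, `trial_id`,
#' `block_id`, `laser_on`; unused fields are NA.
#'
#' @param log Data frame with the columns above (missing ones are added
#'   as NA).
#' @param path File path.
#' @export
write_event_log <- function(log, path) {
  cols <- c("timestamp_s", "event_type", "trial_id", "block_id", "laser_on")
  for (cn in setdiff(cols, names(log))) log[[cn]] <- NA
  utils::write.table(log[cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  utils::read.delim(path)
}

#' Write / read a position stream
#'
#' Tab-separated columns `t_s`, `x_cm`, `y_cm`, `chamber`.
#'
#' @param positions Data frame as produced by the place-preference
#'   simulator.
#' @param path File path.
#' @export
write_positions <- function(positions, path) {
  utils::write.table(positions[c("t_s", "x_cm", "y_cm", "chamber")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  utils::read.delim(path, colClasses = c("numeric", "numeric", "numeric",
                                         "character"))
}

#' Write / read a count matrix as a Matrix Market triplet
#'
#' Writes `<stem>.mtx` plus plain-text `<stem>.genes.txt` and
#' `<stem>.cells.txt` name lists (the GEO-style triplet layout).
#'
#' @param counts Sparse genes x cells matrix with dimnames.
#' @param stem Path stem (no extension).
#' @export
write_count_matrix <- function(counts, stem) {
  Matrix::writeMM(methods::as(methods::as(counts, "dMatrix"), "TsparseMatrix"),
                  paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(counts), paste0(stem, ".cells.txt"))
  invisible(stem)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(stem) {
  m <- Matrix::readMM(paste0(stem, ".mtx"))
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(stem, ".genes.txt")),
                      readLines(paste0(stem, ".cells.txt")))
  m
}
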