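# Tabular trace format and TIFF movie I/O.
#
# Trace tables are UTF-8, tab-delimited text with a mandatory header; one
# row per (molecule, frame); columns: molecule_id, frame, time_s,
# donor_counts, acceptor_counts, plus optional ex488_counts and flag
# columns. All result tables in the package use the same conventions.

#' Write / read a trace table
#'
#' @param traces Tibble in the package trace format.
#' @param path File path.
#' @return `read_trace_table()` returns a tibble; `write_trace_table()`
#'   returns `path` invisibly.
#' @export
write_trace_table <- function(traces, path) {
  utils::write.table(traces, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("molecule_id", "frame", "time_s", "donor_counts", "acceptor_counts")
  if (!all(need %in% names(df)))
    abort_spfret(paste("trace table must contain columns:",
                       paste(need, collapse = ", ")), "spfret_io_error")
  tibble::as_tibble(df)
}

#' Write / read a two-channel movie as multi-page TIFF
#'
#' The two channels are stored side-by-side on one chip (channel 1 left,
#' channel 2 right), one page per frame, mirroring dual-view detection on a
#' single camera. Counts are stored as 32-bit float.
#'
#' @param movie List with `channel1`, `channel2` arrays (`[row, col, frame]`).
#' @param path File path.
#' @return `read_movie_tiff()` returns a movie list; `write_movie_tiff()`
#'   returns `path` invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  n_frames <- dim(movie$channel1)[3]
  pages <- lapply(seq_len(n_frames), function(f)
    cbind(movie$channel1[, , f], movie$channel2[, , f]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nx2 <- ncol(pages[[1]])
  if (nx2 %% 2 != 0)
    abort_spfret("side-by-side movie must have an even chip width", "spfret_io_error")
  half <- nx2 / 2
  ch1 <- simplify2array(lapply(pages, function(p) p[, 1:half] * 65535))
  ch2 <- simplify2array(lapply(pages, function(p) p[, (half + 1):nx2] * 65535))
  list(channel1 = ch1, channel2 = ch2)
}

#' Write ground truth to a structured text file
#'
#' One record per molecule (tab-delimited with header), so recovery tests
#' and external tools can join on `molecule_id`.
#'
#' @param sim A `fret_sim`.
#' @param path File path.
#' @export
write_ground_truth <- function(sim, path) {
  utils::write.table(sim$ground_truth$molecules, path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
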