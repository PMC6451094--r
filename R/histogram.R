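# FRET-efficiency histograms (molecule-wise and frame-wise).

#' Build a FRET-efficiency histogram from values
#'
#' Core constructor: fixed contiguous bins on a FRET range, returning
#' counts and the density normalization used by the mixture fits.
#' Out-of-range values are dropped (and counted in the attribute
#' `"n_out_of_range"`).
#'
#' @param values Numeric FRET efficiencies (one per molecule or per frame).
#' @param mode `"molecule_wise"` or `"frame_wise"` (metadata).
#' @param binwidth Bin width in FRET efficiency (default 0.02).
#' @param range Histogram range (default [-0.1, 1.1]).
#' @param n_molecules Number of contributing molecules (metadata).
#' @return A `fret_histogram`: tibble with `mid`, `lower`, `upper`,
#'   `count`, `density`, and attributes `mode`, `binwidth`, `n_molecules`,
#'   `n_values`.
#' @export
fret_histogram <- function(values, mode = c("molecule_wise", "frame_wise"),
                           binwidth = 0.02, range = c(-0.1, 1.1),
                           n_molecules = NA_integer_) {
  mode <- match.arg(mode)
  values <- values[is.finite(values)]
  if (length(values) == 0)
    abort_spfret("no finite FRET values to histogram", "spfret_histogram_error")
  edges <- seq(range[1], range[2], by = binwidth)
  inside <- values >= range[1] & values <= range[2]
  counts <- graphics::hist(values[inside], breaks = edges, plot = FALSE)$counts
  out <- tibble::tibble(
    lower = edges[-length(edges)], upper = edges[-1],
    mid = (edges[-length(edges)] + edges[-1]) / 2,
    count = counts,
    density = counts / (sum(counts) * binwidth))
  structure(out, class = c("fret_histogram", class(out)),
            mode = mode, binwidth = binwidth,
            n_molecules = n_molecules, n_values = length(values),
            n_out_of_range = sum(!inside))
}

#' Build a histogram from corrected FRET traces
#'
#' Molecule-wise mode histograms one value per molecule: the mean corrected
#' E over the molecule's analysis window. Frame-wise mode histograms every
#' usable frame. By default molecule-wise histograms are built from static
#' molecules only (dynamic molecules average over states); pass a label
#' table to filter, or `include_dynamic = TRUE` to keep everything.
#'
#' @param fret FRET trace table from [compute_fret()].
#' @param mode `"molecule_wise"` or `"frame_wise"`.
#' @param labels Optional tibble `molecule_id`, `label`
#'   ("static"/"dynamic"), e.g. from [classify_traces()] or ground truth.
#' @param include_dynamic Keep dynamic molecules in molecule-wise mode.
#' @inheritParams fret_histogram
#' @return A `fret_histogram`.
#' @export
build_fret_histogram <- function(fret, mode = c("molecule_wise", "frame_wise"),
                                 labels = NULL, include_dynamic = FALSE,
                                 binwidth = 0.02, range = c(-0.1, 1.1)) {
  mode <- match.arg(mode)
  usable <- dplyr::filter(fret, .data$in_window, .data$valid)
  if (!is.null(labels) && mode == "molecule_wise" && !include_dynamic) {
    keep <- labels$molecule_id[labels$label == "static"]
    usable <- dplyr::filter(usable, .data$molecule_id %in% keep)
  }
  if (nrow(usable) == 0)
    abort_spfret("no usable frames", "spfret_histogram_error")
  if (mode == "molecule_wise") {
    vals <- usable |>
      dplyr::summarise(e = mean(.data$fret), .by = "molecule_id")
    fret_histogram(vals$e, mode = mode, binwidth = binwidth, range = range,
                   n_molecules = nrow(vals))
  } else {
    fret_histogram(usable$fret, mode = mode, binwidth = binwidth, range = range,
                   n_molecules = dplyr::n_distinct(usable$molecule_id))
  }
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat("<fret_histogram> ", attr(x, "mode"), ", ", attr(x, "n_values"),
      " values, ", nrow(x), " bins of width ", attr(x, "binwidth"), "\n", sep = "")
  NextMethod()
}
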