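# Transition density plots and subpopulation assignment.

#' Build a transition density plot (TDP)
#'
#' Superimposes each decoded transition as a unit-mass 2D Gaussian of fixed
#' width at (initial E, final E) on a regular grid over [0, 1]^2. The grid
#' integral equals the transition count up to kernel mass lost outside the
#' grid.
#'
#' @param transitions Tibble with columns `e_from`, `e_to` (e.g. bound
#'   rows of `decode_path()$transitions` over many molecules).
#' @param kernel_width SD of the 2D Gaussian kernel in FRET units
#'   (default 0.03).
#' @param grid_n Number of grid points per axis (default 101).
#' @return A `fret_tdp`: list with `x`, `y` (grid coordinates), `density`
#'   (matrix, rows = initial E), `n_transitions`, `kernel_width`.
#' @export
build_tdp <- function(transitions, kernel_width = 0.03, grid_n = 101) {
  if (nrow(transitions) == 0)
    abort_spfret("no transitions to plot", "spfret_tdp_error")
  g <- seq(0, 1, length.out = grid_n)
  dens <- matrix(0, grid_n, grid_n)
  for (i in seq_len(nrow(transitions))) {
    kx <- dnorm(g, transitions$e_from[i], kernel_width)
    ky <- dnorm(g, transitions$e_to[i], kernel_width)
    dens <- dens + outer(kx, ky)
  }
  structure(list(x = g, y = g, density = dens,
                 n_transitions = nrow(transitions),
                 kernel_width = kernel_width),
            class = "fret_tdp")
}

#' @export
print.fret_tdp <- function(x, ...) {
  cat("<fret_tdp> ", x$n_transitions, " transitions, ", length(x$x), "x",
      length(x$y), " grid, kernel ", x$kernel_width, "\n", sep = "")
  invisible(x)
}

#' Integrate TDP density over a rectangular gate
#'
#' @param tdp A `fret_tdp`.
#' @param from_range,to_range Initial/final FRET intervals.
#' @return Integrated density mass (in transitions).
#' @export
tdp_gate_mass <- function(tdp, from_range, to_range) {
  dx <- tdp$x[2] - tdp$x[1]
  ix <- tdp$x >= from_range[1] & tdp$x <= from_range[2]
  iy <- tdp$y >= to_range[1] & tdp$y <= to_range[2]
  sum(tdp$density[ix, iy]) * dx^2
}

#' Rectangular TDP gates from subpopulation state templates
#'
#' Builds, for each subpopulation, the gate set of adjacent-state
#' transitions of a linear chain (S1<->S2, S2<->S3, both directions):
#' rectangles of half-width `half_width` around the (from, to) state-mean
#' pairs.
#'
#' @param templates Tibble with `subpop`, `state`, `mean` (e.g. a condition
#'   subset of [tbp_framewise_states()]).
#' @param half_width Gate half-width in FRET units.
#'   Keep it below half the smallest cross-subpopulation gate distance.
#' @return Tibble of gates: `subpop`, `from_lo/hi`, `to_lo/hi`,
#'   `from_mean`, `to_mean`.
#' @export
subpop_gates <- function(templates, half_width = 0.05) {
  templates |>
    dplyr::group_by(.data$subpop) |>
    dplyr::arrange(.data$state, .by_group = TRUE) |>
    dplyr::group_map(function(tt, key) {
      m <- tt$mean
      pairs <- do.call(rbind, lapply(seq_len(length(m) - 1), function(i)
        rbind(c(m[i], m[i + 1]), c(m[i + 1], m[i]))))
      tibble::tibble(subpop = key$subpop,
                     from_mean = pairs[, 1], to_mean = pairs[, 2],
                     from_lo = pairs[, 1] - half_width,
                     from_hi = pairs[, 1] + half_width,
                     to_lo = pairs[, 2] - half_width,
                     to_hi = pairs[, 2] + half_width)
    }) |>
    dplyr::bind_rows()
}

gates_overlap <- function(gates) {
  n <- nrow(gates)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (gates$subpop[i] == gates$subpop[j]) next
    if (gates$from_lo[i] < gates$from_hi[j] && gates$from_lo[j] < gates$from_hi[i] &&
        gates$to_lo[i] < gates$to_hi[j] && gates$to_lo[j] < gates$to_hi[i])
      return(TRUE)
  }
  FALSE
}

#' Auto-seeded gates from k-means on transition coordinates
#'
#' Convenience alternative to template gates: clusters the (from, to)
#' coordinates with k-means and puts a rectangle of half-width
#' `half_width` around each center. Each cluster becomes its own gate
#' label; group them into subpopulations by renaming `subpop`.
#'
#' @param transitions Tibble with `e_from`, `e_to`.
#' @param k Number of clusters.
#' @param half_width Gate half-width.
#' @param seed Seed for k-means.
#' @return Gate tibble as in [subpop_gates()].
#' @export
gates_from_kmeans <- function(transitions, k, half_width = 0.07, seed = 1L) {
  km <- with_seed(substream_seed(seed, "gates", 0L),
    kmeans(cbind(transitions$e_from, transitions$e_to), k, nstart = 10))
  tibble::tibble(subpop = paste0("C", seq_len(k)),
                 from_mean = km$centers[, 1], to_mean = km$centers[, 2],
                 from_lo = km$centers[, 1] - half_width,
                 from_hi = km$centers[, 1] + half_width,
                 to_lo = km$centers[, 2] - half_width,
                 to_hi = km$centers[, 2] + half_width)
}

#' Assign molecules to subpopulations by gated transitions
#'
#' Each molecule is assigned to the subpopulation whose gate set captures
#' the largest share of its decoded transitions, provided that share
#' exceeds `min_fraction`; molecules with split membership or no
#' transitions stay unassigned. Assignment is per molecule and fixed: no
#' molecule changes label within a run.
#'
#' @param transitions Tibble with `molecule_id`, `e_from`, `e_to` (decoded
#'   transitions of all molecules).
#' @param gates Gate tibble from [subpop_gates()] or [gates_from_kmeans()];
#'   gates of different subpopulations must not overlap.
#' @param min_fraction Minimum captured share for a call (default 0.5).
#' @return Tibble: `molecule_id`, `subpop` ("unassigned" when no gate set
#'   wins), `n_transitions`, `capture_fraction`.
#' @export
assign_subpopulations <- function(transitions, gates, min_fraction = 0.5) {
  if (gates_overlap(gates))
    abort_spfret("gates of different subpopulations overlap", "spfret_config_error")
  subs <- unique(gates$subpop)
  in_gate_set <- function(ef, et, g) {
    hit <- rep(FALSE, length(ef))
    for (i in seq_len(nrow(g)))
      hit <- hit | (ef >= g$from_lo[i] & ef <= g$from_hi[i] &
                    et >= g$to_lo[i] & et <= g$to_hi[i])
    hit
  }
  transitions |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_map(function(tr, key) {
      n <- nrow(tr)
      if (n == 0)
        return(tibble::tibble(molecule_id = key$molecule_id,
                              subpop = "unassigned", n_transitions = 0L,
                              capture_fraction = NA_real_))
      frac <- vapply(subs, function(s)
        mean(in_gate_set(tr$e_from, tr$e_to, gates[gates$subpop == s, ])),
        numeric(1))
      best <- which.max(frac)
      tibble::tibble(molecule_id = key$molecule_id,
                     subpop = if (frac[best] > min_fraction) subs[best] else "unassigned",
                     n_transitions = n, capture_fraction = frac[best])
    }) |>
    dplyr::bind_rows()
}
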