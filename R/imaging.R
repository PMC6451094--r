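# Dual-view channel registration and single-molecule photometry.
#
# Image convention: a channel frame is a numeric matrix indexed [row, col];
# pixel centers sit at integer, 0-based (x, y) coordinates with the origin
# at the top-left, x = col - 1, y = row - 1.

#' Estimate the map between the two spectral channels from beads
#'
#' Least-squares transform taking channel-1 bead centroids onto channel-2
#' centroids, as measured from images of fluorescent beads visible in both
#' channels. Accepts either a bead stack produced by [sim_bead_stack()] (or
#' the same structure from real data) -- in which case beads are detected
#' and paired by mutual proximity -- or a data frame of matched control
#' points with columns `x1, y1, x2, y2`.
#'
#' @param beads Bead stack (list with `channel1`, `channel2` matrices) or a
#'   matched control-point data frame.
#' @param kind `"translation"`, `"affine"` (default) or `"polynomial"`
#'   (full second-order).
#' @param threshold,min_separation Passed to [detect_spots()] when beads
#'   must be detected first.
#' @return A `channel_map` object with elements `kind`, `coef` (2-row
#'   coefficient matrix), `residual` (RMS over control points, px) and
#'   `n_points`.
#' @export
estimate_channel_map <- function(beads, kind = c("affine", "translation", "polynomial"),
                                 threshold = NULL, min_separation = 4) {
  kind <- match.arg(kind)
  pts <- if (is.data.frame(beads)) {
    tibble::as_tibble(beads)
  } else {
    s1 <- detect_spots(beads$channel1, threshold = threshold,
                       min_separation = min_separation)
    s2 <- detect_spots(beads$channel2, threshold = threshold,
                       min_separation = min_separation)
    match_points(s1, s2)
  }
  min_needed <- c(translation = 1, affine = 3, polynomial = 6)[[kind]]
  if (nrow(pts) < min_needed)
    abort_spfret(sprintf("need >= %d bead pairs for a %s map", min_needed, kind),
                 "spfret_map_error")
  basis <- function(x, y) switch(kind,
    translation = cbind(1, x * 0),      # intercept only; slope column dropped below
    affine = cbind(1, x, y),
    polynomial = cbind(1, x, y, x * y, x^2, y^2))
  if (kind == "translation") {
    # median offsets: robust to occasional mismatched bead pairs
    coef <- rbind(c(median(pts$x2 - pts$x1), 1, 0),
                  c(median(pts$y2 - pts$y1), 0, 1))
    pred <- cbind(pts$x1 + coef[1, 1], pts$y1 + coef[2, 1])
  } else {
    X <- basis(pts$x1, pts$y1)
    if (qr(X)$rank < ncol(X))
      abort_spfret("degenerate (collinear) bead layout", "spfret_map_error")
    cx <- qr.solve(X, pts$x2)
    cy <- qr.solve(X, pts$y2)
    coef <- rbind(cx, cy)
    pred <- cbind(X %*% cx, X %*% cy)
  }
  res <- sqrt(mean((pred[, 1] - pts$x2)^2 + (pred[, 2] - pts$y2)^2))
  structure(list(kind = kind, coef = coef, residual = res, n_points = nrow(pts)),
            class = "channel_map")
}

# Pair detected spot lists by mutual nearest neighbour: a pair is kept
# only when each spot is the other's closest match, which discards
# ambiguous pairings in crowded fields.
match_points <- function(s1, s2, max_dist = 10) {
  if (nrow(s1) == 0 || nrow(s2) == 0)
    abort_spfret("no beads detected in one of the channels", "spfret_map_error")
  d <- outer(s1$x, s2$x, "-")^2 + outer(s1$y, s2$y, "-")^2
  j <- apply(d, 1, which.min)           # best ch2 partner of each ch1 spot
  i_back <- apply(d, 2, which.min)      # best ch1 partner of each ch2 spot
  keep <- i_back[j] == seq_len(nrow(s1)) &
    sqrt(d[cbind(seq_len(nrow(s1)), j)]) <= max_dist
  if (!any(keep))
    abort_spfret("no mutually matched bead pairs", "spfret_map_error")
  tibble::tibble(x1 = s1$x[keep], y1 = s1$y[keep],
                 x2 = s2$x[j[keep]], y2 = s2$y[j[keep]])
}

#' Apply a channel map to reference-channel coordinates
#'
#' @param map A `channel_map`.
#' @param xy Two-column matrix or data frame of (x, y) positions.
#' @return Matrix of mapped (x, y) positions.
#' @export
apply_channel_map <- function(map, xy) {
  stopifnot(inherits(map, "channel_map"))
  xy <- as.matrix(xy)
  x <- xy[, 1]; y <- xy[, 2]
  X <- switch(map$kind,
    translation = cbind(1, x, y),
    affine = cbind(1, x, y),
    polynomial = cbind(1, x, y, x * y, x^2, y^2))
  cbind(X %*% map$coef[1, ], X %*% map$coef[2, ])
}

#' @export
print.channel_map <- function(x, ...) {
  cat("<channel_map> ", x$kind, ", ", x$n_points, " control points, RMS residual ",
      signif(x$residual, 3), " px\n", sep = "")
  invisible(x)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n, dim) {
    if (dim == 1) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), , drop = FALSE]
    else m[, c(rep(1, n), seq_len(ncol(m)), rep(ncol(m), n)), drop = FALSE]
  }
  m <- pad(img, r, 1)
  out <- matrix(0, nrow(img), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * m[seq_len(nrow(img)) + i - 1L, , drop = FALSE]
  m <- pad(out, r, 2)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) out2 <- out2 + k[i] * m[, seq_len(ncol(img)) + i - 1L, drop = FALSE]
  out2
}

#' Detect single-molecule spots in a summed or averaged image
#'
#' Local maxima above a threshold after light Gaussian smoothing, with
#' non-maximum suppression at `min_separation` (when two maxima are closer,
#' only the brighter is kept) and sub-pixel refinement by intensity-weighted
#' centroid.
#'
#' @param image Numeric matrix (one channel).
#' @param threshold Minimum smoothed peak intensity; default: image median
#'   plus 5 MAD.
#' @param min_separation Minimum peak separation in px.
#' @param smooth_sigma Gaussian smoothing SD in px.
#' @return Tibble of spots: `x`, `y` (0-based px), `peak`, `background`.
#' @export
detect_spots <- function(image, threshold = NULL, min_separation = 4,
                         smooth_sigma = 1) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  sm <- gaussian_blur(image, smooth_sigma)
  if (is.null(threshold))
    threshold <- median(sm) + 5 * mad(sm)
  ny <- nrow(sm); nx <- ncol(sm)
  if (ny < 3 || nx < 3) return(empty_spots())
  inner <- sm[2:(ny - 1), 2:(nx - 1)]
  is_max <- inner > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & inner >= sm[2:(ny - 1) + dy, 2:(nx - 1) + dx]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_spots())
  cand <- tibble::tibble(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                         val = sm[cbind(idx[, 1] + 1L, idx[, 2] + 1L)]) |>
    dplyr::arrange(dplyr::desc(.data$val))
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      d2 <- (cand$row[later] - cand$row[i])^2 + (cand$col[later] - cand$col[i])^2
      keep[later][d2 < min_separation^2] <- FALSE
    }
  }
  cand <- cand[keep, ]
  # sub-pixel refinement: three-point Gaussian (log-parabolic)
  # interpolation per axis, exact for a Gaussian profile
  interp1 <- function(m1, p0, p1) {
    lm1 <- log(max(m1, 1e-12)); l0 <- log(max(p0, 1e-12))
    lp1 <- log(max(p1, 1e-12))
    den <- lm1 - 2 * l0 + lp1
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (lm1 - lp1) / den))
  }
  floor_val <- min(sm)
  refine <- function(row, col) {
    dx <- if (col > 1 && col < nx)
      interp1(sm[row, col - 1] - floor_val, sm[row, col] - floor_val,
              sm[row, col + 1] - floor_val) else 0
    dy <- if (row > 1 && row < ny)
      interp1(sm[row - 1, col] - floor_val, sm[row, col] - floor_val,
              sm[row + 1, col] - floor_val) else 0
    c(x = col - 1L + dx, y = row - 1L + dy)
  }
  cent <- t(mapply(refine, cand$row, cand$col))
  tibble::tibble(x = cent[, 1], y = cent[, 2], peak = cand$val,
                 background = median(image))
}

empty_spots <- function() {
  tibble::tibble(x = numeric(), y = numeric(), peak = numeric(),
                 background = numeric())
}

aperture_pixels <- function(x0, y0, radius, ny, nx, outer = NULL) {
  # integer pixel coordinates (0-based) within the disc, or the annulus
  # radius..outer when `outer` is given
  r <- ceiling(if (is.null(outer)) radius else outer)
  gx <- (round(x0) - r):(round(x0) + r)
  gy <- (round(y0) - r):(round(y0) + r)
  g <- expand.grid(x = gx, y = gy)
  d <- sqrt((g$x - x0)^2 + (g$y - y0)^2)
  sel <- if (is.null(outer)) d <= radius else d > radius & d <= outer
  g <- g[sel, , drop = FALSE]
  inside <- g$x >= 0 & g$x < nx & g$y >= 0 & g$y < ny
  list(g = g[inside, , drop = FALSE], clipped = any(!inside))
}

#' Extract two-channel intensity traces by aperture photometry
#'
#' For every detected molecule, sums counts in a circular aperture around
#' the reference-channel (donor) position and around the mapped position in
#' the second channel, subtracting a local background estimated as the
#' median annulus pixel value times the aperture area, frame by frame.
#' Frames are demultiplexed according to the excitation scheme. Molecules
#' whose aperture or mapped aperture leaves the image are dropped; the
#' dropped ids and reasons are attached as attribute `"dropped"`.
#'
#' @param movie List with `channel1`, `channel2`: arrays `[row, col, frame]`.
#' @param spots Spot table from [detect_spots()] (reference channel).
#' @param map A `channel_map` from channel 1 to channel 2.
#' @param aperture_radius Aperture radius in px.
#' @param annulus Inner/outer radius of the background annulus in px.
#' @param frame_time Frame time in seconds, stored in the output.
#' @param excitation_scheme `"single"` (all frames donor excitation),
#'   `"alternating_488_532"` (odd frames 532 nm, even frames 488 nm; the
#'   488-frame green-channel signal is returned as `ex488_counts`) or
#'   `"red_after_frame10"` (first 10 frames 532 nm, then direct red
#'   excitation).
#' @return Tibble in the package trace format: `molecule_id`, `frame`,
#'   `time_s`, `donor_counts`, `acceptor_counts` (+ `ex488_counts` for the
#'   alternating scheme, `excitation` for the red-switch scheme).
#' @export
extract_traces <- function(movie, spots, map, aperture_radius = 3,
                           annulus = c(5, 7), frame_time = 0.015,
                           excitation_scheme = c("single", "alternating_488_532",
                                                 "red_after_frame10")) {
  excitation_scheme <- match.arg(excitation_scheme)
  stopifnot(inherits(map, "channel_map"))
  ny <- dim(movie$channel1)[1]; nx <- dim(movie$channel1)[2]
  n_frames <- dim(movie$channel1)[3]
  mapped <- apply_channel_map(map, cbind(spots$x, spots$y))
  dropped <- tibble::tibble(molecule_id = integer(), reason = character())
  out <- vector("list", nrow(spots))
  for (i in seq_len(nrow(spots))) {
    ap1 <- aperture_pixels(spots$x[i], spots$y[i], aperture_radius, ny, nx)
    ap2 <- aperture_pixels(mapped[i, 1], mapped[i, 2], aperture_radius, ny, nx)
    an1 <- aperture_pixels(spots$x[i], spots$y[i], annulus[1], ny, nx, annulus[2])
    an2 <- aperture_pixels(mapped[i, 1], mapped[i, 2], annulus[1], ny, nx, annulus[2])
    if (ap1$clipped || ap2$clipped || nrow(an1$g) == 0 || nrow(an2$g) == 0) {
      dropped <- dplyr::bind_rows(dropped,
        tibble::tibble(molecule_id = i, reason = "aperture outside image"))
      next
    }
    photometry <- function(stack, ap, an) {
      ap_idx <- cbind(ap$g$y + 1L, ap$g$x + 1L)
      an_idx <- cbind(an$g$y + 1L, an$g$x + 1L)
      vapply(seq_len(n_frames), function(f) {
        fr <- stack[, , f]
        sum(fr[ap_idx]) - median(fr[an_idx]) * nrow(ap_idx)
      }, numeric(1))
    }
    ch1 <- photometry(movie$channel1, ap1, an1)
    ch2 <- photometry(movie$channel2, ap2, an2)
    frames <- seq_len(n_frames)
    tr <- switch(excitation_scheme,
      single = tibble::tibble(
        molecule_id = i, frame = frames, time_s = (frames - 1) * frame_time,
        donor_counts = ch1, acceptor_counts = ch2),
      alternating_488_532 = {
        f532 <- frames[frames %% 2 == 1L]
        f488 <- frames[frames %% 2 == 0L]
        n <- min(length(f532), length(f488))
        tibble::tibble(
          molecule_id = i, frame = f532[seq_len(n)],
          time_s = (f532[seq_len(n)] - 1) * frame_time,
          donor_counts = ch1[f532[seq_len(n)]],
          acceptor_counts = ch2[f532[seq_len(n)]],
          ex488_counts = ch1[f488[seq_len(n)]])
      },
      red_after_frame10 = tibble::tibble(
        molecule_id = i, frame = frames, time_s = (frames - 1) * frame_time,
        donor_counts = ch1, acceptor_counts = ch2,
        excitation = ifelse(frames <= 10L, "532", "red")))
    out[[i]] <- tr
  }
  res <- dplyr::bind_rows(out)
  attr(res, "dropped") <- dropped
  res
}
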