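# Synthetic image stacks: beads for registration, movies for extraction.

render_psf <- function(img, x0, y0, amplitude, sigma) {
  ny <- nrow(img); nx <- ncol(img)
  r <- ceiling(4 * sigma)
  cols <- max(0, round(x0) - r):min(nx - 1, round(x0) + r)
  rows <- max(0, round(y0) - r):min(ny - 1, round(y0) + r)
  if (length(cols) == 0 || length(rows) == 0) return(img)
  gx <- exp(-(cols - x0)^2 / (2 * sigma^2))
  gy <- exp(-(rows - y0)^2 / (2 * sigma^2))
  img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
    amplitude * outer(gy, gx)
  img
}

#' Simulate a two-channel fluorescent-bead image
#'
#' Places beads at random positions in channel 1 and at the mapped
#' positions in channel 2, renders Gaussian point-spread profiles and adds
#' background plus Gaussian noise. Used to exercise channel-map estimation
#' with a known ground-truth transform.
#'
#' @param true_map A `channel_map` giving the ground-truth transform, e.g.
#'   from [make_channel_map()].
#' @param n_beads Number of beads (>= 3 for affine estimation downstream).
#' @param nx,ny Channel image size in px.
#' @param intensity Peak bead amplitude in counts.
#' @param psf_sigma PSF SD in px.
#' @param background Constant background counts.
#' @param noise_sd Gaussian noise SD in counts (0 for a noiseless image).
#' @param margin Border kept free of bead centers, px.
#' @param min_separation Minimum bead spacing, px (bead slides are sparse).
#' @param seed Integer seed.
#' @return List with `channel1`, `channel2` (matrices) and `positions`
#'   (tibble `x1, y1, x2, y2` of true centers).
#' @export
sim_bead_stack <- function(true_map, n_beads = 10, nx = 64, ny = 64,
                           intensity = 1000, psf_sigma = 1.2,
                           background = 10, noise_sd = 2, margin = 8,
                           min_separation = 8, seed = 1L) {
  if (n_beads < 3)
    abort_spfret("need at least 3 beads for downstream map estimation",
                 "spfret_config_error")
  with_seed(substream_seed(seed, "beads", 0L), {
    x1 <- numeric(0); y1 <- numeric(0)
    tries <- 0
    while (length(x1) < n_beads && tries < 20000) {
      tries <- tries + 1
      px <- runif(1, margin, nx - 1 - margin)
      py <- runif(1, margin, ny - 1 - margin)
      if (!length(x1) ||
          min((x1 - px)^2 + (y1 - py)^2) >= min_separation^2) {
        x1 <- c(x1, px); y1 <- c(y1, py)
      }
    }
    if (length(x1) < n_beads)
      abort_spfret("could not place beads at the requested separation",
                   "spfret_config_error")
    m2 <- apply_channel_map(true_map, cbind(x1, y1))
    ch1 <- matrix(background, ny, nx)
    ch2 <- matrix(background, ny, nx)
    for (i in seq_len(n_beads)) {
      ch1 <- render_psf(ch1, x1[i], y1[i], intensity, psf_sigma)
      ch2 <- render_psf(ch2, m2[i, 1], m2[i, 2], intensity, psf_sigma)
    }
    if (noise_sd > 0) {
      ch1 <- ch1 + rnorm(length(ch1), 0, noise_sd)
      ch2 <- ch2 + rnorm(length(ch2), 0, noise_sd)
    }
    list(channel1 = ch1, channel2 = ch2,
         positions = tibble::tibble(x1 = x1, y1 = y1, x2 = m2[, 1], y2 = m2[, 2]))
  })
}

#' Construct a channel map from known parameters
#'
#' @param kind `"translation"` or `"affine"`.
#' @param dx,dy Translation components, px.
#' @param a Optional full 2x3 affine coefficient matrix (rows = x', y';
#'   columns = intercept, x, y); overrides `dx`/`dy`.
#' @return A `channel_map`.
#' @export
#' @examples
#' make_channel_map(dx = 3.2, dy = -1.7)
make_channel_map <- function(kind = c("translation", "affine"), dx = 0, dy = 0,
                             a = NULL) {
  kind <- match.arg(kind)
  coef <- if (!is.null(a)) { kind <- "affine"; a } else
    rbind(c(dx, 1, 0), c(dy, 0, 1))
  structure(list(kind = kind, coef = coef, residual = 0, n_points = 0L),
            class = "channel_map")
}

#' Render a simulated trace set into a two-channel movie
#'
#' Places each molecule of a [sim_traces()] result at a random position in
#' the reference channel and renders its per-frame donor/acceptor counts as
#' Gaussian PSFs into the two channels (acceptor positions through the
#' channel map), adding background and Gaussian camera noise at the image
#' level. The trace background is not re-added: the movie's own pedestal
#' plays that role.
#'
#' @param sim A `fret_sim` from [sim_traces()] (trace counts are treated as
#'   total aperture counts above background).
#' @param map `channel_map` from channel 1 to channel 2.
#' @param nx,ny Channel size in px.
#' @param psf_sigma PSF SD in px.
#' @param background Pedestal counts per pixel.
#' @param noise_sd Per-pixel Gaussian noise SD.
#' @param margin Border kept free of molecules, px.
#' @param min_separation Minimum distance between molecule centers, px
#'   (surface densities in these experiments keep spots well separated).
#' @param seed Integer seed for positions and pixel noise.
#' @return List with `channel1`, `channel2` (`[row, col, frame]` arrays) and
#'   `positions` (true molecule positions, reference channel).
#' @export
sim_movie <- function(sim, map = make_channel_map(), nx = 64, ny = 64,
                      psf_sigma = 1.2, background = 5, noise_sd = 0,
                      margin = 8, min_separation = 6, seed = sim$config$seed) {
  mols <- unique(sim$traces$molecule_id)
  n_frames <- max(sim$traces$frame)
  with_seed(substream_seed(seed, "movie", 0L), {
    x1 <- numeric(0); y1 <- numeric(0)
    tries <- 0
    while (length(x1) < length(mols) && tries < 10000) {
      tries <- tries + 1
      px <- runif(1, margin, nx - 1 - margin)
      py <- runif(1, margin, ny - 1 - margin)
      if (!length(x1) ||
          min((x1 - px)^2 + (y1 - py)^2) >= min_separation^2) {
        x1 <- c(x1, px); y1 <- c(y1, py)
      }
    }
    if (length(x1) < length(mols))
      abort_spfret("could not place molecules at the requested separation",
                   "spfret_config_error")
    m2 <- apply_channel_map(map, cbind(x1, y1))
    # PSF unit mass: amplitude scaling so the aperture sum matches counts
    norm <- 2 * pi * psf_sigma^2
    ch1 <- array(background, c(ny, nx, n_frames))
    ch2 <- array(background, c(ny, nx, n_frames))
    bg <- sim$config$background
    for (k in seq_along(mols)) {
      tr <- sim$traces[sim$traces$molecule_id == mols[k], ]
      for (f in seq_len(nrow(tr))) {
        d <- max(tr$donor_counts[f] - bg["donor"], 0)
        a <- max(tr$acceptor_counts[f] - bg["acceptor"], 0)
        ch1[, , tr$frame[f]] <- render_psf(ch1[, , tr$frame[f]], x1[k], y1[k],
                                           d / norm, psf_sigma)
        ch2[, , tr$frame[f]] <- render_psf(ch2[, , tr$frame[f]], m2[k, 1], m2[k, 2],
                                           a / norm, psf_sigma)
      }
    }
    if (noise_sd > 0) {
      ch1 <- ch1 + rnorm(length(ch1), 0, noise_sd)
      ch2 <- ch2 + rnorm(length(ch2), 0, noise_sd)
    }
    list(channel1 = ch1, channel2 = ch2,
         positions = tibble::tibble(molecule_id = mols, x = x1, y = y1))
  })
}
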