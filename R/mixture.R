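# Constrained Gaussian mixture fits of FRET histograms.
#
# Following the field's practice, mixtures are fit by nonlinear least
# squares on the binned histogram (not by EM on raw values); an EM fit is
# used as an independent cross-check in the tests only.

mixture_density <- function(x, w, mu, sd) {
  rowSums(vapply(seq_along(w),
                 function(j) w[j] * dnorm(x, mu[j], sd[j]),
                 numeric(length(x))))
}

mixture_starts <- function(hist, k) {
  # weighted quantile-spread means from the histogram itself
  cw <- cumsum(hist$count) / sum(hist$count)
  mu0 <- vapply((seq_len(k) - 0.5) / k,
                function(q) hist$mid[which(cw >= q)[1]], numeric(1))
  list(w = rep(1 / k, k), mu = mu0, sd = rep(0.05, k))
}

mixture_starts_kmeans <- function(hist, k, seed = 1L) {
  # k-means on count-weighted bin centers: lands near the histogram modes
  # and seeds weights/widths from the cluster masses/spreads
  x <- rep(hist$mid, times = pmax(round(hist$count), 0))
  if (length(unique(x)) < k) return(NULL)
  km <- with_seed(substream_seed(seed, "mixstart", k),
                  kmeans(x, centers = k, nstart = 10))
  ord <- order(km$centers)
  sds <- vapply(seq_len(k), function(j) {
    s <- sd(x[km$cluster == j])
    if (!is.finite(s) || s < 0.02) 0.02 else s
  }, numeric(1))
  list(w = (km$size / length(x))[ord],
       mu = as.numeric(km$centers)[ord], sd = sds[ord])
}

warn_if_degenerate <- function(mu, sd) {
  if (length(mu) < 2) return(invisible())
  d <- outer(mu, mu, function(a, b) abs(a - b))
  s <- outer(sd, sd, pmin)
  diag(d) <- Inf
  if (any(d < s))
    rlang::warn("mixture components closer than one SD: fit may be degenerate",
                class = "spfret_degenerate_mixture")
}

new_mixture_fit <- function(components, r_squared, residuals, fitted, hist,
                            fit_mode, info) {
  structure(list(components = components, r_squared = r_squared,
                 residuals = residuals, fitted = fitted, hist = hist,
                 fit_mode = fit_mode, info = info),
            class = "fret_mixture_fit")
}

#' Fit a Gaussian mixture to a FRET histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints) of a
#' sum of Gaussians to the histogram density over bin centers. Components
#' are returned sorted by mean with areas in % of the total.
#'
#' @param hist A `fret_histogram`.
#' @param n_components Number of Gaussian components.
#' @param start Optional list with `w`, `mu`, `sd` start vectors.
#' @param n_restarts Additional jittered restarts; the best SSE wins.
#' @param sd_bounds Lower/upper bounds on component SDs. The lower bound
#'   (default 0.03) keeps components at least as wide as the shot-noise
#'   floor of a FRET population, preventing single-bin spike solutions.
#' @param seed Seed for the restart jitter.
#' @return A `fret_mixture_fit` with `components` (tibble: `component`,
#'   `area` %, `mean`, `sd`), `r_squared`, residuals and fit diagnostics.
#'   Near-degenerate solutions (means closer than one SD) raise a warning.
#' @export
#' @examples
#' comps <- dplyr::filter(tbp_molwise_states(), condition == "dna_tbp")
#' vals <- sim_molecule_fret(comps, 1000, seed = 1)
#' h <- fret_histogram(vals$e_mol)
#' fit <- fit_fret_mixture(h, 2)
#' tidy(fit)
fit_fret_mixture <- function(hist, n_components, start = NULL, n_restarts = 4,
                             sd_bounds = c(0.03, 0.5), seed = 1L) {
  stopifnot(inherits(hist, "fret_histogram"), n_components >= 1)
  occupied <- sum(hist$count > 0)
  if (occupied <= 3 * n_components)
    abort_spfret("too few occupied bins for the requested components",
                 "spfret_fit_error")
  x <- hist$mid
  y <- hist$density
  k <- n_components
  unpack <- function(p) list(w = p[1:k], mu = p[k + 1:k], sd = p[2 * k + 1:k])
  resid_fn <- function(p) {
    q <- unpack(p)
    y - mixture_density(x, q$w, q$mu, q$sd)
  }
  lower <- c(rep(0, k), rep(min(x), k), rep(sd_bounds[1], k))
  upper <- c(rep(Inf, k), rep(max(x), k), rep(sd_bounds[2], k))
  base_starts <- if (!is.null(start)) list(start) else {
    c(list(mixture_starts(hist, k)),
      Filter(Negate(is.null), list(mixture_starts_kmeans(hist, k, seed))))
  }
  starts <- lapply(base_starts, function(s) c(s$w, s$mu, s$sd))
  if (n_restarts > 0) {
    jit <- with_seed(substream_seed(seed, "mixfit", 0L),
      lapply(seq_len(n_restarts), function(i) {
        s0 <- base_starts[[1 + (i - 1) %% length(base_starts)]]
        c(s0$w * exp(rnorm(k, 0, 0.3)),
          pmin(pmax(s0$mu + rnorm(k, 0, 0.05), min(x)), max(x)),
          pmin(pmax(s0$sd * exp(rnorm(k, 0, 0.3)), sd_bounds[1]), sd_bounds[2]))
      }))
    starts <- c(starts, jit)
  }
  best <- NULL
  for (p0 in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(p0, lower, upper, resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best))
    abort_spfret("mixture fit failed to converge from any start", "spfret_fit_error")
  q <- unpack(best$par)
  ord <- order(q$mu)
  warn_if_degenerate(q$mu, q$sd)
  fitted <- mixture_density(x, q$w, q$mu, q$sd)
  r2 <- r_squared(y, fitted)
  comps <- tibble::tibble(component = seq_len(k),
                          area = 100 * q$w[ord] / sum(q$w),
                          mean = q$mu[ord], sd = q$sd[ord])
  new_mixture_fit(comps, r2, y - fitted, fitted, hist, "free",
                  list(deviance = best$deviance, niter = best$niter,
                       converged = best$info %in% 1:4))
}

r_squared <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    abort_spfret("zero-variance histogram: R^2 undefined", "spfret_fit_error")
  1 - sum((y - fitted)^2) / ss_tot
}

#' Global amplitude-only mixture fit across several histograms
#'
#' Joint least-squares fit of a shared set of Gaussian states to several
#' histograms: peak positions and widths are fixed, only the amplitudes
#' vary freely per histogram. A small per-histogram shift of the peak
#' positions (at most `max_shift`) is allowed when necessary, reflecting
#' slightly different background corrections between measurements.
#'
#' @param hists List of `fret_histogram` objects.
#' @param components Data frame with fixed `mean` and `sd` per state (e.g.
#'   [tbp_global_states()]).
#' @param max_shift Maximum allowed shift of each state mean per histogram
#'   (FRET efficiency; default 0.01, 0 for strictly fixed positions).
#' @param merge Optional list of integer vectors: state indices whose areas
#'   are reported combined (e.g. a low-FRET main peak and its shoulder).
#' @return List of `fret_mixture_fit` objects (one per histogram), each
#'   with the fixed (possibly shifted) means and an `r_squared`.
#' @export
global_amplitude_fit <- function(hists, components, max_shift = 0.01,
                                 merge = NULL) {
  stopifnot(length(hists) >= 1)
  components <- tibble::as_tibble(components)
  k <- nrow(components)
  H <- length(hists)
  x_list <- lapply(hists, function(h) h$mid)
  y_list <- lapply(hists, function(h) h$density)
  # parameters: H*k weights, then H*k per-histogram mean shifts
  resid_fn <- function(p) {
    unlist(lapply(seq_len(H), function(h) {
      w <- p[(h - 1) * k + 1:k]
      shifts <- p[H * k + (h - 1) * k + 1:k]
      y_list[[h]] - mixture_density(x_list[[h]], w,
                                    components$mean + shifts, components$sd)
    }))
  }
  p0 <- c(rep(1 / k, H * k), rep(0, H * k))
  lower <- c(rep(0, H * k), rep(-max_shift, H * k))
  upper <- c(rep(Inf, H * k), rep(max_shift, H * k))
  fit <- minpack.lm::nls.lm(p0, lower, upper, resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 1000))
  lapply(seq_len(H), function(h) {
    w <- fit$par[(h - 1) * k + 1:k]
    shifts <- fit$par[H * k + (h - 1) * k + 1:k]
    mu <- components$mean + shifts
    fitted <- mixture_density(x_list[[h]], w, mu, components$sd)
    comps <- tibble::tibble(component = seq_len(k),
                            area = 100 * w / sum(w),
                            mean = mu, sd = components$sd)
    if (!is.null(merge)) {
      for (grp in merge) {
        i0 <- min(grp)
        comps$area[comps$component == i0] <- sum(comps$area[comps$component %in% grp])
        comps <- comps[!(comps$component %in% setdiff(grp, i0)), ]
      }
      comps$component <- seq_len(nrow(comps))
    }
    new_mixture_fit(comps, r_squared(y_list[[h]], fitted),
                    y_list[[h]] - fitted, fitted, hists[[h]],
                    "global_amplitude_only",
                    list(deviance = fit$deviance, niter = fit$niter,
                         converged = fit$info %in% 1:4, shifts = shifts))
  })
}

#' Goodness of fit of a mixture fit on its histogram
#'
#' @param fit A `fret_mixture_fit`.
#' @return R^2 = 1 - SS_res / SS_tot on the fitted density representation.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "fret_mixture_fit"))
  r_squared(fit$hist$density, fit$fitted)
}

#' @export
print.fret_mixture_fit <- function(x, ...) {
  cat("<fret_mixture_fit> ", x$fit_mode, ", ", nrow(x$components),
      " components, R^2 = ", round(x$r_squared, 4), "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' @export
tidy.fret_mixture_fit <- function(x, ...) x$components

#' @export
glance.fret_mixture_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_components = nrow(x$components),
                 fit_mode = x$fit_mode, deviance = x$info$deviance,
                 converged = x$info$converged)
}
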