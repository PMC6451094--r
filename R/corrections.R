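# Bleach-step detection, per-molecule correction factors and corrected
# FRET-efficiency traces.

rolling_mean_step <- function(y, w) {
  # z[t]: mean(y[t+1..t+w]) - mean(y[t-w+1..t]) scaled to unit SD under
  # no-step, using a robust local noise estimate from first differences.
  n <- length(y)
  s <- mad(diff(y)) / sqrt(2)
  if (s == 0) s <- 1e-12
  cs <- cumsum(y)
  t_idx <- w:(n - w)
  m_before <- (cs[t_idx] - c(0, cs)[t_idx - w + 1]) / w
  m_after <- (cs[t_idx + w] - cs[t_idx]) / w
  z <- (m_after - m_before) / (s * sqrt(2 / w))
  list(t = t_idx, z = z)
}

#' Detect single-step photobleaching events in a two-channel trace
#'
#' Two-sided sliding-window mean-shift statistic on each channel, in units
#' of the local noise SD. An acceptor bleach is a large downward step in
#' the acceptor channel with a concurrent donor rise (the full photon
#' budget returns to the donor) that leaves the acceptor at the
#' crosstalk/background level; the post-step level requirement
#' distinguishes a bleach from a FRET transition to a lower state, which
#' produces the same anti-correlated step but keeps acceptor signal. A
#' downward donor step with no acceptor rise is a donor bleach / total
#' signal loss.
#'
#' @param trace Single-molecule trace tibble (`donor_counts`,
#'   `acceptor_counts`).
#' @param window Half-window width in frames for the step statistic.
#' @param threshold Detection threshold in noise-SD units.
#' @param background Donor/acceptor background counts (for the post-step
#'   level test).
#' @param max_post_ratio Maximum background-corrected acceptor/donor ratio
#'   after a candidate step for it to count as an acceptor bleach (roughly
#'   the largest plausible crosstalk fraction).
#' @return List with `acceptor_frame`, `donor_frame` (first dark frame,
#'   `NA` if not observed) and `order` (`"acceptor_first"`,
#'   `"donor_first"` or `"none"`).
#' @export
detect_bleach_steps <- function(trace, window = 5, threshold = 5,
                                background = c(0, 0), max_post_ratio = 0.2) {
  stopifnot(nrow(trace) >= 10)
  don <- trace$donor_counts
  acc <- trace$acceptor_counts
  zs_a <- rolling_mean_step(acc, window)
  zs_d <- rolling_mean_step(don, window)
  acceptor_frame <- NA_integer_
  donor_frame <- NA_integer_
  # post-step window means for the level test
  n <- length(acc)
  post_mean <- function(y, t) mean(y[(t + 1):min(t + window, n)])
  # acceptor bleach: strong acceptor drop, donor not dropping, and the
  # remaining acceptor signal consistent with crosstalk only
  cand <- which(zs_a$z < -threshold & zs_d$z > threshold / 2)
  if (length(cand)) {
    ratio <- vapply(zs_a$t[cand], function(t)
      (post_mean(acc, t) - background[2]) /
        max(post_mean(don, t) - background[1], 1e-9), numeric(1))
    cand <- cand[ratio < max_post_ratio]
  }
  if (length(cand)) {
    best <- cand[which.min(zs_a$z[cand])]
    acceptor_frame <- as.integer(zs_a$t[best] + 1L)
  }
  # donor bleach / total loss: donor drop with acceptor not rising
  cand_d <- which(zs_d$z < -threshold & zs_a$z < threshold / 2)
  if (!is.na(acceptor_frame))
    cand_d <- cand_d[zs_d$t[cand_d] + 1L > acceptor_frame + window - 1L]
  if (length(cand_d)) {
    best <- cand_d[which.min(zs_d$z[cand_d])]
    donor_frame <- as.integer(zs_d$t[best] + 1L)
  }
  order <- if (!is.na(acceptor_frame) &&
               (is.na(donor_frame) || acceptor_frame < donor_frame)) {
    "acceptor_first"
  } else if (!is.na(donor_frame)) "donor_first" else "none"
  list(acceptor_frame = acceptor_frame, donor_frame = donor_frame, order = order)
}

bleach_windows <- function(trace, bleach, margin = 1L, width = 10L) {
  n <- nrow(trace)
  a <- bleach$acceptor_frame
  d_end <- if (is.na(bleach$donor_frame)) n else bleach$donor_frame - 1L
  post <- (a + margin):min(d_end, a + margin + width - 1L)
  pre <- max(1L, a - margin - width):(a - margin - 1L)
  list(pre = pre[pre >= 1 & pre <= n], post = post[post >= 1 & post <= n])
}

#' Estimate spectral crosstalk from a post-acceptor-bleach window
#'
#' After the acceptor has bleached (donor still alive), all acceptor-channel
#' signal above background is donor leakage; alpha is the ratio of
#' background-corrected acceptor to donor signal over that window.
#'
#' @param trace Single-molecule trace tibble.
#' @param bleach Annotations from [detect_bleach_steps()].
#' @param background Two-element vector of donor/acceptor background counts.
#' @param min_frames Minimum usable post-bleach frames.
#' @return Scalar alpha.
#' @export
estimate_crosstalk <- function(trace, bleach, background = c(0, 0),
                               min_frames = 5L) {
  if (bleach$order != "acceptor_first")
    abort_spfret("crosstalk needs an acceptor-first bleach", "spfret_no_bleach_window")
  w <- bleach_windows(trace, bleach)
  if (length(w$post) < min_frames)
    abort_spfret("too few post-bleach frames for crosstalk", "spfret_no_bleach_window")
  num <- mean(trace$acceptor_counts[w$post]) - background[2]
  den <- mean(trace$donor_counts[w$post]) - background[1]
  if (den <= 0)
    abort_spfret("no donor signal in the crosstalk window", "spfret_no_bleach_window")
  max(num / den, 0)
}

#' Estimate the detection-efficiency factor gamma from an acceptor bleach
#'
#' gamma is the ratio of the (crosstalk- and background-corrected) acceptor
#' intensity drop across the acceptor-bleach step to the donor intensity
#' rise across the same step, window-averaged on both sides.
#'
#' @inheritParams estimate_crosstalk
#' @param alpha Crosstalk factor used to correct the acceptor channel.
#' @return Scalar gamma.
#' @export
estimate_gamma <- function(trace, bleach, alpha = 0, background = c(0, 0),
                           min_frames = 5L) {
  if (bleach$order != "acceptor_first")
    abort_spfret("gamma needs an acceptor-first bleach", "spfret_no_bleach_window")
  w <- bleach_windows(trace, bleach)
  if (length(w$pre) < min_frames || length(w$post) < min_frames)
    abort_spfret("too few frames around the bleach step", "spfret_no_bleach_window")
  acc_corr <- function(idx) mean(trace$acceptor_counts[idx]) - background[2] -
    alpha * (mean(trace$donor_counts[idx]) - background[1])
  drop <- acc_corr(w$pre) - acc_corr(w$post)
  rise <- mean(trace$donor_counts[w$post]) - mean(trace$donor_counts[w$pre])
  if (rise <= 0)
    abort_spfret("donor rise across the bleach step is not positive",
                 "spfret_no_bleach_window")
  drop / rise
}

#' Per-molecule correction factors with population/config fallback
#'
#' For every molecule with an acceptor-first bleach, alpha and gamma are
#' estimated from its own trace; molecules without a usable bleach event
#' fall back to the population median of the per-molecule estimates and,
#' failing that, to the configured constants. The source of each factor is
#' recorded. Estimates are never produced from donor-first traces.
#'
#' @param traces Trace table (many molecules).
#' @param background Two-element donor/acceptor background counts.
#' @param fallback_alpha,fallback_gamma Config constants of last resort.
#' @param window,threshold Passed to [detect_bleach_steps()].
#' @return Tibble: `molecule_id`, `alpha`, `gamma`, `source`,
#'   `acceptor_frame`, `donor_frame`, `order`.
#' @export
correction_factors <- function(traces, background = c(0, 0),
                               fallback_alpha = 0, fallback_gamma = 1,
                               window = 5, threshold = 5) {
  per <- traces |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_map(function(tr, key) {
      bl <- detect_bleach_steps(tr, window = window, threshold = threshold,
                                background = background)
      est <- tryCatch({
        a <- estimate_crosstalk(tr, bl, background)
        g <- estimate_gamma(tr, bl, alpha = a, background = background)
        list(alpha = a, gamma = g, source = "per_molecule")
      }, spfret_no_bleach_window = function(e)
        list(alpha = NA_real_, gamma = NA_real_, source = NA_character_))
      tibble::tibble(molecule_id = key$molecule_id, alpha = est$alpha,
                     gamma = est$gamma, source = est$source,
                     acceptor_frame = bl$acceptor_frame,
                     donor_frame = bl$donor_frame, order = bl$order)
    }) |>
    dplyr::bind_rows()
  med_a <- median(per$alpha, na.rm = TRUE)
  med_g <- median(per$gamma, na.rm = TRUE)
  per |>
    dplyr::mutate(
      source = dplyr::case_when(
        !is.na(.data$alpha) ~ "per_molecule",
        is.finite(med_a) & is.finite(med_g) ~ "population_median",
        TRUE ~ "config"),
      alpha = dplyr::case_when(
        !is.na(.data$alpha) ~ .data$alpha,
        is.finite(med_a) ~ med_a, TRUE ~ fallback_alpha),
      gamma = dplyr::case_when(
        !is.na(.data$gamma) ~ .data$gamma,
        is.finite(med_g) ~ med_g, TRUE ~ fallback_gamma))
}

#' Compute corrected FRET-efficiency traces
#'
#' Per frame, E = (IA - alpha ID - bgA) / ((IA - alpha ID - bgA) +
#' gamma (ID - bgD)), where IA and ID are the raw acceptor/donor channel
#' counts (background subtraction uses the raw donor in the crosstalk
#' term). The analysis window runs from the first frame to the frame before
#' the first bleach event; frames with a vanishing denominator are flagged
#' invalid. E is left unclamped; clamping to [0, 1] is a display choice.
#'
#' @param traces Trace table (one or many molecules).
#' @param factors Per-molecule factor table from [correction_factors()], or
#'   a list with `alpha` and `gamma` applied to all molecules.
#' @param background Two-element donor/acceptor background counts.
#' @return Tibble: `molecule_id`, `frame`, `time_s`, `fret`, `in_window`,
#'   `valid`.
#' @export
compute_fret <- function(traces, factors, background = c(0, 0)) {
  if (!is.data.frame(factors)) {
    factors <- tibble::tibble(molecule_id = unique(traces$molecule_id),
                              alpha = factors$alpha, gamma = factors$gamma,
                              acceptor_frame = NA_integer_,
                              donor_frame = NA_integer_)
  }
  traces |>
    dplyr::left_join(
      dplyr::select(factors, "molecule_id", "alpha", "gamma",
                    dplyr::any_of(c("acceptor_frame", "donor_frame"))),
      by = "molecule_id") |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::mutate(
      last_usable = pmin(
        ifelse(is.na(.data$acceptor_frame), dplyr::n() + 1L, .data$acceptor_frame),
        ifelse(is.na(.data$donor_frame), dplyr::n() + 1L, .data$donor_frame)) - 1L,
      num = .data$acceptor_counts - .data$alpha *
        (.data$donor_counts - background[1]) - background[2],
      den = .data$num + .data$gamma * (.data$donor_counts - background[1]),
      valid = abs(.data$den) > .Machine$double.eps^0.5,
      fret = ifelse(.data$valid, .data$num / .data$den, NA_real_),
      in_window = .data$frame <= .data$last_usable) |>
    dplyr::ungroup() |>
    dplyr::select("molecule_id", "frame", "time_s", "fret", "in_window", "valid")
}

#' Subtract direct excitation from the 488-excitation series
#'
#' In frame-alternating three-color traces, part of the green signal after
#' 488 nm excitation stems from direct excitation of the 532 nm dye; it is
#' removed by subtracting a fixed fraction of the temporally adjacent
#' 532 nm green signal.
#'
#' @param trace Trace tibble with `ex488_counts` and `donor_counts` (the
#'   adjacent 532 nm green signal).
#' @param fraction Direct-excitation fraction in [0, 1).
#' @return The trace with a corrected `ex488_counts` column.
#' @export
correct_direct_excitation <- function(trace, fraction) {
  if (!"ex488_counts" %in% names(trace))
    abort_spfret("trace has no 488-excitation series", "spfret_config_error")
  stopifnot(fraction >= 0, fraction < 1)
  dplyr::mutate(trace, ex488_counts = .data$ex488_counts -
                  fraction * .data$donor_counts)
}

#' Call the presence of labeled Mot1 from the 488-excitation series
#'
#' A complex is called Mot1-bound when the windowed mean of the corrected
#' 488 nm green signal exceeds a threshold (default: background mean plus
#' 3 SD) for at least `min_run` consecutive frames. Single-frame spikes
#' never trigger a call.
#'
#' @param ex488 Numeric vector of corrected 488-excitation counts.
#' @param bg_mean,bg_sd Background statistics of the series.
#' @param threshold Override for the default `bg_mean + 3 * bg_sd`.
#' @param window Width of the rolling mean.
#' @param min_run Minimum number of consecutive above-threshold frames.
#' @return Logical.
#' @export
call_mot1_presence <- function(ex488, bg_mean = 0, bg_sd = 1, threshold = NULL,
                               window = 5L, min_run = 3L) {
  if (length(ex488) < window) return(FALSE)
  if (is.null(threshold)) threshold <- bg_mean + 3 * bg_sd
  cs <- cumsum(c(0, ex488))
  rm_ <- (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
  above <- rm_ > threshold
  r <- rle(above)
  any(r$values & r$lengths >= min_run)
}
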