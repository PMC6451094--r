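# Photobleaching-corrected dissociation kinetics from molecule
# disappearance times.

#' Build a survival curve from disappearance times
#'
#' Counts the molecules still fluorescent at each grid time. Censored
#' molecules (still visible at the end of the recording) count as
#' surviving through the censoring horizon. The curve starts at the full
#' molecule count at t = 0.
#'
#' @param data Tibble with `time_s` (disappearance or censoring time) and
#'   logical `censored`; e.g. one arm of [sim_survival_experiment()].
#' @param time_grid Evaluation times; default: 0 and every observed time.
#' @param condition Condition label stored with the curve.
#' @param frame_time Acquisition frame time in seconds (metadata from the
#'   recording settings; paired arms are checked for matching values).
#' @return A `survival_curve`: tibble with `time_s`, `n_surviving`,
#'   `fraction`; attributes `n0`, `n_events`, `horizon`, `condition`,
#'   `frame_time` and the raw `data` (used for resampled standard errors).
#' @export
build_survival <- function(data, time_grid = NULL, condition = NA_character_,
                           frame_time = NA_real_) {
  if (nrow(data) < 10)
    abort_spfret("need >= 10 molecules for a survival curve", "spfret_survival_error")
  if (!"censored" %in% names(data)) data$censored <- FALSE
  if (is.null(time_grid))
    time_grid <- sort(unique(c(0, data$time_s)))
  # surviving at t: uncensored with time > t, censored with time >= t
  ev <- sort(data$time_s[!data$censored])
  cn <- sort(data$time_s[data$censored])
  n_surv <- nrow(data) - findInterval(time_grid, ev) -
    findInterval(time_grid, cn, left.open = TRUE)
  out <- tibble::tibble(time_s = time_grid, n_surviving = n_surv,
                        fraction = n_surv / nrow(data))
  structure(out, class = c("survival_curve", class(out)),
            n0 = nrow(data), n_events = sum(!data$censored),
            horizon = max(data$time_s), condition = condition,
            frame_time = frame_time, data = data)
}

#' Fit a mono-exponential decay to a survival curve
#'
#' Least-squares fit of the normalized curve to f(t) = exp(-k t): the
#' amplitude is fixed at one, so the fitted model is exactly 1 at t = 0.
#' Because survival-curve points are serially correlated, the
#' least-squares covariance is not a valid standard error; the SE is
#' instead computed by resampling molecules (a nonparametric bootstrap of
#' the disappearance times, refitting each replicate) when the curve
#' carries its raw data, and falls back to the exponential event-count
#' asymptotics k / sqrt(events) otherwise.
#'
#' @param curve A `survival_curve`.
#' @param n_boot Bootstrap replicates for the SE (0 forces the event-count
#'   fallback).
#' @return A `rate_estimate` tibble: `k` (1/s), `se`, `r_squared`,
#'   `n_events`, `method`. A non-decaying curve returns k = 0 with a
#'   warning.
#' @export
fit_survival <- function(curve, n_boot = 200) {
  stopifnot(inherits(curve, "survival_curve"))
  if (sum(curve$n_surviving > 0) < 5)
    abort_spfret("need >= 5 occupied grid points", "spfret_survival_error")
  ls_rate <- function(t, y) {
    sse <- function(k) sum((y - exp(-k * t))^2)
    up <- 10 / max(mean(t[t > 0]), 1e-9)
    optimize(sse, c(0, up), tol = 1e-10)$minimum
  }
  t <- curve$time_s
  y <- curve$fraction
  flat <- all(diff(curve$n_surviving) == 0)
  if (flat) {
    rlang::warn("survival curve does not decay; returning k = 0",
                class = "spfret_flat_survival")
    k <- 0
  } else {
    k <- ls_rate(t, y)
  }
  n_ev <- attr(curve, "n_events")
  data <- attr(curve, "data")
  se <- if (!flat && !is.null(data) && n_boot > 0) {
    # molecule-level bootstrap; fixed internal stream so results are a
    # deterministic function of the data
    boots <- with_seed(substream_seed(20231115L, "surv_boot", nrow(data)), {
      vapply(seq_len(n_boot), function(b) {
        d <- data[sample.int(nrow(data), replace = TRUE), ]
        grid <- sort(unique(c(0, d$time_s)))
        ev <- sort(d$time_s[!d$censored])
        cn <- sort(d$time_s[d$censored])
        frac <- (nrow(d) - findInterval(grid, ev) -
                   findInterval(grid, cn, left.open = TRUE)) / nrow(d)
        ls_rate(grid, frac)
      }, numeric(1))
    })
    sd(boots)
  } else {
    k / sqrt(max(n_ev, 1))
  }
  fitted <- exp(-k * t)
  ss_tot <- sum((y - mean(y))^2)
  structure(tibble::tibble(
    k = k, se = se,
    r_squared = if (ss_tot > 0) 1 - sum((y - fitted)^2) / ss_tot else NA_real_,
    n_events = n_ev, method = "ls_monoexp"),
    class = c("rate_estimate", "tbl_df", "tbl", "data.frame"))
}

#' Censored maximum-likelihood rate estimate (cross-check)
#'
#' Closed-form exponential MLE with right censoring: events divided by
#' total observed time. Serves as an independent check on the
#' least-squares curve fit.
#'
#' @param data Tibble with `time_s` and `censored`.
#' @return A `rate_estimate` tibble (as [fit_survival()]).
#' @export
survival_rate_mle <- function(data) {
  if (!"censored" %in% names(data)) data$censored <- FALSE
  d <- sum(!data$censored)
  k <- d / sum(data$time_s)
  structure(tibble::tibble(k = k, se = k / sqrt(max(d, 1)),
                           r_squared = NA_real_, n_events = d,
                           method = "censored_mle"),
            class = c("rate_estimate", "tbl_df", "tbl", "data.frame"))
}

#' Photobleaching-corrected dissociation rate
#'
#' Fits the control (photobleaching-only) and treatment arm with
#' mono-exponential decays and attributes the rate difference k2 - k1 to
#' dissociation. The standard error is the quadrature sum of the two rate
#' SEs. Negative differences are reported as-is with a flag (conditions
#' without dissociation scatter around zero).
#'
#' @param control,treatment `survival_curve` objects from the same
#'   experiment and illumination settings.
#' @param condition Condition label (e.g. nucleotide and Mot1
#'   concentration).
#' @param concentration Numeric concentration for series analyses.
#' @return A `dissociation_result`: tibble with `condition`,
#'   `concentration`, `k1`, `k1_se`, `k2`, `k2_se`, `rate` (= k2 - k1),
#'   `se`, `negative` flag.
#' @export
dissociation_rate <- function(control, treatment, condition = NA_character_,
                              concentration = NA_real_) {
  stopifnot(inherits(control, "survival_curve"),
            inherits(treatment, "survival_curve"))
  ft1 <- attr(control, "frame_time")
  ft2 <- attr(treatment, "frame_time")
  if (is.finite(ft1) && is.finite(ft2) && abs(ft1 - ft2) > 1e-9)
    abort_spfret("control and treatment have different frame times",
                 "spfret_survival_error")
  f1 <- fit_survival(control)
  f2 <- fit_survival(treatment)
  structure(tibble::tibble(
    condition = condition, concentration = concentration,
    k1 = f1$k, k1_se = f1$se, k2 = f2$k, k2_se = f2$se,
    rate = f2$k - f1$k, se = sqrt(f1$se^2 + f2$se^2),
    negative = f2$k < f1$k),
    class = c("dissociation_result", "tbl_df", "tbl", "data.frame"))
}

#' Order dissociation results into a concentration series
#'
#' @param results List of `dissociation_result` rows (or a bound tibble).
#' @return Tibble sorted by concentration with a Spearman rank
#'   correlation between concentration and rate reported as attributes
#'   `rho` and `p_value` (no functional form is imposed).
#' @export
concentration_series <- function(results) {
  tab <- if (is.data.frame(results)) tibble::as_tibble(results) else
    dplyr::bind_rows(results)
  if (nrow(tab) < 2)
    abort_spfret("need >= 2 conditions", "spfret_survival_error")
  if (anyDuplicated(tab$condition))
    abort_spfret("duplicate condition labels", "spfret_survival_error")
  tab <- dplyr::arrange(tab, .data$concentration)
  ct <- suppressWarnings(stats::cor.test(tab$concentration, tab$rate,
                                         method = "spearman"))
  structure(tab, rho = unname(ct$estimate), p_value = ct$p.value)
}
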