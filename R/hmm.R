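# Per-molecule Gaussian-emission hidden Markov models on corrected FRET
# traces: Baum-Welch training, Viterbi decoding, model selection and
# static/dynamic classification. The per-frame recursions live in C++
# (src/hmm.cpp); the M-step and orchestration are here.

hmm_param_count <- function(k) (k - 1) + k * (k - 1) + 2 * k

single_state_loglik <- function(e) {
  mu <- mean(e)
  s <- sqrt(mean((e - mu)^2))
  s <- max(s, 1e-6)
  sum(dnorm(e, mu, s, log = TRUE))
}

#' Train a Gaussian-emission HMM on one FRET trace
#'
#' Baum-Welch (EM) on the corrected FRET-efficiency series of a single
#' molecule. Training stops when the log-likelihood changes by less than
#' `tol` (default 1e-9) between iterations or `max_iter` is reached.
#' Several seeded initializations with quantile-spread emission means are
#' run and the best likelihood kept. States are relabeled by increasing
#' emission mean. The log-likelihood is non-decreasing across iterations
#' (`$loglik_trace`).
#'
#' @param e Numeric vector of corrected FRET efficiencies (one molecule's
#'   analysis window).
#' @param n_states Number of hidden states (default 3).
#' @param frame_time Frame time in seconds (stored; used by dwell-time
#'   conversions downstream).
#' @param tol Convergence threshold on the log-likelihood change.
#' @param max_iter Iteration cap; hitting it flags `converged = FALSE`.
#' @param n_restarts Number of seeded initializations.
#' @param seed Seed for the initializations.
#' @return A `fret_hmm`: initial probabilities `pi`, `transition` matrix,
#'   emission `means`/`sds`, `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `degenerate` flag and the observations `e`.
#' @export
#' @examples
#' cfg <- sim_config(n_molecules = 1, n_frames = 400, bleach_rate_donor = 0,
#'   bleach_rate_acceptor = 0, crosstalk_alpha = 0, gamma = 1,
#'   emission_states = data.frame(mean = c(0.25, 0.69), sd = 0.05),
#'   transition_matrix = matrix(c(.95, .05, .05, .95), 2, byrow = TRUE))
#' path <- sim_state_path(cfg, 1)
#' e <- 0.25 + 0.44 * (path - 1) + rnorm(400, 0, 0.05)
#' m <- fit_fret_hmm(e, n_states = 2)
#' m$means
fit_fret_hmm <- function(e, n_states = 3, frame_time = 0.015, tol = 1e-9,
                         max_iter = 500, n_restarts = 5, seed = 1L) {
  e <- e[is.finite(e)]
  if (length(e) < 10 * n_states)
    abort_spfret("trace too short for HMM training", "spfret_hmm_error")
  k <- n_states
  run_one <- function(mu0, sd0) {
    pi <- rep(1 / k, k)
    A <- matrix(0.05 / max(k - 1, 1), k, k); diag(A) <- if (k > 1) 0.95 else 1
    mu <- mu0; s <- sd0
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0
    while (iter < max_iter) {
      iter <- iter + 1
      fb <- hmm_forward_backward(e, pi, A, mu, s)
      ll_trace <- c(ll_trace, fb$loglik)
      if (abs(fb$loglik - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- fb$loglik
      g <- fb$gamma
      occ <- colSums(g)
      pi <- g[1, ]
      if (k > 1) {
        A <- fb$xi_sum / pmax(rowSums(fb$xi_sum), 1e-300)
      }
      mu <- colSums(g * e) / pmax(occ, 1e-300)
      s <- sqrt(colSums(g * (outer(e, mu, "-")^2)) / pmax(occ, 1e-300))
      s <- pmax(s, 1e-3)
    }
    list(pi = pi, A = A, mu = mu, s = s, loglik = ll_trace[length(ll_trace)],
         loglik_trace = ll_trace, n_iter = iter, converged = converged,
         occ = colSums(hmm_forward_backward(e, pi, A, mu, s)$gamma))
  }
  sd_all <- max(sd(e), 0.01)
  inits <- with_seed(substream_seed(seed, "hmm_init", 0L), {
    lapply(seq_len(max(n_restarts, 1)), function(r) {
      probs <- (seq_len(k) - 0.5) / k
      mu0 <- as.numeric(quantile(e, probs))
      if (r > 1) mu0 <- mu0 + rnorm(k, 0, sd_all / 2)
      list(mu0 = sort(mu0), sd0 = rep(sd_all / sqrt(k), k))
    })
  })
  fits <- lapply(inits, function(i) run_one(i$mu0, i$sd0))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  ord <- order(best$mu)
  # degenerate: duplicated/empty states, or no BIC support over a single
  # Gaussian (the trace carries no resolvable state structure)
  bic_k <- -2 * best$loglik + hmm_param_count(k) * log(length(e))
  bic_1 <- -2 * single_state_loglik(e) + 2 * log(length(e))
  degenerate <- k > 1 &&
    (any(diff(sort(best$mu)) < 1e-3) || any(best$occ < 1) || bic_k >= bic_1)
  structure(list(n_states = k, pi = best$pi[ord],
                 transition = best$A[ord, ord, drop = FALSE],
                 means = best$mu[ord], sds = best$s[ord],
                 loglik = best$loglik, loglik_trace = best$loglik_trace,
                 n_iter = best$n_iter, converged = best$converged,
                 degenerate = degenerate, frame_time = frame_time, e = e),
            class = "fret_hmm")
}

#' @export
print.fret_hmm <- function(x, ...) {
  cat("<fret_hmm> ", x$n_states, " states, logL = ", signif(x$loglik, 8),
      if (!x$converged) " (not converged)", if (x$degenerate) " (degenerate)",
      "\n  means: ", paste(round(x$means, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.fret_hmm <- function(x, ...) {
  tibble::tibble(state = seq_len(x$n_states), mean = x$means, sd = x$sds,
                 initial_prob = x$pi, stay_prob = diag(x$transition))
}

#' @export
glance.fret_hmm <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, loglik = x$loglik,
                 n_iter = x$n_iter, converged = x$converged,
                 degenerate = x$degenerate, n_frames = length(x$e))
}

#' Forward log-likelihood of a FRET trace under an HMM
#'
#' @param e Observations.
#' @param model A `fret_hmm`, or `NULL` if the parameters are given
#'   explicitly.
#' @param pi,A,means,sds Explicit parameters (used when `model` is `NULL`).
#' @return Scalar log-likelihood.
#' @export
hmm_forward_loglik <- function(e, model = NULL, pi = model$pi,
                               A = model$transition, means = model$means,
                               sds = model$sds) {
  hmm_loglik(e, pi, A, means, sds)
}

#' Decode the most likely state path (Viterbi)
#'
#' @param model A `fret_hmm`.
#' @param e Observations; defaults to the trace the model was trained on.
#' @param molecule_id Id stored in the output tables.
#' @return A `state_path`: list with `path` (tibble: frame, time_s, state,
#'   e_state), `transitions` (tibble: time_s, from_state, to_state,
#'   e_from, e_to) and `logprob`. The Viterbi path log-probability never
#'   exceeds the total forward log-likelihood.
#' @export
decode_path <- function(model, e = model$e, molecule_id = 1L) {
  stopifnot(inherits(model, "fret_hmm"))
  v <- hmm_viterbi(e, model$pi, model$transition, model$means, model$sds)
  path <- v$path
  frames <- seq_along(path)
  sw <- which(diff(path) != 0)
  transitions <- tibble::tibble(
    molecule_id = molecule_id,
    time_s = sw * model$frame_time,
    from_state = path[sw], to_state = path[sw + 1L],
    e_from = model$means[path[sw]], e_to = model$means[path[sw + 1L]])
  structure(list(
    path = tibble::tibble(molecule_id = molecule_id, frame = frames,
                          time_s = (frames - 1L) * model$frame_time,
                          state = path, e_state = model$means[path]),
    transitions = transitions, logprob = v$logprob, model = model),
    class = "state_path")
}

#' Select the number of HMM states
#'
#' Trains HMMs with each candidate state count and returns the smallest
#' count whose penalized likelihood (BIC) is within `tolerance` of the
#' best, i.e. the lowest number of states that describes the data.
#'
#' @inheritParams fit_fret_hmm
#' @param candidates Candidate state counts.
#' @param tolerance BIC slack (default 0: the minimum itself, smallest
#'   count on ties).
#' @return Integer state count.
#' @export
select_n_states <- function(e, candidates = 1:4, frame_time = 0.015,
                            tolerance = 0, n_restarts = 3, seed = 1L,
                            max_iter = 200) {
  e <- e[is.finite(e)]
  bic <- vapply(candidates, function(k) {
    ll <- if (k == 1) single_state_loglik(e) else
      fit_fret_hmm(e, k, frame_time, n_restarts = n_restarts, seed = seed,
                   max_iter = max_iter)$loglik
    -2 * ll + hmm_param_count(k) * log(length(e))
  }, numeric(1))
  candidates[which(bic <= min(bic) + tolerance)[1]]
}

has_flanked_transition <- function(path, min_dwell = 2L) {
  r <- rle(path)
  if (length(r$lengths) < 2) return(FALSE)
  any(r$lengths[-length(r$lengths)] >= min_dwell & r$lengths[-1] >= min_dwell)
}

#' Classify traces as static or dynamic
#'
#' A molecule is dynamic when (a) a 3-state HMM improves the BIC over a
#' single Gaussian by more than `margin` and (b) its decoded path contains
#' at least one transition flanked by dwells of >= `min_dwell` frames on
#' both sides; otherwise it is static. Windows shorter than `min_frames`
#' are left unassigned. A `manual_label` column in the input, when present,
#' overrides the automatic call.
#'
#' @param fret FRET trace table from [compute_fret()] (uses the analysis
#'   window of each molecule).
#' @param min_frames Minimum analysis-window length.
#' @param margin Required BIC improvement (default 0).
#' @param min_dwell Minimum flanking dwell length in frames.
#' @param frame_time Frame time in seconds.
#' @param n_restarts,seed,max_iter Passed to [fit_fret_hmm()].
#' @return Tibble: `molecule_id`, `label` ("static", "dynamic",
#'   "unassigned"), `score` (BIC improvement), `n_transitions`.
#' @export
classify_traces <- function(fret, min_frames = 20, margin = 0, min_dwell = 2L,
                            frame_time = 0.015, n_restarts = 3, seed = 1L,
                            max_iter = 200) {
  fret |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::group_map(function(tr, key) {
      out <- tibble::tibble(molecule_id = key$molecule_id,
                            label = "unassigned", score = NA_real_,
                            n_transitions = NA_integer_)
      if ("manual_label" %in% names(tr) && !all(is.na(tr$manual_label))) {
        out$label <- tr$manual_label[!is.na(tr$manual_label)][1]
        return(out)
      }
      e <- tr$fret[tr$in_window & tr$valid]
      e <- e[is.finite(e)]
      if (length(e) < max(min_frames, 30)) return(out)
      bic1 <- -2 * single_state_loglik(e) + 2 * log(length(e))
      m3 <- fit_fret_hmm(e, 3, frame_time, n_restarts = n_restarts,
                         seed = substream_seed(seed, "classify", key$molecule_id),
                         max_iter = max_iter)
      bic3 <- -2 * m3$loglik + hmm_param_count(3) * log(length(e))
      dec <- decode_path(m3, molecule_id = key$molecule_id)
      out$score <- bic1 - bic3
      out$n_transitions <- nrow(dec$transitions)
      out$label <- if (bic1 - bic3 > margin &&
                       has_flanked_transition(dec$path$state, min_dwell))
        "dynamic" else "static"
      out
    }) |>
    dplyr::bind_rows()
}
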