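# Independent oracles and small fixture builders used across tests.

# Brute-force HMM likelihood: enumerate every state path (feasible for
# short traces); independent of the scaled forward recursion in C++.
oracle_forward_loglik <- function(e, pi, A, mu, sd) {
  K <- length(pi)
  Tn <- length(e)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- log(pi[p[1]]) + sum(dnorm(e, mu[p], sd[p], log = TRUE))
    if (Tn > 1) lp <- lp + sum(log(A[cbind(p[-Tn], p[-1])]))
    total <- total + exp(lp)
  }
  log(total)
}

# Noise-free, correction-free config for exact-arithmetic tests.
clean_config <- function(n_molecules = 1, n_frames = 100,
                         emission_states = data.frame(mean = 0.5, sd = 0.05),
                         transition_matrix = diag(nrow(emission_states)), ...) {
  sim_config(n_molecules = n_molecules, n_frames = n_frames,
             emission_states = emission_states,
             transition_matrix = transition_matrix,
             noise_model = "gaussian_read", read_noise_sd = 0,
             crosstalk_alpha = 0, gamma = 1,
             bleach_rate_donor = 0, bleach_rate_acceptor = 0, ...)
}

# Hand-built two-channel trace tibble.
manual_trace <- function(donor, acceptor, frame_time = 0.015, id = 1L) {
  n <- length(donor)
  tibble::tibble(molecule_id = id, frame = seq_len(n),
                 time_s = (seq_len(n) - 1) * frame_time,
                 donor_counts = donor, acceptor_counts = acceptor)
}

table2_states <- function(cond, pops = c("P1", "P2")) {
  dplyr::filter(tbp_framewise_states(), condition == cond, subpop %in% pops)
}

# Dynamic-subpopulation simulation + per-molecule HMM decoding, shared by
# the TDP/assignment tests and the acceptance suite.
decode_population <- function(condition, n_molecules, n_frames = 800,
                              p_switch = 0.05, seed = 1L) {
  base <- sim_config(n_molecules = n_molecules, n_frames = n_frames,
                     frame_time = 0.015, static_fraction = 0,
                     bleach_rate_donor = 0, bleach_rate_acceptor = 0,
                     seed = seed)
  sim <- sim_population(base, subpop_mixture(condition, p_switch = p_switch))
  fac <- list(alpha = sim$config$crosstalk_alpha, gamma = sim$config$gamma)
  fret <- compute_fret(sim$traces, fac, background = sim$config$background)
  decs <- purrr::map(unique(fret$molecule_id), function(id) {
    e <- fret$fret[fret$molecule_id == id & fret$in_window & fret$valid]
    m <- fit_fret_hmm(e, 3, frame_time = 0.015,
                      seed = spfret:::substream_seed(seed, "test_hmm", id))
    decode_path(m, molecule_id = id)
  })
  list(sim = sim, decodes = decs,
       transitions = dplyr::bind_rows(purrr::map(decs, "transitions")))
}
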