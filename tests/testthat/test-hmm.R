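# Hidden Markov model training, decoding, model selection, TDPs and
# dwell-time kinetics.

test_that("forward likelihood matches brute-force path enumeration", {
  set.seed(30)
  for (rep in 1:3) {
    K <- sample(2:3, 1)
    Tn <- sample(6:9, 1)
    A <- matrix(runif(K * K), K)
    A <- A / rowSums(A)
    pi <- runif(K); pi <- pi / sum(pi)
    mu <- sort(runif(K))
    s <- runif(K, 0.03, 0.1)
    e <- runif(Tn)
    ll_fast <- hmm_forward_loglik(e, pi = pi, A = A, means = mu, sds = s)
    ll_brute <- oracle_forward_loglik(e, pi, A, mu, s)
    expect_equal(ll_fast, ll_brute, tolerance = 1e-10)
  }
})

test_that("a trained model's likelihood equals the forward recursion", {
  set.seed(31)
  e <- c(rnorm(60, 0.3, 0.05), rnorm(60, 0.7, 0.05))[sample(120)]
  m <- fit_fret_hmm(e, 2, seed = 1)
  expect_equal(m$loglik,
               hmm_forward_loglik(e, m), tolerance = 1e-8)
})

test_that("Baum-Welch log-likelihood is non-decreasing every iteration", {
  cfg <- clean_config(
    n_frames = 600, emission_states = data.frame(mean = c(.25, .44, .69), sd = .06),
    transition_matrix = linear_chain_matrix(3, 0.08), seed = 32)
  path <- sim_state_path(cfg, 1)
  e <- sim_trace(cfg, path)$frames$e_app
  m <- fit_fret_hmm(e, 3, seed = 2)
  expect_true(all(diff(m$loglik_trace) > -1e-8))
  expect_true(m$converged)
})

test_that("emission means are recovered from 3-state chains", {
  cfg <- clean_config(
    n_frames = 2000, emission_states = data.frame(mean = c(.25, .44, .69), sd = .05),
    transition_matrix = linear_chain_matrix(3, 0.1), seed = 33)
  path <- sim_state_path(cfg, 1)
  e <- sim_trace(cfg, path)$frames$e_app
  m <- fit_fret_hmm(e, 3, seed = 3)
  expect_lt(max(abs(m$means - c(0.25, 0.44, 0.69))), 0.02)
  expect_true(all(diff(m$means) > 0))   # states ordered by increasing E
})

test_that("emission-mean recovery bias is small across an ensemble", {
  cfg <- clean_config(
    n_molecules = 25, n_frames = 1500,
    emission_states = data.frame(mean = c(.25, .44, .69), sd = .05),
    transition_matrix = linear_chain_matrix(3, 0.1), seed = 34)
  sim <- sim_traces(cfg)
  means <- t(vapply(seq_len(25), function(i) {
    e <- sim$ground_truth$frames$e_app[sim$ground_truth$frames$molecule_id == i]
    fit_fret_hmm(e, 3, seed = i, n_restarts = 3)$means
  }, numeric(3)))
  expect_lt(max(abs(colMeans(means) - c(0.25, 0.44, 0.69))), 0.005)
})

test_that("Viterbi decoding is exact on well-separated traces", {
  cfg <- clean_config(
    n_frames = 500, emission_states = data.frame(mean = c(.2, .8), sd = .02),
    transition_matrix = matrix(c(.95, .05, .05, .95), 2, byrow = TRUE),
    seed = 35)
  path <- sim_state_path(cfg, 1)
  e <- sim_trace(cfg, path)$frames$e_app
  m <- fit_fret_hmm(e, 2, seed = 4)
  dec <- decode_path(m)
  expect_equal(dec$path$state, path)
  # Viterbi path log-probability never exceeds the forward log-likelihood
  expect_lte(dec$logprob, m$loglik + 1e-10)
  # transitions tabulated only at state changes
  expect_equal(nrow(dec$transitions), sum(diff(path) != 0))
})

test_that("decoding accuracy stays high at realistic emission overlap", {
  cfg <- clean_config(
    n_frames = 1000, emission_states = data.frame(mean = c(.25, .44, .69), sd = .07),
    transition_matrix = linear_chain_matrix(3, 0.05), seed = 36)
  path <- sim_state_path(cfg, 1)
  e <- sim_trace(cfg, path)$frames$e_app
  dec <- decode_path(fit_fret_hmm(e, 3, seed = 5))
  expect_gte(mean(dec$path$state == path), 0.9)
})

test_that("model selection picks the lowest adequate state count", {
  set.seed(37)
  e1 <- rnorm(500, 0.4, 0.05)
  expect_equal(select_n_states(e1, seed = 1), 1L)

  picks <- vapply(1:5, function(i) {
    cfg <- clean_config(
      n_frames = 1500,
      emission_states = data.frame(mean = c(.25, .44, .69), sd = .05),
      transition_matrix = linear_chain_matrix(3, 0.1), seed = 38 + i)
    p <- sim_state_path(cfg, 1)
    e <- sim_trace(cfg, p)$frames$e_app
    select_n_states(e, seed = i)
  }, numeric(1))
  expect_gte(mean(picks == 3), 0.8)

  # 2-state data never selects 4 states under the BIC penalty
  cfg2 <- clean_config(
    n_frames = 800, emission_states = data.frame(mean = c(.3, .7), sd = .05),
    transition_matrix = matrix(c(.9, .1, .1, .9), 2, byrow = TRUE), seed = 39)
  p2 <- sim_state_path(cfg2, 1)
  e2 <- sim_trace(cfg2, p2)$frames$e_app
  expect_lt(select_n_states(e2, seed = 2), 4L)
})

test_that("constant traces forced through training are flagged degenerate", {
  set.seed(40)
  e <- rnorm(300, 0.5, 0.03)
  m <- fit_fret_hmm(e, 3, seed = 6)
  expect_true(m$degenerate || diff(range(m$means)) < 0.05)
})

test_that("static/dynamic classification obeys its decision rule", {
  set.seed(41)
  # constant + noise -> static; high-SNR square wave -> dynamic
  mk_fret <- function(e, id) tibble::tibble(
    molecule_id = id, frame = seq_along(e), time_s = 0.015 * (seq_along(e) - 1),
    fret = e, in_window = TRUE, valid = TRUE)
  f_static <- mk_fret(rnorm(300, 0.4, 0.05), 1L)
  f_dyn <- mk_fret(rep(c(0.25, 0.69), each = 25, times = 6) +
                     rnorm(300, 0, 0.04), 2L)
  f_short <- mk_fret(rnorm(15, 0.4, 0.05), 3L)
  lab <- classify_traces(dplyr::bind_rows(f_static, f_dyn, f_short),
                         seed = 1)
  expect_equal(lab$label, c("static", "dynamic", "unassigned"))
  # manual override wins
  f_manual <- f_static
  f_manual$manual_label <- "dynamic"
  expect_equal(classify_traces(f_manual, seed = 1)$label, "dynamic")
})

test_that("TDPs superpose unit-mass kernels and conserve mass", {
  tr <- tibble::tibble(e_from = rep(0.25, 10), e_to = rep(0.44, 10))
  tdp <- build_tdp(tr, kernel_width = 0.03, grid_n = 201)
  dx <- tdp$x[2] - tdp$x[1]
  expect_lt(abs(sum(tdp$density) * dx^2 / 10 - 1), 1e-3)
  peak <- which(tdp$density == max(tdp$density), arr.ind = TRUE)
  expect_lt(abs(tdp$x[peak[1]] - 0.25), 0.011)
  expect_lt(abs(tdp$y[peak[2]] - 0.44), 0.011)

  # symmetric transition sets give symmetric TDPs
  tr2 <- tibble::tibble(e_from = c(0.3, 0.7), e_to = c(0.7, 0.3))
  tdp2 <- build_tdp(tr2, grid_n = 101)
  expect_equal(tdp2$density, t(tdp2$density), tolerance = 1e-12)

  expect_error(build_tdp(tr[0, ]), class = "spfret_tdp_error")
})

test_that("linear-chain TDPs leave the forbidden corner empty", {
  cfg <- clean_config(
    n_molecules = 30, n_frames = 500,
    emission_states = data.frame(mean = c(.25, .44, .69), sd = .05),
    transition_matrix = linear_chain_matrix(3, 0.08), seed = 42)
  sim <- sim_traces(cfg)
  # ground-truth transitions (generator path level)
  trans <- sim$ground_truth$frames |>
    dplyr::group_by(molecule_id) |>
    dplyr::reframe(e_from = c(.25, .44, .69)[state[-dplyr::n()]][diff(state) != 0],
                   e_to = c(.25, .44, .69)[state[-1]][diff(state) != 0])
  tdp <- build_tdp(trans, kernel_width = 0.03)
  m13 <- tdp_gate_mass(tdp, c(0.25 - 0.05, 0.25 + 0.05), c(0.69 - 0.05, 0.69 + 0.05))
  m12 <- tdp_gate_mass(tdp, c(0.25 - 0.05, 0.25 + 0.05), c(0.44 - 0.05, 0.44 + 0.05))
  expect_lt(m13 / m12, 0.01)
})

test_that("subpopulation assignment recovers gated molecule classes", {
  res <- decode_population("dna_tbp", n_molecules = 40, n_frames = 600,
                           seed = 43)
  gates <- subpop_gates(table2_states("dna_tbp"))
  asn <- assign_subpopulations(res$transitions, gates)
  truth <- res$sim$ground_truth$molecules
  tab <- dplyr::inner_join(asn, truth, by = "molecule_id")
  called <- tab[tab$subpop.x != "unassigned", ]
  expect_gt(nrow(called) / nrow(tab), 0.9)
  expect_gte(mean(called$subpop.x == called$subpop.y), 0.95)

  # single-subpopulation input: one label only
  solo <- assign_subpopulations(
    res$transitions[res$transitions$molecule_id %in%
                      truth$molecule_id[truth$subpop == "P1"], ],
    gates[gates$subpop == "P1", ])
  expect_true(all(solo$subpop == "P1"))

  # zero transitions -> unassigned
  none <- assign_subpopulations(
    tibble::tibble(molecule_id = 1L, e_from = numeric(0)[0],
                   e_to = numeric(0)[0])[0, ], gates)
  expect_equal(nrow(none), 0)
  # overlapping gates across subpopulations are a configuration error
  g2 <- gates
  g2$from_lo[g2$subpop == "P2"] <- gates$from_lo[1]
  g2$from_hi[g2$subpop == "P2"] <- gates$from_hi[1]
  g2$to_lo[g2$subpop == "P2"] <- gates$to_lo[1]
  g2$to_hi[g2$subpop == "P2"] <- gates$to_hi[1]
  expect_error(assign_subpopulations(res$transitions, g2),
               class = "spfret_config_error")
})

test_that("dwell-time rates are recovered with censoring honored", {
  set.seed(44)
  d <- tibble::tibble(duration_s = rexp(1e4, 2), censored = FALSE)
  fit <- fit_dwell_rate(d)
  expect_lt(abs(fit$rate - 2), 0.05)
  # MLE cross-check: 1/mean
  mle <- fit_dwell_rate(d, method = "mle")
  expect_equal(mle$rate, 1 / mean(d$duration_s), tolerance = 1e-10)

  expect_error(fit_dwell_rate(tibble::tibble(duration_s = rexp(50, 1),
                                             censored = TRUE)),
               class = "spfret_dwell_error")
  expect_error(fit_dwell_rate(rexp(5, 1)), class = "spfret_dwell_error")
})

test_that("frame-quantized dwells recover the exit rate with discretization correction", {
  dt <- 0.015
  k_true <- 1.5
  p_stay <- exp(-k_true * dt)
  cfg <- clean_config(
    n_molecules = 40, n_frames = 3000,
    emission_states = data.frame(mean = c(.3, .7), sd = .05),
    transition_matrix = matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay), 2,
                               byrow = TRUE),
    frame_time = dt, seed = 45)
  sim <- sim_traces(cfg)
  dwells <- extract_dwells(sim$ground_truth$frames, frame_time = dt)
  fit <- fit_dwell_rate(dwells, frame_time = dt)
  expect_lt(abs(fit$rate - k_true), 0.1)
  mle <- fit_dwell_rate(dwells, frame_time = dt, method = "mle")
  expect_lt(abs(mle$rate - k_true), 0.1)
  # first/last dwells are flagged censored
  one <- dwells[dwells$molecule_id == 1, ]
  expect_true(one$censored[1] && one$censored[nrow(one)])
  expect_false(any(one$censored[-c(1, nrow(one))]))
})
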