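# Synthetic-data generator: state paths, forward model, populations,
# survival experiments.

test_that("state paths follow the transition matrix", {
  # absorbing chain: identity matrix keeps the initial state forever
  cfg <- clean_config(n_frames = 200,
                      emission_states = data.frame(mean = c(.2, .8), sd = .05),
                      seed = 4)
  path <- sim_state_path(cfg, 1)
  expect_length(unique(path), 1)

  # linear chain: no direct exchange between the outer states
  cfg3 <- clean_config(
    n_frames = 20000,
    emission_states = data.frame(mean = c(.25, .44, .69), sd = .05),
    transition_matrix = linear_chain_matrix(3, 0.2), seed = 5)
  p3 <- sim_state_path(cfg3, 1)
  jumps <- cbind(p3[-length(p3)], p3[-1])
  expect_false(any(jumps[, 1] == 1 & jumps[, 2] == 3))
  expect_false(any(jumps[, 1] == 3 & jumps[, 2] == 1))
  expect_setequal(unique(p3), 1:3)

  # symmetric two-state chain: empirical switch frequency within 3 SE
  p <- 0.1
  n <- 1e5
  cfg2 <- clean_config(
    n_frames = n, emission_states = data.frame(mean = c(.2, .8), sd = .05),
    transition_matrix = matrix(c(1 - p, p, p, 1 - p), 2, byrow = TRUE),
    seed = 6)
  path2 <- sim_state_path(cfg2, 1)
  freq <- mean(diff(path2) != 0)
  expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("empirical transition frequencies match every matrix cell", {
  A <- matrix(c(.9, .08, .02,
                .05, .9, .05,
                .03, .07, .9), 3, byrow = TRUE)
  cfg <- clean_config(n_frames = 3e4,
                      emission_states = data.frame(mean = c(.2, .5, .8), sd = .05),
                      transition_matrix = A, seed = 7)
  path <- sim_state_path(cfg, 1)
  from <- path[-length(path)]
  to <- path[-1]
  for (i in 1:3) {
    n_i <- sum(from == i)
    for (j in 1:3) {
      phat <- sum(from == i & to == j) / n_i
      se <- sqrt(A[i, j] * (1 - A[i, j]) / n_i)
      expect_lt(abs(phat - A[i, j]), 3 * se + 1e-12)
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(transition_matrix = matrix(c(.5, .4, .1, .9), 2)),
               class = "spfret_config_error")
  expect_error(sim_config(frame_time = 0), class = "spfret_config_error")
  expect_error(sim_config(static_fraction = 1.2), class = "spfret_config_error")
  expect_error(sim_config(emission_states = data.frame(mean = 1.4, sd = .05)),
               class = "spfret_config_error")
  expect_error(sim_config(crosstalk_alpha = 1), class = "spfret_config_error")
})

test_that("the noiseless forward model inverts exactly", {
  cfg <- clean_config(n_frames = 50,
                      emission_states = data.frame(mean = 0.25, sd = 0.03),
                      background = c(0, 0), seed = 8)
  out <- sim_trace(cfg, rep(1L, 50))
  ratio <- out$trace$acceptor_counts /
    (out$trace$acceptor_counts + out$trace$donor_counts)
  expect_equal(ratio, out$frames$e_app, tolerance = 1e-12)
})

test_that("crosstalk and gamma enter the forward model as specified", {
  cfg <- sim_config(n_molecules = 1, n_frames = 20,
                    emission_states = data.frame(mean = 0.5, sd = 0.02),
                    noise_model = "gaussian_read", read_noise_sd = 0,
                    crosstalk_alpha = 0.1, gamma = 0.8, total_intensity = 100,
                    background = c(0, 0),
                    bleach_rate_donor = 0, bleach_rate_acceptor = 0, seed = 9)
  out <- sim_trace(cfg, rep(1L, 20))
  e <- out$frames$e_app
  expect_equal(out$trace$donor_counts, (1 - e) * 100, tolerance = 1e-12)
  expect_equal(out$trace$acceptor_counts,
               0.8 * e * 100 + 0.1 * (1 - e) * 100, tolerance = 1e-12)
})

test_that("acceptor bleaching is a single step that returns the budget to the donor", {
  cfg <- sim_config(n_molecules = 1, n_frames = 300,
                    emission_states = data.frame(mean = 0.6, sd = 0.02),
                    noise_model = "gaussian_read", read_noise_sd = 0,
                    crosstalk_alpha = 0.05, gamma = 0.9,
                    background = c(50, 50), frame_time = 0.015,
                    bleach_rate_donor = 0, bleach_rate_acceptor = 2, seed = 10)
  out <- sim_trace(cfg, rep(1L, 300))
  b <- out$molecule$bleach_acceptor_frame
  expect_false(is.na(b))
  post <- out$trace[out$trace$frame >= b, ]
  # donor at the full budget + background, acceptor at crosstalk + background
  expect_equal(post$donor_counts, rep(500 + 50, nrow(post)), tolerance = 1e-9)
  expect_equal(post$acceptor_counts, rep(0.05 * 500 + 50, nrow(post)),
               tolerance = 1e-9)
  # donor rises in a single step at the bleach frame
  pre_mean <- mean(out$trace$donor_counts[out$trace$frame < b])
  expect_gt(min(post$donor_counts) - pre_mean, 100)
})

test_that("populations are drawn at the requested weights with fixed labels", {
  base <- clean_config(n_molecules = 500, n_frames = 12, seed = 11)
  mix <- tibble::tibble(
    weight = c(0.435, 0.565), label = c("P1", "P2"),
    overrides = list(list(), list(emission_states = data.frame(mean = .7, sd = .05))))
  sim <- sim_population(base, mix)
  counts <- table(sim$ground_truth$molecules$subpop)
  se <- sqrt(0.435 * 0.565 * 500)
  expect_lt(abs(counts[["P1"]] - 0.435 * 500), 3 * se)
  expect_equal(nrow(sim$ground_truth$molecules), 500)
  # one label per molecule, never time-varying
  expect_equal(anyDuplicated(sim$ground_truth$molecules$molecule_id), 0L)

  expect_error(
    sim_population(base, tibble::tibble(weight = c(.5, .4),
                                        label = c("a", "b"),
                                        overrides = list(list(), list()))),
    class = "spfret_config_error")

  single <- sim_population(base, tibble::tibble(weight = 1, label = "only",
                                                overrides = list(list())))
  expect_true(all(single$ground_truth$molecules$subpop == "only"))
})

test_that("static fraction controls the static/dynamic label split", {
  cfg <- clean_config(
    n_molecules = 500, n_frames = 10, static_fraction = 0.6,
    emission_states = data.frame(mean = c(.25, .45, .69), sd = .05),
    transition_matrix = linear_chain_matrix(3, 0.05), seed = 12)
  sim <- sim_traces(cfg)
  # stratified split: the stated fraction is realized exactly
  n_static <- sum(sim$ground_truth$molecules$label == "static")
  expect_equal(n_static, 300)
  # static molecules have constant ground-truth state paths
  st_ids <- sim$ground_truth$molecules$molecule_id[
    sim$ground_truth$molecules$label == "static"]
  frames <- sim$ground_truth$frames
  n_states <- vapply(st_ids, function(id)
    length(unique(frames$state[frames$molecule_id == id])), numeric(1))
  expect_true(all(n_states == 1))
})

test_that("molecule-wise mixture sampling reproduces component structure", {
  comps <- dplyr::filter(tbp_molwise_states(), condition == "dna_tbp")
  v <- sim_molecule_fret(comps, 4000, seed = 13)
  expect_equal(nrow(v), 4000)
  frac1 <- mean(v$component == 1)
  expect_lt(abs(frac1 - 72 / 99), 3 * sqrt(72 / 99 * 27 / 99 / 4000))
  m1 <- mean(v$e_mol[v$component == 1])
  expect_lt(abs(m1 - 0.25), 3 * 0.04 / sqrt(sum(v$component == 1)))
})

test_that("survival experiments draw exponential arms with censoring", {
  # mean lifetime of an uncensored exponential sample
  sc <- survival_config(n_molecules = 1e4, bleach_rate = 0.1,
                        dissociation_rate = 0, frame_time = 0.03,
                        n_frames = 1e4, seed = 14)
  ex <- sim_survival_experiment(sc)
  ctrl <- ex$data[ex$data$arm == "control", ]
  expect_lt(mean(ctrl$censored), 0.06)
  expect_lt(abs(mean(ctrl$time_s[!ctrl$censored]) - 10), 0.4)

  # treatment times are stochastically smaller when dissociation occurs
  sc2 <- survival_config(n_molecules = 500, bleach_rate = 0.1,
                         dissociation_rate = 0.05, frame_time = 0.03,
                         n_frames = 4000, seed = 15)
  ex2 <- sim_survival_experiment(sc2)
  w <- wilcox.test(ex2$data$time_s[ex2$data$arm == "treatment"],
                   ex2$data$time_s[ex2$data$arm == "control"],
                   alternative = "less")
  expect_lt(w$p.value, 0.01)

  # censoring flags: all times within the horizon
  expect_true(all(ex2$data$time_s <= sc2$n_frames * sc2$frame_time))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_molecules = 5, n_frames = 100, seed = 99,
                    emission_states = data.frame(mean = c(.3, .7), sd = .05),
                    transition_matrix = matrix(c(.9, .1, .1, .9), 2, byrow = TRUE))
  s1 <- sim_traces(cfg)
  s2 <- sim_traces(cfg)
  expect_identical(s1$traces, s2$traces)
  expect_identical(s1$ground_truth, s2$ground_truth)
  ex1 <- sim_survival_experiment(survival_config(seed = 7))
  ex2 <- sim_survival_experiment(survival_config(seed = 7))
  expect_identical(ex1$data, ex2$data)
})
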