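# Bleach detection, correction-factor estimation and corrected FRET.

test_that("bleach steps are detected and classified", {
  set.seed(1)
  # constant trace: no events
  tr0 <- manual_trace(rnorm(200, 300, 5), rnorm(200, 200, 5))
  bl0 <- detect_bleach_steps(tr0)
  expect_equal(bl0$order, "none")

  # acceptor bleach at frame 120: acceptor drops, donor rises
  don <- c(rnorm(119, 250, 8), rnorm(81, 500, 8))
  acc <- c(rnorm(119, 225, 8), rnorm(81, 50, 8))
  bl <- detect_bleach_steps(manual_trace(don, acc))
  expect_equal(bl$order, "acceptor_first")
  expect_lt(abs(bl$acceptor_frame - 120), 3)

  # simultaneous two-channel loss: donor/total loss, not acceptor bleach
  don2 <- c(rnorm(100, 300, 8), rnorm(100, 50, 8))
  acc2 <- c(rnorm(100, 250, 8), rnorm(100, 50, 8))
  bl2 <- detect_bleach_steps(manual_trace(don2, acc2))
  expect_equal(bl2$order, "donor_first")
  expect_lt(abs(bl2$donor_frame - 101), 3)
})

test_that("crosstalk estimation is the post-bleach channel ratio", {
  # post-bleach acceptor ~ 0 -> alpha = 0
  don <- c(rep(200, 100), rep(400, 100))
  acc <- c(rep(300, 100), rep(0, 100))
  bl <- list(acceptor_frame = 101L, donor_frame = NA_integer_,
             order = "acceptor_first")
  expect_equal(estimate_crosstalk(manual_trace(don, acc), bl), 0)

  # donor 100, acceptor 5 after bleach -> alpha = 0.05
  don2 <- c(rep(50, 100), rep(100, 100))
  acc2 <- c(rep(60, 100), rep(5, 100))
  expect_equal(estimate_crosstalk(manual_trace(don2, acc2), bl), 0.05)

  # donor-first traces never yield an estimate
  bl_d <- list(acceptor_frame = NA_integer_, donor_frame = 101L,
               order = "donor_first")
  expect_error(estimate_crosstalk(manual_trace(don2, acc2), bl_d),
               class = "spfret_no_bleach_window")
  expect_error(estimate_gamma(manual_trace(don2, acc2), bl_d),
               class = "spfret_no_bleach_window")
})

test_that("gamma estimation is the step-ratio across the acceptor bleach", {
  bl <- list(acceptor_frame = 101L, donor_frame = NA_integer_,
             order = "acceptor_first")
  # equal steps -> gamma = 1
  tr1 <- manual_trace(c(rep(50, 100), rep(100, 100)),
                      c(rep(50, 100), rep(0, 100)))
  expect_equal(estimate_gamma(tr1, bl), 1.0)
  # drop 80 / rise 100 -> gamma = 0.8
  tr2 <- manual_trace(c(rep(60, 100), rep(160, 100)),
                      c(rep(80, 100), rep(0, 100)))
  expect_equal(estimate_gamma(tr2, bl), 0.8)
  # no donor rise -> error
  tr3 <- manual_trace(rep(100, 200), c(rep(80, 100), rep(0, 100)))
  expect_error(estimate_gamma(tr3, bl), class = "spfret_no_bleach_window")
})

test_that("generator correction factors are recovered from bleach events", {
  cfg <- sim_config(n_molecules = 100, n_frames = 400,
                    emission_states = data.frame(mean = 0.5, sd = 0.05),
                    crosstalk_alpha = 0.08, gamma = 0.9,
                    bleach_rate_donor = 0.05, bleach_rate_acceptor = 0.4,
                    seed = 17)
  sim <- sim_traces(cfg)
  fac <- correction_factors(sim$traces, background = c(50, 50),
                            fallback_alpha = 0, fallback_gamma = 1)
  per <- fac[fac$source == "per_molecule", ]
  expect_gt(nrow(per), 30)
  expect_lt(abs(median(per$alpha) - 0.08), 0.01)
  expect_lt(abs(median(per$gamma) - 0.9), 0.05)
  # fallback source recorded for the rest
  expect_true(all(fac$source %in% c("per_molecule", "population_median")))
})

test_that("the corrected FRET formula is applied per frame", {
  tr <- manual_trace(c(75, 100, 100, 50), c(25, 60, 0, 30))
  f0 <- compute_fret(tr[1, ], list(alpha = 0, gamma = 1))
  expect_equal(f0$fret, 0.25)
  f1 <- compute_fret(tr[2, ], list(alpha = 0.1, gamma = 0.8))
  expect_equal(f1$fret, 50 / 130)
  # acceptor at background -> E = 0
  f2 <- compute_fret(tr[3, ], list(alpha = 0, gamma = 1))
  expect_equal(f2$fret, 0)
  # zero denominator -> frame flagged invalid
  f3 <- compute_fret(manual_trace(0, 0), list(alpha = 0, gamma = 1))
  expect_false(f3$valid)
  expect_true(is.na(f3$fret))
})

test_that("zero-noise round trip recovers apparent E below 1e-6", {
  cfg <- sim_config(n_molecules = 5, n_frames = 150,
                    emission_states = data.frame(mean = 0.4, sd = 0.08),
                    noise_model = "gaussian_read", read_noise_sd = 0,
                    crosstalk_alpha = 0.12, gamma = 0.75,
                    bleach_rate_donor = 0, bleach_rate_acceptor = 0, seed = 18)
  sim <- sim_traces(cfg)
  fret <- compute_fret(sim$traces, list(alpha = 0.12, gamma = 0.75),
                       background = sim$config$background)
  expect_lt(max(abs(fret$fret - sim$ground_truth$frames$e_app)), 1e-6)
})

test_that("the analysis window ends at the first bleach event", {
  don <- c(rep(250, 150), rep(500, 150))
  acc <- c(rep(225, 150), rep(0, 150))
  tr <- manual_trace(don, acc)
  fac <- tibble::tibble(molecule_id = 1L, alpha = 0, gamma = 1,
                        acceptor_frame = 151L, donor_frame = NA_integer_)
  f <- compute_fret(tr, fac)
  expect_true(all(f$in_window[1:150]))
  expect_false(any(f$in_window[151:300]))
})

test_that("corrected E means are invariant under the intensity budget", {
  means <- vapply(c(250, 1000), function(budget) {
    cfg <- sim_config(n_molecules = 40, n_frames = 300,
                      emission_states = data.frame(mean = 0.35, sd = 0.05),
                      total_intensity = budget,
                      background = c(budget / 10, budget / 10),
                      read_noise_sd = budget / 50,
                      crosstalk_alpha = 0.08, gamma = 0.9,
                      bleach_rate_donor = 0, bleach_rate_acceptor = 0,
                      seed = 19)
    sim <- sim_traces(cfg)
    fret <- compute_fret(sim$traces, list(alpha = 0.08, gamma = 0.9),
                         background = cfg$background)
    mean(fret$fret)
  }, numeric(1))
  expect_lt(abs(means[1] - means[2]), 0.01)
})

test_that("direct-excitation subtraction and Mot1 calls behave as specified", {
  tr <- manual_trace(rep(500, 20), rep(100, 20))
  tr$ex488_counts <- rep(200, 20)
  expect_equal(correct_direct_excitation(tr, 0)$ex488_counts, rep(200, 20))
  expect_equal(correct_direct_excitation(tr, 0.1)$ex488_counts[1], 150)
  # a series that is pure direct excitation corrects to ~ 0
  tr2 <- tr
  tr2$ex488_counts <- 0.1 * tr2$donor_counts
  expect_equal(correct_direct_excitation(tr2, 0.1)$ex488_counts,
               rep(0, 20))
  expect_error(correct_direct_excitation(manual_trace(1:20, 1:20), 0.1),
               class = "spfret_config_error")

  # Mot1 presence: zero signal and single spikes are FALSE, real signal TRUE
  expect_false(call_mot1_presence(rep(0, 50), bg_mean = 0, bg_sd = 1))
  spike <- rep(0, 50); spike[25] <- 100
  expect_false(call_mot1_presence(spike, bg_mean = 0, bg_sd = 1, window = 1))
  set.seed(20)
  expect_true(call_mot1_presence(rnorm(50, 5, 1), bg_mean = 0, bg_sd = 1))
})

test_that("labeled-Mot1 molecules are called correctly at moderate SNR", {
  set.seed(21)
  calls_pos <- vapply(1:40, function(i)
    call_mot1_presence(rnorm(60, 5, 1), bg_mean = 0, bg_sd = 1), logical(1))
  calls_neg <- vapply(1:40, function(i)
    call_mot1_presence(rnorm(60, 0, 1), bg_mean = 0, bg_sd = 1), logical(1))
  expect_gte(mean(calls_pos), 0.95)
  expect_gte(mean(!calls_neg), 0.95)
})
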