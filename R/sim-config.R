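#' Simulation configuration for synthetic spFRET traces
#'
#' Collects every knob of the two-channel trace generator: state model,
#' camera/noise model, correction factors and photobleaching rates. Defaults
#' emulate a prism-type TIRF measurement of surface-immobilized TBP-DNA
#' complexes on an EMCCD at 15 ms frames, with signal-to-noise comparable to
#' typical single-molecule traces (total budget ~500 counts/frame over
#' ~50 counts/frame/channel background).
#'
#' @param n_molecules Number of molecules to simulate.
#' @param frame_time Frame integration time in seconds (camera range
#'   0.015-0.3 s; default 0.015).
#' @param n_frames Number of frames per trace.
#' @param emission_states Data frame with columns `mean` and `sd`: apparent
#'   FRET efficiency of each state is drawn per frame from
#'   `N(mean, sd)` (frame-wise width, i.e. what a frame-wise histogram shows).
#' @param transition_matrix Row-stochastic matrix of per-frame switch
#'   probabilities between states; must match `nrow(emission_states)`.
#' @param static_fraction Probability that a molecule is static (one state,
#'   no transitions) rather than dynamic.
#' @param total_intensity Photon budget per frame (donor-only counts after
#'   acceptor bleach equal this value).
#' @param crosstalk_alpha Donor leakage fraction into the acceptor channel.
#' @param gamma Relative detection efficiency of acceptor vs donor.
#' @param background Two-element vector, background counts/frame for the
#'   donor and acceptor channel.
#' @param read_noise_sd Gaussian read noise SD in counts.
#' @param noise_model One of `"poisson_read"` (Poisson shot noise plus
#'   Gaussian read noise, the default), `"gaussian_read"` (read noise only)
#'   or `"emccd_excess"` (Poisson variance doubled to emulate the EM excess
#'   noise factor sqrt(2), plus read noise).
#' @param bleach_rate_donor,bleach_rate_acceptor Single-step photobleaching
#'   rates in 1/s (exponential waiting times, independent fluorophores).
#' @param seed Integer seed; all draws for a config are reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_molecules = 5, n_frames = 100)
#' cfg$frame_time
sim_config <- function(n_molecules = 100,
                       frame_time = 0.015,
                       n_frames = 500,
                       emission_states = data.frame(mean = 0.5, sd = 0.05),
                       transition_matrix = diag(nrow(emission_states)),
                       static_fraction = 0,
                       total_intensity = 500,
                       crosstalk_alpha = 0.08,
                       gamma = 0.9,
                       background = c(donor = 50, acceptor = 50),
                       read_noise_sd = 10,
                       noise_model = c("poisson_read", "gaussian_read", "emccd_excess"),
                       bleach_rate_donor = 0.02,
                       bleach_rate_acceptor = 0.02,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  emission_states <- tibble::as_tibble(emission_states)
  if (!all(c("mean", "sd") %in% names(emission_states)))
    abort_spfret("`emission_states` needs columns `mean` and `sd`", "spfret_config_error")
  transition_matrix <- as.matrix(transition_matrix)
  cfg <- structure(
    list(n_molecules = as.integer(n_molecules), frame_time = frame_time,
         n_frames = as.integer(n_frames), emission_states = emission_states,
         transition_matrix = transition_matrix,
         static_fraction = static_fraction,
         total_intensity = total_intensity,
         crosstalk_alpha = crosstalk_alpha, gamma = gamma,
         background = setNames(as.numeric(background), c("donor", "acceptor")),
         read_noise_sd = read_noise_sd, noise_model = noise_model,
         bleach_rate_donor = bleach_rate_donor,
         bleach_rate_acceptor = bleach_rate_acceptor,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$frame_time <= 0)
    abort_spfret("`frame_time` must be > 0", "spfret_config_error")
  if (cfg$static_fraction < 0 || cfg$static_fraction > 1)
    abort_spfret("`static_fraction` must lie in [0, 1]", "spfret_config_error")
  if (any(cfg$emission_states$mean < 0 | cfg$emission_states$mean > 1))
    abort_spfret("emission-state means must lie in [0, 1]", "spfret_config_error")
  if (any(cfg$emission_states$sd <= 0))
    abort_spfret("emission-state SDs must be > 0", "spfret_config_error")
  if (!is_stochastic_matrix(cfg$transition_matrix))
    abort_spfret("`transition_matrix` must be square and row-stochastic", "spfret_config_error")
  if (nrow(cfg$transition_matrix) != nrow(cfg$emission_states))
    abort_spfret("transition matrix size must match the number of emission states",
                 "spfret_config_error")
  if (cfg$crosstalk_alpha < 0 || cfg$crosstalk_alpha >= 1)
    abort_spfret("`crosstalk_alpha` must lie in [0, 1)", "spfret_config_error")
  if (cfg$gamma <= 0)
    abort_spfret("`gamma` must be > 0", "spfret_config_error")
  if (cfg$bleach_rate_donor < 0 || cfg$bleach_rate_acceptor < 0)
    abort_spfret("bleach rates must be >= 0", "spfret_config_error")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_molecules, " molecules x ", x$n_frames,
      " frames @ ", x$frame_time * 1000, " ms, ",
      nrow(x$emission_states), " state(s), static fraction ",
      x$static_fraction, "\n", sep = "")
  invisible(x)
}

#' Linear-chain transition matrix
#'
#' Per-frame switch matrix for a chain of FRET states in which only adjacent
#' states exchange (the low and high state communicate only through the
#' intermediate). Interior states split their exit probability equally
#' between both neighbours.
#'
#' @param n_states Number of states in the chain.
#' @param p_switch Per-frame probability of leaving a state.
#' @return Row-stochastic `n_states` x `n_states` matrix.
#' @export
#' @examples
#' linear_chain_matrix(3, 0.05)
linear_chain_matrix <- function(n_states, p_switch) {
  stopifnot(n_states >= 1, p_switch >= 0, p_switch <= 1)
  m <- diag(1 - p_switch, n_states)
  if (n_states == 1) return(matrix(1, 1, 1))
  for (i in seq_len(n_states)) {
    nb <- c(i - 1, i + 1)
    nb <- nb[nb >= 1 & nb <= n_states]
    m[i, nb] <- p_switch / length(nb)
  }
  m
}

#' Configuration of a paired survival (dissociation) experiment
#'
#' Describes one arm-pair of a molecule-disappearance experiment: a control
#' arm in which immobilized complexes vanish only by photobleaching at
#' `bleach_rate`, and a treatment arm in which they additionally dissociate
#' at `dissociation_rate`, observed for `n_frames` frames of `frame_time`
#' seconds (default 30 ms, the direct red-excitation imaging mode).
#'
#' @param n_molecules Molecules per arm.
#' @param bleach_rate Photobleaching rate k1 in 1/s.
#' @param dissociation_rate Excess disappearance rate in 1/s (>= 0).
#' @param frame_time Frame time in seconds.
#' @param n_frames Observation horizon in frames.
#' @param seed Integer seed.
#' @return An object of class `survival_config`.
#' @export
survival_config <- function(n_molecules = 500, bleach_rate = 0.1,
                            dissociation_rate = 0, frame_time = 0.030,
                            n_frames = 4000, seed = 1L) {
  if (bleach_rate < 0 || dissociation_rate < 0)
    abort_spfret("rates must be >= 0", "spfret_config_error")
  if (frame_time <= 0) abort_spfret("`frame_time` must be > 0", "spfret_config_error")
  structure(list(n_molecules = as.integer(n_molecules),
                 bleach_rate = bleach_rate,
                 dissociation_rate = dissociation_rate,
                 frame_time = frame_time, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "survival_config")
}
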