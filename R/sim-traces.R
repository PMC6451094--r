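#' Simulate a Markov state path for one molecule
#'
#' Realizes the per-frame hidden state sequence of a molecule from the
#' config's per-frame switch matrix. Dynamic molecules start from the
#' stationary distribution of the chain; static molecules sit in a single
#' state for the whole trace.
#'
#' @param config A [sim_config()].
#' @param molecule_index 1-based molecule index (selects the random
#'   substream, so paths are reproducible molecule by molecule).
#' @param static If `TRUE` the path is constant.
#' @param state Optional fixed state for a static molecule; defaults to a
#'   draw from the stationary distribution.
#' @return Integer vector of state indices, length `config$n_frames`.
#' @export
#' @examples
#' cfg <- sim_config(n_frames = 50,
#'                   emission_states = data.frame(mean = c(.2, .6), sd = .05),
#'                   transition_matrix = matrix(c(.9, .1, .1, .9), 2, byrow = TRUE))
#' sim_state_path(cfg, 1)
sim_state_path <- function(config, molecule_index, static = FALSE, state = NULL) {
  validate_sim_config(config)
  if (molecule_index < 1 || molecule_index > config$n_molecules)
    abort_spfret("`molecule_index` out of range", "spfret_config_error")
  n_states <- nrow(config$transition_matrix)
  pstat <- stationary_dist(config$transition_matrix)
  with_seed(substream_seed(config$seed, "path", molecule_index), {
    if (is.null(state)) state <- sample.int(n_states, 1, prob = pstat)
    if (static || n_states == 1) return(rep(as.integer(state), config$n_frames))
    path <- integer(config$n_frames)
    path[1] <- state
    u <- runif(config$n_frames - 1L)
    cum <- apply(config$transition_matrix, 1, cumsum)  # n_states x n_states, col = from
    for (t in seq_len(config$n_frames - 1L)) {
      path[t + 1L] <- which(u[t] <= cum[, path[t]])[1]
    }
    path
  })
}

# Forward model for one molecule: apparent E per frame -> two detected
# channels. Split so that I_A / (I_A + gamma I_D) equals the apparent E,
# i.e. I_D = (1 - E) T and I_A = gamma E T with T the donor-only budget.
render_channels <- function(e_app, config, bleach_a = Inf, bleach_d = Inf) {
  n <- length(e_app)
  frames <- seq_len(n)
  e <- e_app
  e[frames >= bleach_a] <- 0                       # acceptor dark: all budget to donor
  T0 <- config$total_intensity
  i_d <- (1 - e) * T0
  i_a <- config$gamma * e * T0
  alive_d <- frames < bleach_d
  i_d[!alive_d] <- 0
  i_a[!alive_d] <- 0
  donor <- i_d + config$background["donor"]
  acceptor <- i_a + config$crosstalk_alpha * i_d + config$background["acceptor"]
  list(donor = unname(donor), acceptor = unname(acceptor))
}

add_camera_noise <- function(counts, config) {
  switch(config$noise_model,
    gaussian_read = counts + rnorm(length(counts), 0, config$read_noise_sd),
    poisson_read = rpois(length(counts), pmax(counts, 0)) +
      rnorm(length(counts), 0, config$read_noise_sd),
    emccd_excess = {
      lam <- pmax(counts, 0)
      lam + sqrt(2) * (rpois(length(lam), lam) - lam) +
        rnorm(length(lam), 0, config$read_noise_sd)
    })
}

#' Simulate the two-channel intensity trace of one molecule
#'
#' Draws the apparent FRET efficiency of each frame from the emission state
#' along `path`, converts it to ideal donor/acceptor intensities, applies
#' spectral crosstalk, detection-efficiency imbalance, single-step
#' photobleaching, background and camera noise.
#'
#' @inheritParams sim_state_path
#' @param path Integer state path of length `config$n_frames`.
#' @param molecule_id Identifier stored in the output.
#' @return List with `trace` (tibble: molecule_id, frame, time_s,
#'   donor_counts, acceptor_counts), `frames` (per-frame ground truth:
#'   state, apparent E) and `molecule` (per-molecule ground truth incl.
#'   bleach frames, `NA` if the fluorophore outlives the trace).
#' @export
sim_trace <- function(config, path, molecule_id = 1L, molecule_index = molecule_id) {
  validate_sim_config(config)
  if (length(path) != config$n_frames)
    abort_spfret("`path` length must equal `n_frames`", "spfret_config_error")
  with_seed(substream_seed(config$seed, "emit", molecule_index), {
    st <- config$emission_states
    e_app <- rnorm(config$n_frames, st$mean[path], st$sd[path])
    bleach_a <- if (config$bleach_rate_acceptor > 0)
      ceiling(rexp(1, config$bleach_rate_acceptor) / config$frame_time) else Inf
    bleach_d <- if (config$bleach_rate_donor > 0)
      ceiling(rexp(1, config$bleach_rate_donor) / config$frame_time) else Inf
    ch <- render_channels(e_app, config, bleach_a, bleach_d)
    donor <- add_camera_noise(ch$donor, config)
    acceptor <- add_camera_noise(ch$acceptor, config)
    frames <- seq_len(config$n_frames)
    list(
      trace = tibble::tibble(
        molecule_id = molecule_id, frame = frames,
        time_s = (frames - 1L) * config$frame_time,
        donor_counts = donor, acceptor_counts = acceptor),
      frames = tibble::tibble(
        molecule_id = molecule_id, frame = frames, state = path,
        e_app = e_app),
      molecule = tibble::tibble(
        molecule_id = molecule_id,
        bleach_acceptor_frame = if (is.finite(bleach_a) && bleach_a <= config$n_frames)
          as.integer(bleach_a) else NA_integer_,
        bleach_donor_frame = if (is.finite(bleach_d) && bleach_d <= config$n_frames)
          as.integer(bleach_d) else NA_integer_))
  })
}

#' Simulate a homogeneous population of traces
#'
#' Generates `config$n_molecules` traces from one configuration. A fraction
#' `static_fraction` of molecules is static (one state, no transitions);
#' the rest follow the Markov chain.
#'
#' @param config A [sim_config()].
#' @param subpop Label recorded for every molecule (used by
#'   [sim_population()]).
#' @param id_offset Added to molecule ids, for concatenating populations.
#' @return A `fret_sim` object: list with `traces` (one row per molecule and
#'   frame), `ground_truth` (`$molecules`, `$frames`) and `config`.
#' @export
#' @examples
#' sim <- sim_traces(sim_config(n_molecules = 3, n_frames = 50))
#' head(sim$traces)
sim_traces <- function(config, subpop = "pop", id_offset = 0L) {
  validate_sim_config(config)
  # stratified static/dynamic split: the population realizes the stated
  # static fraction exactly (randomly placed), so the generated ground
  # truth is the configured condition, not a binomial draw around it
  n_static <- round(config$n_molecules * config$static_fraction)
  is_static <- with_seed(substream_seed(config$seed, "class", 0L),
    sample(rep(c(TRUE, FALSE), c(n_static, config$n_molecules - n_static))))
  out <- purrr::map(seq_len(config$n_molecules), function(i) {
    path <- sim_state_path(config, i, static = is_static[i])
    sim_trace(config, path, molecule_id = i + id_offset, molecule_index = i)
  })
  molecules <- dplyr::bind_rows(purrr::map(out, "molecule"))
  molecules$label <- ifelse(is_static, "static", "dynamic")
  molecules$subpop <- subpop
  structure(list(
    traces = dplyr::bind_rows(purrr::map(out, "trace")),
    ground_truth = list(molecules = molecules,
                        frames = dplyr::bind_rows(purrr::map(out, "frames"))),
    config = config), class = "fret_sim")
}

#' @export
print.fret_sim <- function(x, ...) {
  cat("<fret_sim> ", nrow(x$ground_truth$molecules), " molecules, ",
      nrow(x$traces), " trace rows\n", sep = "")
  invisible(x)
}

#' Simulate a mixed population of molecule classes
#'
#' Draws each molecule from one of several sub-configurations (e.g.
#' conformational subpopulations with shifted state means, or static vs
#' dynamic classes) and records the class label in the ground truth.
#' Within a run no molecule ever changes its subpopulation label.
#'
#' @param config Base [sim_config()]; per-class entries override its fields.
#' @param mixture Data frame with columns `weight` (summing to 1), `label`
#'   and a list-column `overrides` of named lists passed over the base
#'   config.
#' @return A `fret_sim` object (see [sim_traces()]); ground-truth molecules
#'   carry the class label in `subpop`.
#' @export
sim_population <- function(config, mixture) {
  validate_sim_config(config)
  mixture <- tibble::as_tibble(mixture)
  if (!all(c("weight", "label", "overrides") %in% names(mixture)))
    abort_spfret("`mixture` needs columns weight, label, overrides", "spfret_config_error")
  if (abs(sum(mixture$weight) - 1) > 1e-8)
    abort_spfret("mixture weights must sum to 1", "spfret_config_error")
  k <- with_seed(substream_seed(config$seed, "mixture", 0L),
    sample.int(nrow(mixture), config$n_molecules, replace = TRUE,
               prob = mixture$weight))
  sims <- purrr::map(seq_len(nrow(mixture)), function(j) {
    idx <- which(k == j)
    if (length(idx) == 0) return(NULL)
    fields <- unclass(config)
    ov <- mixture$overrides[[j]]
    if (length(ov)) fields[names(ov)] <- ov
    fields$n_molecules <- length(idx)
    fields$seed <- substream_seed(config$seed, "subcfg", j)
    sub <- do.call(sim_config, fields[setdiff(names(fields), character())])
    sim_traces(sub, subpop = mixture$label[j], id_offset = 0L)
  })
  sims <- purrr::compact(sims)
  # reassign globally unique, interleaved molecule ids
  offset <- 0L
  for (j in seq_along(sims)) {
    n_j <- nrow(sims[[j]]$ground_truth$molecules)
    remap <- function(id) id + offset
    sims[[j]]$traces$molecule_id <- remap(sims[[j]]$traces$molecule_id)
    sims[[j]]$ground_truth$molecules$molecule_id <-
      remap(sims[[j]]$ground_truth$molecules$molecule_id)
    sims[[j]]$ground_truth$frames$molecule_id <-
      remap(sims[[j]]$ground_truth$frames$molecule_id)
    offset <- offset + n_j
  }
  structure(list(
    traces = dplyr::bind_rows(purrr::map(sims, "traces")),
    ground_truth = list(
      molecules = dplyr::bind_rows(purrr::map(sims, ~ .x$ground_truth$molecules)),
      frames = dplyr::bind_rows(purrr::map(sims, ~ .x$ground_truth$frames))),
    config = config, mixture = mixture), class = "fret_sim")
}

#' Sample molecule-wise FRET values from a Gaussian mixture
#'
#' Emulates a molecule-wise FRET histogram directly: each molecule is
#' assigned to a mixture component with probability proportional to the
#' component area and its molecule-wise FRET efficiency is drawn from that
#' component's Gaussian. This is the population model behind molecule-wise
#' histograms of static complexes, where the component SD reflects
#' molecule-to-molecule spread.
#'
#' @param components Data frame with columns `area` (relative weights, any
#'   scale), `mean`, `sd` (FRET efficiency, 0-1 scale).
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @return Tibble with `molecule_id`, `component` (ground truth) and
#'   `e_mol`.
#' @export
#' @examples
#' comps <- dplyr::filter(tbp_molwise_states(), condition == "dna_tbp")
#' sim_molecule_fret(comps, 100, seed = 1)
sim_molecule_fret <- function(components, n, seed = 1L) {
  components <- tibble::as_tibble(components)
  stopifnot(all(c("area", "mean", "sd") %in% names(components)))
  with_seed(substream_seed(seed, "molwise", 0L), {
    k <- sample.int(nrow(components), n, replace = TRUE,
                    prob = components$area / sum(components$area))
    tibble::tibble(molecule_id = seq_len(n), component = k,
                   e_mol = rnorm(n, components$mean[k], components$sd[k]))
  })
}

#' Simulate static traces of a molecule-wise FRET mixture
#'
#' Trace-level counterpart of [sim_molecule_fret()]: each molecule draws a
#' component (by area) and a molecule-wise mean FRET from that component's
#' Gaussian (molecule-to-molecule spread), then emits a static trace whose
#' frames scatter around the molecule's own mean with `frame_sd`. Use this
#' to feed the full correction/histogram pipeline with a population whose
#' molecule-wise histogram reproduces the component structure.
#'
#' @param components Data frame with `area`, `mean`, `sd` columns.
#' @param n_molecules Number of molecules.
#' @param frame_sd Frame-to-frame FRET scatter of a single molecule.
#' @param ... Passed to [sim_config()] (e.g. `n_frames`, noise and bleach
#'   settings).
#' @param seed Integer seed.
#' @return A `fret_sim`; ground-truth molecules carry the component index
#'   in `subpop` and the drawn molecule mean in `e_mol`.
#' @export
sim_molwise_traces <- function(components, n_molecules, frame_sd = 0.03,
                               ..., seed = 1L) {
  draws <- sim_molecule_fret(components, n_molecules, seed = seed)
  draws$e_mol <- pmin(pmax(draws$e_mol, 0), 1)
  base <- sim_config(n_molecules = n_molecules, static_fraction = 1,
                     seed = seed, ...)
  out <- purrr::map(seq_len(n_molecules), function(i) {
    fields <- unclass(base)
    fields$emission_states <- data.frame(mean = draws$e_mol[i], sd = frame_sd)
    fields$transition_matrix <- matrix(1, 1, 1)
    fields$n_molecules <- 1L
    fields$seed <- substream_seed(seed, "molwise_trace", i)
    cfg <- do.call(sim_config, fields)
    sim_trace(cfg, rep(1L, cfg$n_frames), molecule_id = i, molecule_index = 1L)
  })
  molecules <- dplyr::bind_rows(purrr::map(out, "molecule"))
  molecules$label <- "static"
  molecules$subpop <- paste0("S", draws$component)
  molecules$e_mol <- draws$e_mol
  structure(list(
    traces = dplyr::bind_rows(purrr::map(out, "trace")),
    ground_truth = list(molecules = molecules,
                        frames = dplyr::bind_rows(purrr::map(out, "frames"))),
    config = base), class = "fret_sim")
}

#' Mixture specification for a dynamic-subpopulation simulation
#'
#' Builds a [sim_population()] mixture from the reference frame-wise state
#' table: one class per subpopulation of the given condition, each with its
#' three-state emission set, a linear-chain switch matrix and the tabulated
#' subpopulation weight.
#'
#' @param condition Condition name in [tbp_framewise_states()].
#' @param p_switch Per-frame exit probability of the chain.
#' @param weights `"weight2"` (two-subpopulation ratio) or `"weight3"`.
#' @return Mixture tibble for [sim_population()].
#' @export
subpop_mixture <- function(condition, p_switch = 0.05, weights = "weight2") {
  tab <- dplyr::filter(tbp_framewise_states(), .data$condition == !!condition,
                       !is.na(.data[[weights]]))
  if (nrow(tab) == 0) abort_spfret("unknown condition", "spfret_config_error")
  tab |>
    dplyr::group_by(.data$subpop) |>
    dplyr::summarise(weight = .data[[weights]][1],
                     overrides = list(list(
                       emission_states = data.frame(mean = .data$mean, sd = .data$sd),
                       transition_matrix = linear_chain_matrix(dplyr::n(), p_switch))),
                     .groups = "drop") |>
    dplyr::rename(label = "subpop") |>
    dplyr::mutate(weight = .data$weight / sum(.data$weight))
}

#' Simulate a paired survival (dissociation) experiment
#'
#' Generates per-molecule disappearance times for a control arm
#' (photobleaching only, rate k1) and a treatment arm (photobleaching plus
#' dissociation, rate k2 = k1 + dissociation rate). Times are exponential,
#' discretized to the frame grid and right-censored at the observation
#' horizon.
#'
#' @param config A [survival_config()].
#' @return List with `data` (tibble: arm, molecule_id, time_s, censored)
#'   and `truth` (k1, k2).
#' @export
#' @examples
#' ex <- sim_survival_experiment(survival_config(n_molecules = 50, seed = 2))
#' head(ex$data)
sim_survival_experiment <- function(config) {
  stopifnot(inherits(config, "survival_config"))
  k1 <- config$bleach_rate
  k2 <- config$bleach_rate + config$dissociation_rate
  horizon <- config$n_frames * config$frame_time
  draw_arm <- function(rate, arm, idx) {
    t_raw <- with_seed(substream_seed(config$seed, paste0("surv_", arm), 0L),
                       rexp(config$n_molecules, max(rate, 1e-12)))
    if (rate == 0) t_raw <- rep(Inf, config$n_molecules)
    t_disc <- ceiling(t_raw / config$frame_time) * config$frame_time
    censored <- t_disc > horizon
    tibble::tibble(arm = arm, molecule_id = seq_len(config$n_molecules),
                   time_s = pmin(t_disc, horizon), censored = censored)
  }
  list(data = dplyr::bind_rows(draw_arm(k1, "control"), draw_arm(k2, "treatment")),
       truth = list(k1 = k1, k2 = k2,
                    dissociation_rate = config$dissociation_rate),
       config = config)
}
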