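# End-to-end pipeline: config handling, stage orchestration, reporting.

#' Read a pipeline run configuration
#'
#' Configurations are structured text (YAML: key/value with nested
#' sections): a global `seed`, an `output_dir`, the `stages` to run and
#' one section per stage with that stage's parameters. See
#' [default_run_config()] for a complete example.
#'
#' @param path YAML file path.
#' @return Config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Default demo configuration
#'
#' A small end-to-end run: simulate a mixed static population with the
#' reference ternary-complex mixture, correct, classify, and fit the
#' molecule-wise histogram with three components.
#'
#' @param output_dir Where stage outputs are written.
#' @param seed Global seed.
#' @return Config list (class `run_config`).
#' @export
default_run_config <- function(output_dir = tempfile("spfret_run_"), seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    stages = c("simulate", "correct", "classify", "histfit"),
    simulate = list(kind = "molwise_mixture", condition = "dna_tbp_mot1",
                    n_molecules = 300, n_frames = 200, frame_time = 0.015,
                    molwise_frame_sd = 0.03, static_fraction = 1),
    correct = list(fallback_alpha = 0.08, fallback_gamma = 0.9),
    classify = list(min_frames = 20),
    histfit = list(mode = "molecule_wise", n_components = 3, binwidth = 0.02)),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Cross-field checks: stage dependencies (every enabled stage must get
#' its inputs from an earlier enabled stage or from a configured input
#' file), parameter ranges, and transition-matrix stochasticity. Never
#' mutates the config.
#'
#' @param config A `run_config` list.
#' @return `TRUE` when valid, otherwise a character vector of errors
#'   (invisibly `FALSE`-ish: length > 0).
#' @export
validate_run_config <- function(config) {
  errors <- character()
  stages <- config$stages
  known <- c("simulate", "correct", "classify", "histfit", "hmm", "tdp", "survival")
  if (length(setdiff(stages, known)))
    errors <- c(errors, paste("unknown stages:",
                              paste(setdiff(stages, known), collapse = ", ")))
  needs_traces <- intersect(stages, c("correct"))
  if (length(needs_traces) && !"simulate" %in% stages &&
      is.null(config$input_traces))
    errors <- c(errors, "stage 'correct' needs 'simulate' or an input_traces file")
  for (st in intersect(stages, c("classify", "histfit", "hmm"))) {
    if (!"correct" %in% stages)
      errors <- c(errors, sprintf("stage '%s' needs stage 'correct'", st))
  }
  if ("tdp" %in% stages && !"hmm" %in% stages)
    errors <- c(errors, "stage 'tdp' needs stage 'hmm'")
  sim <- config$simulate
  if (!is.null(sim)) {
    if (!is.null(sim$frame_time) && sim$frame_time <= 0)
      errors <- c(errors, "simulate$frame_time must be > 0")
    if (!is.null(sim$n_molecules) && sim$n_molecules < 1)
      errors <- c(errors, "simulate$n_molecules must be >= 1")
    if (!is.null(sim$static_fraction) &&
        (sim$static_fraction < 0 || sim$static_fraction > 1))
      errors <- c(errors, "simulate$static_fraction must lie in [0, 1]")
    if (!is.null(sim$transition_matrix)) {
      m <- do.call(rbind, sim$transition_matrix)
      if (!is_stochastic_matrix(m, tol = 1e-8))
        errors <- c(errors, "simulate$transition_matrix rows must sum to 1")
    }
  }
  sv <- config$survival
  if (!is.null(sv)) {
    if (!is.null(sv$bleach_rate) && sv$bleach_rate < 0)
      errors <- c(errors, "survival$bleach_rate must be >= 0")
    if (!is.null(sv$dissociation_rate) && sv$dissociation_rate < 0)
      errors <- c(errors, "survival$dissociation_rate must be >= 0")
  }
  if (length(errors)) errors else TRUE
}

pipeline_simulate <- function(config) {
  p <- config$simulate
  seed <- substream_seed(config$seed, "stage_simulate", 0L)
  if (identical(p$kind, "molwise_mixture")) {
    comps <- dplyr::filter(tbp_molwise_states(), .data$condition == p$condition)
    sim_molwise_traces(comps, p$n_molecules,
                       frame_sd = p$molwise_frame_sd %||% 0.03,
                       n_frames = p$n_frames,
                       frame_time = p$frame_time %||% 0.015,
                       seed = seed)
  } else if (identical(p$kind, "subpop_mixture")) {
    base <- sim_config(n_molecules = p$n_molecules, n_frames = p$n_frames,
                       frame_time = p$frame_time %||% 0.015,
                       static_fraction = p$static_fraction %||% 0,
                       bleach_rate_donor = p$bleach_rate_donor %||% 0.02,
                       bleach_rate_acceptor = p$bleach_rate_acceptor %||% 0.02,
                       seed = seed)
    sim_population(base, subpop_mixture(p$condition,
                                        p_switch = p$p_switch %||% 0.05))
  } else {
    states <- if (is.null(p$emission_states))
      data.frame(mean = 0.5, sd = 0.05)
    else as.data.frame(p$emission_states)
    tm <- if (!is.null(p$transition_matrix)) do.call(rbind, p$transition_matrix)
      else if (!is.null(p$p_switch)) linear_chain_matrix(nrow(states), p$p_switch)
      else diag(nrow(states))
    cfg <- sim_config(
      n_molecules = p$n_molecules %||% 100, n_frames = p$n_frames %||% 500,
      frame_time = p$frame_time %||% 0.015, emission_states = states,
      transition_matrix = tm, static_fraction = p$static_fraction %||% 0,
      seed = seed)
    sim_traces(cfg)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the spFRET analysis pipeline
#'
#' Executes the enabled stages in order (simulate, correct, classify,
#' histfit, hmm, tdp, survival), writing every intermediate artifact as a
#' delimited text table under `output_dir`. Two runs with the same config
#' produce byte-identical tables. A failing stage aborts with the stage
#' name; artifacts of completed stages remain on disk.
#'
#' @param config A `run_config` list or a YAML file path.
#' @return A `run_report`: per-stage molecule counts, result tables, the
#'   package version and a config hash.
#' @export
#' @examples
#' rep <- run_pipeline(default_run_config(seed = 42))
#' rep$counts
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  val <- validate_run_config(config)
  if (!isTRUE(val))
    abort_spfret(paste("invalid config:", paste(val, collapse = "; ")),
                 "spfret_config_error")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  counts <- list()
  tables <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort_spfret(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   "spfret_stage_error"))
  }

  sim <- NULL; fret <- NULL; labels <- NULL; models <- NULL

  if ("simulate" %in% config$stages) {
    sim <- stage("simulate", pipeline_simulate(config))
    write_trace_table(sim$traces, out("traces.tsv"))
    write_ground_truth(sim, out("ground_truth.tsv"))
    counts$simulated <- nrow(sim$ground_truth$molecules)
  }
  traces <- if (!is.null(sim)) sim$traces else
    read_trace_table(config$input_traces)

  if ("correct" %in% config$stages) {
    p <- config$correct %||% list()
    bg <- if (!is.null(sim)) unname(sim$config$background) else
      p$background %||% c(0, 0)
    fret <- stage("correct", {
      fac <- correction_factors(traces, background = bg,
                                fallback_alpha = p$fallback_alpha %||% 0,
                                fallback_gamma = p$fallback_gamma %||% 1)
      write_trace_table(fac, out("corrections.tsv"))
      tables$corrections <- fac
      compute_fret(traces, fac, background = bg)
    })
    write_trace_table(fret, out("fret.tsv"))
    counts$corrected <- dplyr::n_distinct(fret$molecule_id)
  }

  if ("classify" %in% config$stages) {
    p <- config$classify %||% list()
    labels <- stage("classify",
      classify_traces(fret, min_frames = p$min_frames %||% 20,
                      frame_time = config$simulate$frame_time %||% 0.015,
                      seed = substream_seed(config$seed, "stage_classify", 0L)))
    write_trace_table(labels, out("labels.tsv"))
    counts$static <- sum(labels$label == "static")
    counts$dynamic <- sum(labels$label == "dynamic")
    tables$labels <- labels
  }

  if ("histfit" %in% config$stages) {
    p <- config$histfit %||% list()
    fit <- stage("histfit", {
      h <- build_fret_histogram(fret, mode = p$mode %||% "molecule_wise",
                                labels = labels,
                                include_dynamic = is.null(labels),
                                binwidth = p$binwidth %||% 0.02)
      fit_fret_mixture(h, p$n_components %||% 3)
    })
    write_trace_table(tidy(fit), out("mixture_fit.tsv"))
    tables$mixture_fit <- tidy(fit)
    tables$mixture_glance <- glance(fit)
  }

  if ("hmm" %in% config$stages) {
    p <- config$hmm %||% list()
    dyn_ids <- if (!is.null(labels))
      labels$molecule_id[labels$label == "dynamic"] else unique(fret$molecule_id)
    models <- stage("hmm", {
      purrr::map(dyn_ids, function(id) {
        e <- fret$fret[fret$molecule_id == id & fret$in_window & fret$valid]
        m <- fit_fret_hmm(e, p$n_states %||% 3,
                          frame_time = config$simulate$frame_time %||% 0.015,
                          seed = substream_seed(config$seed, "stage_hmm", id))
        decode_path(m, molecule_id = id)
      })
    })
    trans <- dplyr::bind_rows(purrr::map(models, "transitions"))
    write_trace_table(trans, out("transitions.tsv"))
    tables$transitions <- trans
    counts$hmm_molecules <- length(models)
  }

  if ("tdp" %in% config$stages) {
    p <- config$tdp %||% list()
    tdp <- stage("tdp", build_tdp(tables$transitions,
                                  kernel_width = p$kernel_width %||% 0.03))
    grid_tab <- tibble::tibble(
      e_from = rep(tdp$x, times = length(tdp$y)),
      e_to = rep(tdp$y, each = length(tdp$x)),
      density = as.vector(tdp$density))
    write_trace_table(grid_tab, out("tdp.tsv"))
    tables$tdp <- tdp
  }

  if ("survival" %in% config$stages) {
    p <- config$survival %||% list()
    res <- stage("survival", {
      sc <- survival_config(
        n_molecules = p$n_molecules %||% 500,
        bleach_rate = p$bleach_rate %||% 0.1,
        dissociation_rate = p$dissociation_rate %||% 0,
        frame_time = p$frame_time %||% 0.030,
        n_frames = p$n_frames %||% 4000,
        seed = substream_seed(config$seed, "stage_survival", 0L))
      ex <- sim_survival_experiment(sc)
      ctrl <- build_survival(dplyr::filter(ex$data, .data$arm == "control"),
                             condition = "control")
      trt <- build_survival(dplyr::filter(ex$data, .data$arm == "treatment"),
                            condition = p$condition %||% "treatment")
      dissociation_rate(ctrl, trt, condition = p$condition %||% "treatment")
    })
    write_trace_table(res, out("dissociation.tsv"))
    tables$dissociation <- res
  }

  structure(list(counts = counts, tables = tables,
                 config = config,
                 config_hash = rlang::hash(unclass(config)),
                 version = as.character(utils::packageVersion("spfret"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> spfret ", x$version, ", config ", substr(x$config_hash, 1, 8),
      "\n  counts: ", paste(names(x$counts), unlist(x$counts), sep = "=",
                            collapse = ", "),
      "\n  tables: ", paste(names(x$tables), collapse = ", "), "\n", sep = "")
  invisible(x)
}
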