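#' Reference FRET-population parameters for TBP--promoter complexes
#'
#' Gaussian-population parameters (relative area in %, mean and SD in FRET
#' efficiency %) that characterise molecule-wise FRET histograms of
#' TBP complexes on an H2B-promoter construct labeled between downstream DNA
#' and TBP, under three conditions: the binary DNA/TBP complex, the ternary
#' DNA/TBP/Mot1 complex, and the ternary complex after ATP addition. The
#' low-FRET population is a composite of a main component (mean 25, SD 4)
#' and a small shoulder (mean 18, SD 7) whose areas are conventionally
#' combined. These parameter sets are the simulation presets used throughout
#' the package's recovery tests.
#'
#' @return Tibble with columns `condition`, `component`, `area` (%),
#'   `mean` and `sd` (FRET efficiency, 0-1 scale).
#' @export
#' @examples
#' tbp_molwise_states()
tbp_molwise_states <- function() {
  tibble::tribble(
    ~condition,           ~component, ~area, ~mean, ~sd,
    "dna_tbp",            1L,         72,    0.25,  0.04,
    "dna_tbp",            2L,         27,    0.34,  0.13,
    "dna_tbp_mot1",       1L,          6,    0.24,  0.04,
    "dna_tbp_mot1",       2L,         28,    0.34,  0.13,
    "dna_tbp_mot1",       3L,         65,    0.78,  0.07,
    "dna_tbp_mot1_atp",   1L,         49,    0.24,  0.04,
    "dna_tbp_mot1_atp",   2L,         43,    0.32,  0.13,
    "dna_tbp_mot1_atp",   3L,          8,    0.77,  0.07)
}

#' Shared four-state component set for global amplitude-only fits
#'
#' The four Gaussian states (low-FRET shoulder, low-FRET main, intermediate,
#' high) whose positions and widths are held fixed across conditions while
#' only amplitudes vary in a global fit of molecule-wise histograms.
#'
#' @return Tibble with columns `component`, `mean`, `sd`.
#' @export
tbp_global_states <- function() {
  tibble::tibble(component = 1:4,
                 mean = c(0.18, 0.25, 0.34, 0.78),
                 sd = c(0.07, 0.04, 0.13, 0.07))
}

#' Reference frame-wise FRET states of dynamic dual-labeled promoter DNA
#'
#' Three-state parameter sets (area %, mean and SD in FRET efficiency) per
#' molecule subpopulation for dynamic dual-labeled H2B-promoter DNA bound by
#' TBP, with and without TFIIA or Mot1 (and Mot1 + ATP). Subpopulation
#' weights give the fraction of molecules in each subpopulation: `weight2`
#' is the two-subpopulation (P1/P2) ratio, `weight3` the three-subpopulation
#' ratio where a minor P3 class was resolved. States are ordered S1 < S2 <
#' S3 by mean FRET within each subpopulation, and the chain is linear: the
#' outer states exchange only via S2.
#'
#' @return Tibble with columns `condition`, `subpop`, `weight2`, `weight3`,
#'   `state`, `area` (%), `mean`, `sd` (FRET efficiency, 0-1 scale).
#' @export
#' @examples
#' dplyr::filter(tbp_framewise_states(), condition == "dna_tbp")
tbp_framewise_states <- function() {
  tibble::tribble(
    ~condition,          ~subpop, ~weight2, ~weight3, ~state, ~area, ~mean, ~sd,
    "dna_tbp",           "P1",    0.435,    NA,       1L,     18,    0.25,  0.09,
    "dna_tbp",           "P1",    0.435,    NA,       2L,     51,    0.44,  0.08,
    "dna_tbp",           "P1",    0.435,    NA,       3L,     31,    0.69,  0.09,
    "dna_tbp",           "P2",    0.564,    NA,       1L,     21,    0.32,  0.10,
    "dna_tbp",           "P2",    0.564,    NA,       2L,     39,    0.59,  0.07,
    "dna_tbp",           "P2",    0.564,    NA,       3L,     40,    0.76,  0.07,
    "dna_tbp_tfiia",     "P1",    0.183,    0.162,    1L,      9,    0.19,  0.06,
    "dna_tbp_tfiia",     "P1",    0.183,    0.162,    2L,     53,    0.41,  0.09,
    "dna_tbp_tfiia",     "P1",    0.183,    0.162,    3L,     39,    0.68,  0.07,
    "dna_tbp_tfiia",     "P2",    0.817,    0.722,    1L,     11,    0.29,  0.10,
    "dna_tbp_tfiia",     "P2",    0.817,    0.722,    2L,     48,    0.56,  0.07,
    "dna_tbp_tfiia",     "P2",    0.817,    0.722,    3L,     41,    0.75,  0.06,
    "dna_tbp_tfiia",     "P3",    NA,       0.117,    1L,      6,    0.32,  0.12,
    "dna_tbp_tfiia",     "P3",    NA,       0.117,    2L,     51,    0.68,  0.07,
    "dna_tbp_tfiia",     "P3",    NA,       0.117,    3L,     43,    0.83,  0.05,
    "dna_tbp_mot1",      "P1",    0.418,    0.344,    1L,     15,    0.25,  0.08,
    "dna_tbp_mot1",      "P1",    0.418,    0.344,    2L,     39,    0.45,  0.09,
    "dna_tbp_mot1",      "P1",    0.418,    0.344,    3L,     46,    0.69,  0.07,
    "dna_tbp_mot1",      "P2",    0.582,    0.479,    1L,     10,    0.30,  0.10,
    "dna_tbp_mot1",      "P2",    0.582,    0.479,    2L,     43,    0.57,  0.08,
    "dna_tbp_mot1",      "P2",    0.582,    0.479,    3L,     47,    0.76,  0.06,
    "dna_tbp_mot1",      "P3",    NA,       0.178,    1L,     51,    0.35,  0.11,
    "dna_tbp_mot1",      "P3",    NA,       0.178,    2L,     44,    0.61,  0.06,
    "dna_tbp_mot1",      "P3",    NA,       0.178,    3L,      5,    0.81,  0.06,
    "dna_tbp_mot1_atp",  "P1",    0.231,    0.202,    1L,     23,    0.25,  0.07,
    "dna_tbp_mot1_atp",  "P1",    0.231,    0.202,    2L,     30,    0.45,  0.07,
    "dna_tbp_mot1_atp",  "P1",    0.231,    0.202,    3L,     47,    0.68,  0.07,
    "dna_tbp_mot1_atp",  "P2",    0.770,    0.675,    1L,     11,    0.30,  0.11,
    "dna_tbp_mot1_atp",  "P2",    0.770,    0.675,    2L,     39,    0.56,  0.06,
    "dna_tbp_mot1_atp",  "P2",    0.770,    0.675,    3L,     50,    0.74,  0.06,
    "dna_tbp_mot1_atp",  "P3",    NA,       0.124,    1L,     15,    0.32,  0.14,
    "dna_tbp_mot1_atp",  "P3",    NA,       0.124,    2L,     42,    0.67,  0.07,
    "dna_tbp_mot1_atp",  "P3",    NA,       0.124,    3L,     43,    0.82,  0.04)
}

#' Reference dissociation rates of TBP from the H2B promoter
#'
#' Photobleaching-corrected TBP dissociation rates (k2 - k1, 1/s) measured
#' for free Mot1 added in solution together with 1 mM ATP to preformed
#' DNA/TBP/Mot1 complexes, by Mot1 concentration. Controls with ADP, without
#' free Mot1, or with ATPgammaS show no dissociation. Used as ground-truth
#' presets by the survival-experiment generator.
#'
#' @return Tibble with columns `condition`, `mot1_nM`, `rate` (1/s).
#' @export
tbp_dissociation_rates <- function() {
  tibble::tribble(
    ~condition,            ~mot1_nM, ~rate,
    "atp_mot1_1nM",        1,        0.02,
    "atp_mot1_3.4nM",      3.4,      0.05,
    "atp_mot1_12nM",       12,       0.2,
    "atp_only",            0,        0,
    "adp_mot1",            3.4,      0,
    "atpgs_mot1",          3.4,      0)
}
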