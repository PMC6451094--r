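# Internal helpers shared across modules.

# Derive a reproducible substream seed from a base seed, a stage name and an
# index, staying inside the 32-bit integer range. Different stages get
# disjoint streams so toggling one stage does not reshuffle another's draws.
substream_seed <- function(seed, stage, index = 0L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + stage_code * 1299721 + index * 2654435) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_stochastic_matrix <- function(m, tol = 1e-12) {
  is.matrix(m) && nrow(m) == ncol(m) && all(m >= -tol) &&
    all(abs(rowSums(m) - 1) <= tol)
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
stationary_dist <- function(m) {
  e <- eigen(t(m))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

abort_spfret <- function(msg, class) {
  rlang::abort(msg, class = c(class, "spfret_error"))
}
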