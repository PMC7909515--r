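# Small shared helpers.

# Round half away from zero, matching the reporting style of benchmark
# percentages (base round() rounds half to even).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Self-contained RNG stream: draws are reproducible from `seed` and never
# disturb (or depend on) the caller's global RNG state.
local_rng <- function(seed) {
  state <- NULL
  run <- function(fn, ...) {
    had <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, globalenv())
    res <- fn(...)
    state <<- get(".Random.seed", globalenv())
    if (had) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
    res
  }
  list(runif = function(...) run(stats::runif, ...),
       rnorm = function(...) run(stats::rnorm, ...),
       rpois = function(...) run(stats::rpois, ...),
       rbinom = function(...) run(stats::rbinom, ...),
       sample = function(...) run(base::sample, ...))
}

# Derive a per-task sub-seed from a master seed, kept within 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

# Write a data.frame as TSV via a temp file + rename so readers never see a
# partial file.
write_tsv_atomic <- function(df, path, col.names = TRUE) {
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  file.rename(tmp, path)
  invisible(path)
}
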