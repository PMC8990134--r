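# Shared synthetic fixtures, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# light session for structural tests
quick_session <- function(duration = 30, seed = 1, m = 0.5, cadence = 0.75) {
  key <- sprintf("sess_%g_%d_%g_%g", duration, seed, m, cadence)
  cached(key, generate_session(synth_config(
    duration = duration, seed = seed,
    gait = gait_model(cadence = cadence),
    coupling = coupling_spec(m = matrix(m, 8, 6)))))
}

quick_prep <- function(duration = 30, seed = 1, m = 0.5, cadence = 0.75) {
  key <- sprintf("prep_%g_%d_%g_%g", duration, seed, m, cadence)
  cached(key, preprocess_session(quick_session(duration, seed, m, cadence)))
}

# strongly coupled 60 s session used by decoder-learning tests
strong_prep <- function() {
  cached("strong_prep", {
    s <- generate_session(synth_config(
      duration = 60, seed = 7, gait = gait_model(cadence = 0.72),
      coupling = coupling_spec(m = matrix(0.8, 8, 6))))
    preprocess_session(s)
  })
}

# tiny CNN configuration for fast unit tests
tiny_cnn <- function(seed = 0, ...) {
  cnn_config(n_filters = 2, hidden = 8, seed = seed, ...)
}

# desk-scale CNN used by recovery experiments (architecture and training
# regime as published; capacity reduced to fit a single-CPU test budget)
desk_cnn <- function(seed = 0, ...) {
  cnn_config(n_filters = 4, hidden = 32, seed = seed, ...)
}

rms <- function(x) sqrt(mean(x^2))
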