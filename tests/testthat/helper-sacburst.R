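# Shared helpers for the test suite.

default_params <- function(...) sac_params(...)

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# Synthetic calcium trace on a regular grid (ms).
make_calcium_trace <- function(t_end, dt, level_fun) {
  tt <- seq(0, t_end, by = dt)
  list(times = tt, C = vapply(tt, level_fun, 0))
}
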