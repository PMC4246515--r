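# canonical parameter sets used across the suite:
# maize control-like growth curve and its cell-length profile
ctrl_params <- function() growth_params(Lm = 535, t0 = 0, tm = 167, te = 231)
ctrl_cells <- function() cell_profile_params(Lb = 10.9, Lm = 118.5,
                                             Pm = 21.3, Pe = 43.4)

# daily sampling at constant 24 C over a 10 C base: 14 degree-days/day
daily_schedule <- function(days = 17) seq(0, days) * 14

# random valid growth parameter sets for property tests
random_growth_params <- function(n, seed = 101) {
  with_seed_local(seed, replicate(n, {
    Lm <- stats::runif(1, 80, 1200)
    tm <- stats::runif(1, 80, 300)
    te <- tm + stats::runif(1, 30, 200)
    growth_params(Lm, 0, tm, te)
  }, simplify = FALSE))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
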