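#' Simulate one leaf-length series from the beta sigmoid
#'
#' Evaluates the growth curve on a sampling schedule and adds additive
#' Gaussian measurement noise (a ruler-style instrument error), truncating
#' at 0. Reproducible for a given seed.
#'
#' @param params A [growth_params()] object (the generating truth).
#' @param t Sampling schedule in degree-days (e.g. daily measurements at
#'   14 degree-days per day: `seq(0, 238, by = 14)`). At least 2 points.
#' @param sd Additive Gaussian noise standard deviation, mm. `0` gives
#'   exact model values.
#' @param seed Optional integer seed; when supplied the series is
#'   reproducible and the caller's RNG state is untouched.
#' @param leaf_id,group Identifier columns stamped on the output.
#'
#' @return A tibble with columns `leaf_id`, `group`, `t`, `length`.
#' @examples
#' p <- growth_params(535, 0, 167, 231)
#' simulate_leaf_series(p, t = seq(0, 238, by = 14), sd = 5, seed = 42)
#' @export
simulate_leaf_series <- function(params, t, sd = 0, seed = NULL,
                                 leaf_id = "leaf1", group = "control") {
  stopifnot(inherits(params, "growth_params"), is.numeric(t),
            length(t) >= 2, sd >= 0)
  if (any(diff(t) <= 0)) {
    stop("sampling schedule must be strictly increasing", call. = FALSE)
  }
  mu <- beta_length(params, t)
  noise <- with_seed(seed, stats::rnorm(length(t), 0, sd))
  tibble::tibble(leaf_id = leaf_id, group = group, t = t,
                 length = pmax(mu + noise, 0))
}

#' Simulate one cell-length profile from the extended beta sigmoid
#'
#' Evaluates the cell-length profile on a positional schedule and adds
#' noise. Cell lengths scatter strongly even between adjacent cells and
#' the scatter grows with cell size, so the default noise model is
#' multiplicative (`length * (1 + cv * N(0,1))`); additive Gaussian noise
#' is available through `sd`. Values are floored at a small positive
#' length.
#'
#' @param params A [cell_profile_params()] object.
#' @param p Positional schedule, mm from the leaf base (e.g.
#'   `seq(0.5, 60, by = 0.5)`).
#' @param cv Multiplicative noise coefficient of variation.
#' @param sd Additive noise standard deviation, um (used when `cv = 0`).
#' @inheritParams simulate_leaf_series
#'
#' @return A tibble with columns `leaf_id`, `group`, `position`,
#'   `cell_length`.
#' @examples
#' cp <- cell_profile_params(10.9, 118.5, 21.3, 43.4)
#' simulate_cell_profile(cp, p = seq(0.5, 60, by = 0.5), cv = 0.25,
#'                       seed = 7)
#' @export
simulate_cell_profile <- function(params, p, cv = 0, sd = 0, seed = NULL,
                                  leaf_id = "leaf1", group = "control") {
  stopifnot(inherits(params, "cell_profile_params"), is.numeric(p),
            length(p) >= 2, cv >= 0, sd >= 0)
  if (any(diff(p) <= 0) || any(p < 0)) {
    stop("positions must be nonnegative and strictly increasing",
         call. = FALSE)
  }
  mu <- cell_length_at(params, p)
  z <- with_seed(seed, stats::rnorm(length(p)))
  len <- if (cv > 0) mu * (1 + cv * z) else mu + sd * z
  tibble::tibble(leaf_id = leaf_id, group = group, position = p,
                 cell_length = pmax(len, 0.1))
}

#' Simulate a two-cohort leaf-growth experiment
#'
#' Generates a control-like and a treatment-like cohort of leaves with
#' per-leaf biological variation around the cohort mean parameters plus
#' additive measurement noise, emulating a daily-measurement greenhouse
#' experiment (14 degree-days per day at constant 24 C over a 10 C base).
#' Cohort defaults mirror a typical maize overexpression experiment:
#' control (Lm 535 mm, tm 167, te 231 degree-days; n = 9) versus a larger,
#' later transgenic cohort (Lm 743, tm 180, te 246; n = 11).
#'
#' @param n Integer vector of cohort sizes, one per cohort.
#' @param params List of [growth_params()] cohort means (same length as
#'   `n`).
#' @param groups Cohort labels.
#' @param t Sampling schedule, degree-days.
#' @param sd Measurement noise sd, mm.
#' @param cv_bio Between-leaf coefficient of variation applied to
#'   `Lm`, `tm` and `te - tm` (per-leaf biological variation).
#' @param seed Integer seed (reproducible experiment).
#'
#' @return A long-format tibble (`leaf_id`, `group`, `t`, `length`) of
#'   all leaves.
#' @examples
#' exp <- simulate_experiment(seed = 1)
#' dplyr::count(exp, group)
#' @export
simulate_experiment <- function(n = c(9, 11),
                                params = list(
                                  growth_params(535, 0, 167, 231),
                                  growth_params(743, 0, 180, 246)),
                                groups = c("control", "transgenic"),
                                t = seq(0, 17) * 14,
                                sd = 5, cv_bio = 0.04, seed = 1) {
  stopifnot(length(n) == length(params), length(n) == length(groups))
  with_seed(seed, {
    purrr::map_dfr(seq_along(n), function(g) {
      purrr::map_dfr(seq_len(n[g]), function(i) {
        pg <- params[[g]]
        Lm_i <- pg$Lm * (1 + cv_bio * stats::rnorm(1))
        tm_i <- pg$tm * (1 + cv_bio * stats::rnorm(1))
        dte_i <- (pg$te - pg$tm) * (1 + cv_bio * stats::rnorm(1))
        pi_ <- growth_params(max(Lm_i, 1), pg$t0,
                             max(tm_i, pg$t0 + 1), max(tm_i, pg$t0 + 1) +
                               max(dte_i, 1))
        mu <- beta_length(pi_, t)
        tibble::tibble(
          leaf_id = sprintf("%s_%02d", groups[g], i),
          group = groups[g], t = t,
          length = pmax(mu + stats::rnorm(length(t), 0, sd), 0))
      })
    })
  })
}

# run code with a temporary RNG state; NULL seed = use current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
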