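#' Leaf length under the beta sigmoid growth function
#'
#' Evaluates the beta sigmoid determinate-growth function
#' \deqn{L(t) = L_m \left(1 + \frac{t_e - t}{t_e - t_m}\right)
#'   \left(\frac{t - t_0}{t_e - t_0}\right)^{\frac{t_e - t_0}{t_e - t_m}}}
#' for `t0 <= t <= te`. Beyond `te` growth has ceased and the function
#' plateaus at `Lm`; before `t0` the leaf has not initiated and length is 0.
#'
#' @param params A [growth_params()] object.
#' @param t Thermal time(s), degree-days. Vectorised.
#'
#' @return Leaf length(s) in mm, same length as `t`.
#' @examples
#' p <- growth_params(535, 0, 167, 231)
#' beta_length(p, c(0, 167, 231, 300))
#' @export
beta_length <- function(params, t) {
  stopifnot(inherits(params, "growth_params"), is.numeric(t))
  Lm <- params$Lm; t0 <- params$t0; tm <- params$tm; te <- params$te
  out <- numeric(length(t))
  inside <- t >= t0 & t <= te
  ti <- t[inside]
  ex <- (te - t0) / (te - tm)
  out[inside] <- Lm * (1 + (te - ti) / (te - tm)) *
    ((ti - t0) / (te - t0))^ex
  out[t > te] <- Lm
  out
}

#' Leaf elongation rate (LER) of the beta sigmoid
#'
#' Analytic first derivative of [beta_length()] with respect to thermal
#' time: the bell-shaped leaf elongation rate curve, zero at `t0` and `te`
#' with a single maximum at `tm`. Outside `[t0, te]` the rate is 0.
#'
#' @inheritParams beta_length
#' @return Elongation rate(s), mm per degree-day.
#' @examples
#' p <- growth_params(535, 0, 167, 231)
#' beta_rate(p, c(0, 167, 231))
#' @export
beta_rate <- function(params, t) {
  stopifnot(inherits(params, "growth_params"), is.numeric(t))
  Lm <- params$Lm; t0 <- params$t0; tm <- params$tm; te <- params$te
  out <- numeric(length(t))
  inside <- t >= t0 & t <= te
  ti <- t[inside]
  u <- (ti - t0) / (te - t0)
  # dL/dt = Lm/(te-tm) * u^((tm-t0)/(te-tm)) * (1 + (te-t)/(te-tm) - u)
  out[inside] <- Lm / (te - tm) * u^((tm - t0) / (te - tm)) *
    (1 + (te - ti) / (te - tm) - u)
  out
}

#' Maximal leaf elongation rate (LERmax)
#'
#' Closed form for the maximum of the elongation-rate curve, attained at
#' `tm`:
#' \deqn{LER_{max} = L_m \frac{2t_e - t_m - t_0}{(t_e - t_m)(t_e - t_0)}
#'   \left(\frac{t_m - t_0}{t_e - t_0}\right)^{\frac{t_m - t_0}{t_e - t_m}}}
#'
#' @inheritParams beta_length
#' @return A tibble with columns `tm` (degree-days) and `lermax`
#'   (mm per degree-day).
#' @examples
#' beta_max_rate(growth_params(535, 0, 167, 231))
#' @export
beta_max_rate <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  Lm <- params$Lm; t0 <- params$t0; tm <- params$tm; te <- params$te
  lermax <- Lm * (2 * te - tm - t0) / ((te - tm) * (te - t0)) *
    ((tm - t0) / (te - t0))^((tm - t0) / (te - tm))
  tibble::tibble(tm = tm, lermax = lermax)
}

#' Thermal time at which the leaf reaches a given length
#'
#' Numerically inverts [beta_length()]: the unique `t` in `(t0, te]` at
#' which the fitted leaf attains length `L`. The inverse is found by a
#' bracketed root search (monotone interval), relative tolerance 1e-9 on
#' the abscissa. `time_at_length(params, Lm)` returns `te` exactly.
#'
#' @inheritParams beta_length
#' @param L Target leaf length(s), mm; each must lie in `(0, Lm]`.
#'
#' @return Thermal time(s) in degree-days, same length as `L`.
#' @examples
#' p <- growth_params(535, 0, 167, 231)
#' time_at_length(p, 100)   # thermal time at 100 mm
#' @export
time_at_length <- function(params, L) {
  stopifnot(inherits(params, "growth_params"), is.numeric(L))
  Lm <- params$Lm; t0 <- params$t0; te <- params$te
  if (any(L <= 0 | L > Lm)) {
    stop("target length must lie in (0, Lm]", call. = FALSE)
  }
  vapply(L, function(Lq) {
    if (Lq == Lm) return(te)
    eps <- 1e-9 * (te - t0)
    stats::uniroot(function(t) beta_length(params, t) - Lq,
                   lower = t0 + eps, upper = te,
                   tol = 1e-9 * (te - t0))$root
  }, numeric(1))
}

#' Thermal time at which the leaf reaches a fraction of its final length
#'
#' Convenience inverse: `time_at_fraction(params, f)` equals
#' `time_at_length(params, f * Lm)`. Typical fractions are 0.2, 0.5 and
#' 0.9, giving the timing points t20%, t50% and t90%.
#'
#' @inheritParams beta_length
#' @param f Fraction(s) of final length, each in `(0, 1]`.
#' @return Thermal time(s), degree-days.
#' @examples
#' time_at_fraction(growth_params(535, 0, 167, 231), c(0.2, 0.5, 0.9))
#' @export
time_at_fraction <- function(params, f) {
  stopifnot(inherits(params, "growth_params"), is.numeric(f))
  if (any(f <= 0 | f > 1)) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  time_at_length(params, f * params$Lm)
}

#' Steady-state growth window at a fraction of LERmax
#'
#' Thermal-time interval over which the leaf elongation rate stays at or
#' above `frac * LERmax`. The two endpoints are the roots of
#' `rate(t) = frac * LERmax` on either side of `tm`, found by bracketed
#' root searches on `[t0, tm]` and `[tm, te]`. `frac = 1` gives the
#' degenerate window `(tm, tm, 0)`.
#'
#' @inheritParams beta_length
#' @param frac Fraction of LERmax in `(0, 1]`; e.g. 0.90 or 0.95.
#' @return A tibble with columns `frac`, `t_lo`, `t_hi`, `width`
#'   (degree-days). One row per element of `frac`.
#' @examples
#' rate_window(growth_params(535, 0, 167, 231), c(0.90, 0.95))
#' @export
rate_window <- function(params, frac) {
  stopifnot(inherits(params, "growth_params"), is.numeric(frac))
  if (any(frac <= 0 | frac > 1)) {
    stop("fraction of LERmax must lie in (0, 1]", call. = FALSE)
  }
  t0 <- params$t0; tm <- params$tm; te <- params$te
  lermax <- beta_max_rate(params)$lermax
  eps <- 1e-9 * (te - t0)
  one <- function(fr) {
    if (fr == 1) return(c(tm, tm))
    target <- fr * lermax
    lo <- stats::uniroot(function(t) beta_rate(params, t) - target,
                         lower = t0 + eps, upper = tm,
                         tol = 1e-9 * (te - t0))$root
    hi <- stats::uniroot(function(t) beta_rate(params, t) - target,
                         lower = tm, upper = te - eps,
                         tol = 1e-9 * (te - t0))$root
    c(lo, hi)
  }
  ends <- t(vapply(frac, one, numeric(2)))
  tibble::tibble(frac = frac, t_lo = ends[, 1], t_hi = ends[, 2],
                 width = ends[, 2] - ends[, 1])
}

#' Cell length along the leaf axis under the extended beta sigmoid
#'
#' Evaluates
#' \deqn{\ell(p) = L_b + (L_m - L_b)\left(1 + \frac{P_e - p}{P_e - P_m}\right)
#'   \left(\frac{p}{P_e}\right)^{\frac{P_e}{P_e - P_m}}}
#' for positions `0 <= p <= Pe` (mm from the leaf base); beyond `Pe` cells
#' are mature and the profile plateaus at `Lm`. Negative positions are not
#' physical and raise an error.
#'
#' @param params A [cell_profile_params()] object.
#' @param p Position(s) along the leaf axis, mm from the base; `p >= 0`.
#' @return Cell length(s), um.
#' @examples
#' cp <- cell_profile_params(10.9, 118.5, 21.3, 43.4)
#' cell_length_at(cp, c(0, 21.3, 43.4, 60))
#' @export
cell_length_at <- function(params, p) {
  stopifnot(inherits(params, "cell_profile_params"), is.numeric(p))
  if (any(p < 0)) stop("position must be >= 0 (leaf base is 0)", call. = FALSE)
  Lb <- params$Lb; Lm <- params$Lm; Pm <- params$Pm; Pe <- params$Pe
  out <- numeric(length(p))
  inside <- p <= Pe
  pi_ <- p[inside]
  out[inside] <- Lb + (Lm - Lb) * (1 + (Pe - pi_) / (Pe - Pm)) *
    (pi_ / Pe)^(Pe / (Pe - Pm))
  out[!inside] <- Lm
  out
}

#' Evaluate an alternative four-parameter sigmoid family
#'
#' Evaluates the logistic, Gompertz or Weibull sigmoid specified by a
#' [sigmoid_family()] object. All three share the lower/upper asymptote
#' semantics (`Lb`, `Lm`) of the extended beta sigmoid so that goodness of
#' fit is comparable across families.
#'
#' @param family A [sigmoid_family()] object.
#' @param x Abscissa value(s). For the Weibull family `x` must be >= 0.
#' @return Sigmoid value(s), monotone nondecreasing in `x`.
#' @examples
#' sigmoid_at(sigmoid_family("logistic", 0, 1, 0, 1), 0)  # 0.5
#' @export
sigmoid_at <- function(family, x) {
  stopifnot(inherits(family, "sigmoid_family"), is.numeric(x))
  Lb <- family$Lb; Lm <- family$Lm; x0 <- family$x0; k <- family$k
  switch(family$family,
    logistic = Lb + (Lm - Lb) / (1 + exp(-k * (x - x0))),
    gompertz = Lb + (Lm - Lb) * exp(-exp(-k * (x - x0))),
    weibull = {
      if (any(x < 0)) stop("weibull abscissa must be >= 0", call. = FALSE)
      Lb + (Lm - Lb) * (1 - exp(-(x / x0)^k))
    },
    stop("unknown sigmoid family", call. = FALSE)
  )
}
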