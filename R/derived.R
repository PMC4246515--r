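#' Leaf elongation duration between two time points
#'
#' The thermal-time interval between two defined moments of leaf growth,
#' e.g. between reaching 20% and 90% of the final length.
#'
#' @param t_early,t_late Thermal times, degree-days; `t_late >= t_early`.
#' @return Duration in degree-days (`t_late - t_early`).
#' @examples
#' led(111, 203)  # 92 degree-days
#' @export
led <- function(t_early, t_late) {
  stopifnot(is.numeric(t_early), is.numeric(t_late))
  if (any(t_late < t_early)) {
    stop("t_late must not precede t_early", call. = FALSE)
  }
  t_late - t_early
}

#' Derive biologically relevant parameters from a growth fit
#'
#' Extracts the secondary parameters of interest from fitted beta sigmoid
#' parameters: the maximal elongation rate `LERmax`, the timing points at
#' which the leaf reaches given fractions of its final length (t20%,
#' t50%, t90% by default) and given absolute lengths (100 mm by default),
#' the leaf elongation durations (LEDs) between named pairs of those time
#' points, and the steady-state growth windows over which LER stays above
#' a fraction of LERmax.
#'
#' Absolute-length targets exceeding the fitted `Lm` are unattainable for
#' that leaf; they yield `NA` with a warning rather than an error, so that
#' batch runs over genotypes of different sizes are robust.
#'
#' Time-point columns are named `t<f*100>pct` (fractions) and `t<L>mm`
#' (absolute lengths); LEDs `led_<from>_<to>`; steady-state windows
#' `ss<frac*100>_lo`, `_hi`, `_width`. When `day_equiv` (degree-days
#' accrued per day at constant temperature) is supplied, day-equivalents
#' `<point>_days` are appended for each time point.
#'
#' @param params A [growth_params()] object or a `growth_fit`.
#' @param fractions Fractions of final length for timing points.
#' @param lengths Absolute lengths (mm) for timing points.
#' @param led_pairs List of 2-vectors naming time points (e.g.
#'   `c("t100mm", "te")`); names must be among the generated time-point
#'   columns or `"te"`/`"tm"`.
#' @param steady_fracs Fractions of LERmax for steady-state windows.
#' @param day_equiv Optional degree-days per day (constant-temperature
#'   experiments) used to append day-equivalents.
#'
#' @return A one-row tibble of derived quantities.
#' @examples
#' derive_growth(growth_params(535, 0, 167, 231))
#' @export
derive_growth <- function(params,
                          fractions = c(0.2, 0.5, 0.9),
                          lengths = 100,
                          led_pairs = list(c("t100mm", "te"),
                                           c("t20pct", "t90pct"),
                                           c("t20pct", "te")),
                          steady_fracs = c(0.9, 0.95),
                          day_equiv = NULL) {
  if (inherits(params, "growth_fit")) params <- params$params
  stopifnot(inherits(params, "growth_params"))
  out <- list(
    lermax = beta_max_rate(params)$lermax,
    tm = params$tm,
    te = params$te
  )
  for (f in fractions) {
    out[[sprintf("t%gpct", 100 * f)]] <- time_at_fraction(params, f)
  }
  for (L in lengths) {
    nm <- sprintf("t%gmm", L)
    if (L > params$Lm) {
      warning(sprintf(
        "absolute length %g mm exceeds fitted Lm = %g mm; %s set to NA",
        L, params$Lm, nm), call. = FALSE)
      out[[nm]] <- NA_real_
    } else {
      out[[nm]] <- time_at_length(params, L)
    }
  }
  for (pair in led_pairs) {
    stopifnot(length(pair) == 2)
    nm <- sprintf("led_%s_%s", pair[1], pair[2])
    a <- out[[pair[1]]]; b <- out[[pair[2]]]
    if (is.null(a) || is.null(b)) {
      stop(sprintf("LED pair (%s, %s) references unknown time points",
                   pair[1], pair[2]), call. = FALSE)
    }
    out[[nm]] <- if (is.na(a) || is.na(b)) NA_real_ else led(a, b)
  }
  for (fr in steady_fracs) {
    w <- rate_window(params, fr)
    tag <- sprintf("ss%g", 100 * fr)
    out[[paste0(tag, "_lo")]] <- w$t_lo
    out[[paste0(tag, "_hi")]] <- w$t_hi
    out[[paste0(tag, "_width")]] <- w$width
  }
  if (!is.null(day_equiv)) {
    stopifnot(is.numeric(day_equiv), day_equiv > 0)
    tp <- c("tm", "te", sprintf("t%gpct", 100 * fractions),
            sprintf("t%gmm", lengths))
    for (nm in tp) {
      out[[paste0(nm, "_days")]] <- out[[nm]] / day_equiv
    }
  }
  tibble::as_tibble(out)
}

#' Division and elongation zone lengths from a cell-length profile fit
#'
#' The division zone is the basal stretch of the leaf over which the
#' fitted cell length does not exceed a threshold (40 um by default,
#' the operational size bound for dividing cells); its distal limit is
#' the root of `cell_length(p) = threshold`. The elongation zone runs
#' from there to `Pe`, where cells reach their final length.
#'
#' @param params A [cell_profile_params()] object or a `cell_fit` with a
#'   beta-family fit.
#' @param threshold Cell-length threshold separating dividing from
#'   elongating cells, um. Must lie strictly between `Lb` and `Lm`.
#' @return A tibble with columns `division_zone` (mm), `elongation_zone`
#'   (mm) and `threshold` (um).
#' @examples
#' zone_lengths(cell_profile_params(10.9, 118.5, 21.3, 43.4))
#' @export
zone_lengths <- function(params, threshold = 40) {
  if (inherits(params, "cell_fit")) {
    if (!inherits(params$params, "cell_profile_params")) {
      stop("zone lengths require a beta-family cell-profile fit",
           call. = FALSE)
    }
    params <- params$params
  }
  stopifnot(inherits(params, "cell_profile_params"))
  if (!(threshold > params$Lb && threshold < params$Lm)) {
    stop("threshold must lie strictly between Lb and Lm", call. = FALSE)
  }
  Pe <- params$Pe
  dz <- stats::uniroot(function(p) cell_length_at(params, p) - threshold,
                       lower = 1e-9 * Pe, upper = Pe,
                       tol = 1e-9 * Pe)$root
  tibble::tibble(division_zone = dz, elongation_zone = Pe - dz,
                 threshold = threshold)
}
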