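#' Beta sigmoid growth parameters for one leaf
#'
#' Constructs and validates the four parameters of the beta sigmoid
#' determinate-growth function: final leaf length `Lm` (mm), growth start
#' `t0` (thermal time, degree-days), time of maximal elongation rate `tm`
#' (degree-days) and time at which growth ceases `te` (degree-days).
#'
#' Validity requires `Lm > 0` and `t0 <= tm < te`.
#'
#' @param Lm Final (asymptotic) leaf length, mm. Must be positive.
#' @param t0 Thermal time at which growth starts, degree-days (°Cd).
#'   Conventionally 0 at sowing.
#' @param tm Thermal time at which the elongation rate is maximal, °Cd.
#' @param te Thermal time at which growth ceases, °Cd.
#'
#' @return An object of class `growth_params` (a named list).
#' @examples
#' growth_params(Lm = 535, t0 = 0, tm = 167, te = 231)
#' @export
growth_params <- function(Lm, t0 = 0, tm, te) {
  stopifnot(is.numeric(Lm), is.numeric(t0), is.numeric(tm), is.numeric(te))
  if (!all(is.finite(c(Lm, t0, tm, te)))) {
    stop("growth parameters must be finite", call. = FALSE)
  }
  if (Lm <= 0) {
    stop("final length `Lm` must be positive", call. = FALSE)
  }
  if (!(t0 <= tm && tm < te)) {
    stop("growth parameters must satisfy t0 <= tm < te", call. = FALSE)
  }
  structure(list(Lm = Lm, t0 = t0, tm = tm, te = te),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Beta sigmoid growth parameters\n")
  cat(sprintf("  Lm = %g mm, t0 = %g, tm = %g, te = %g (degree-days)\n",
              x$Lm, x$t0, x$tm, x$te))
  invisible(x)
}

#' Extended beta sigmoid parameters for a cell-length profile
#'
#' Parameters of the extended beta sigmoid that describes cell length as a
#' function of position along the growing leaf axis: basal cell length `Lb`
#' (um), mature cell length `Lm` (um), position of maximal cell elongation
#' `Pm` (mm from leaf base) and position `Pe` at which cells reach their
#' final length (mm). Position zero is the leaf base.
#'
#' Validity requires `0 < Lb < Lm` and `0 <= Pm < Pe`.
#'
#' @param Lb Initial (basal) cell length, um.
#' @param Lm Final (mature) cell length, um.
#' @param Pm Position of maximal cell elongation, mm from leaf base.
#' @param Pe Position at which cells attain final length, mm from leaf base.
#'
#' @return An object of class `cell_profile_params`.
#' @examples
#' cell_profile_params(Lb = 10.9, Lm = 118.5, Pm = 21.3, Pe = 43.4)
#' @export
cell_profile_params <- function(Lb, Lm, Pm, Pe) {
  stopifnot(is.numeric(Lb), is.numeric(Lm), is.numeric(Pm), is.numeric(Pe))
  if (!all(is.finite(c(Lb, Lm, Pm, Pe)))) {
    stop("cell-profile parameters must be finite", call. = FALSE)
  }
  if (!(Lb > 0 && Lb < Lm)) {
    stop("cell-profile parameters must satisfy 0 < Lb < Lm", call. = FALSE)
  }
  if (!(Pm >= 0 && Pm < Pe)) {
    stop("cell-profile parameters must satisfy 0 <= Pm < Pe", call. = FALSE)
  }
  structure(list(Lb = Lb, Lm = Lm, Pm = Pm, Pe = Pe),
            class = "cell_profile_params")
}

#' @export
print.cell_profile_params <- function(x, ...) {
  cat("Extended beta sigmoid cell-profile parameters\n")
  cat(sprintf("  Lb = %g um, Lm = %g um, Pm = %g mm, Pe = %g mm\n",
              x$Lb, x$Lm, x$Pm, x$Pe))
  invisible(x)
}

#' Alternative sigmoid family specification
#'
#' Bundles a family tag with its shape parameters for the four-parameter
#' sigmoid families used to benchmark the extended beta sigmoid on
#' cell-length profiles. All families share the asymptote semantics: lower
#' asymptote `Lb`, upper asymptote `Lm`.
#'
#' Forms (x is position along the leaf axis):
#' * logistic: `Lb + (Lm - Lb) / (1 + exp(-k (x - x0)))`
#' * gompertz: `Lb + (Lm - Lb) * exp(-exp(-k (x - x0)))`
#' * weibull:  `Lb + (Lm - Lb) * (1 - exp(-(x / lambda)^k))`, x >= 0
#'
#' @param family One of `"logistic"`, `"gompertz"`, `"weibull"`.
#' @param Lb Lower asymptote (same units as the response).
#' @param Lm Upper asymptote; must exceed `Lb`.
#' @param x0 Location parameter (logistic midpoint / Gompertz shift), in
#'   abscissa units. For `weibull` this is the scale `lambda` (> 0).
#' @param k Steepness (logistic, Gompertz) or Weibull shape; must be > 0.
#'
#' @return An object of class `sigmoid_family`.
#' @examples
#' sigmoid_family("logistic", Lb = 0, Lm = 1, x0 = 0, k = 1)
#' @export
sigmoid_family <- function(family = c("logistic", "gompertz", "weibull"),
                           Lb, Lm, x0, k) {
  family <- match.arg(family)
  stopifnot(is.numeric(Lb), is.numeric(Lm), is.numeric(x0), is.numeric(k))
  if (Lm <= Lb) stop("upper asymptote `Lm` must exceed `Lb`", call. = FALSE)
  if (k <= 0) stop("steepness/shape `k` must be positive", call. = FALSE)
  if (family == "weibull" && x0 <= 0) {
    stop("weibull scale must be positive", call. = FALSE)
  }
  structure(list(family = family, Lb = Lb, Lm = Lm, x0 = x0, k = k),
            class = "sigmoid_family")
}
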