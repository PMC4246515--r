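#' Automatic starting values for a growth-curve fit
#'
#' Heuristic starting values for the beta sigmoid parameters of one leaf
#' series: `Lm0 = 1.05 * max(L)`, `te0` is the first thermal time at which
#' the series reaches 95% of its maximum, `tm0` is the midpoint of the
#' sampling interval with the largest finite-difference elongation rate,
#' and `t0` is fixed (0 at sowing by default).
#'
#' @param data Data frame with one leaf's measurements.
#' @param t,length Names of the thermal-time (degree-days) and leaf-length
#'   (mm) columns.
#' @param t0 Growth-start thermal time assumed for the starting values.
#'
#' @return A [growth_params()] object of starting values.
#' @export
initial_guess <- function(data, t = "t", length = "length", t0 = 0) {
  ser <- check_series(data, t, length, min_points = 5,
                      allow_duplicates = TRUE)
  # duplicate abscissae (pooled replicates) are averaged for the heuristic
  agg <- dplyr::summarise(dplyr::group_by(ser, .data$t),
                          length = mean(.data$length), .groups = "drop")
  tt <- agg$t; L <- agg$length
  if (diff(range(L)) == 0) {
    stop("degenerate series: all lengths equal, no growth signal",
         call. = FALSE)
  }
  Lm0 <- 1.05 * max(L)
  te0 <- tt[which(L >= 0.95 * max(L))[1]]
  rates <- diff(L) / diff(tt)
  k <- which.max(rates)
  tm0 <- (tt[k] + tt[k + 1]) / 2
  # guards: the heuristics can collide on short or noisy series
  if (tm0 <= t0) tm0 <- t0 + 0.5 * (te0 - t0)
  if (te0 <= tm0) te0 <- tm0 + 0.25 * (max(tt) - min(tt))
  growth_params(Lm = Lm0, t0 = t0, tm = tm0, te = te0)
}

# validate one series; returns tibble(t, length) sorted by t
check_series <- function(data, t, length, min_points,
                         allow_duplicates = FALSE) {
  stopifnot(is.data.frame(data))
  if (!all(c(t, length) %in% names(data))) {
    stop(sprintf("series must contain columns '%s' and '%s'", t, length),
         call. = FALSE)
  }
  out <- tibble::tibble(t = as.numeric(data[[t]]),
                        length = as.numeric(data[[length]]))
  if (anyNA(out$t) || anyNA(out$length)) {
    stop("series contains missing or unparseable values", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$t)
  if (!allow_duplicates && any(duplicated(out$t))) {
    stop("duplicate abscissa values in series", call. = FALSE)
  }
  if (any(out$length < 0)) {
    stop("negative lengths in series", call. = FALSE)
  }
  if (nrow(out) < min_points) {
    stop(sprintf("series has %d points; at least %d required",
                 nrow(out), min_points), call. = FALSE)
  }
  out
}

# deterministic +-20% perturbation factors for restart r (r = 1..max)
perturb_factors <- function(r, n_par) {
  signs <- c(1, -1, 1, -1, 1)
  base <- 0.2 * signs[((r - 1) %% 5) + 1]
  # alternate the sign across parameters so restarts explore corners
  1 + base * rep_len(c(1, -1), n_par)
}

#' Fit the beta sigmoid growth function to one leaf series
#'
#' Bounded derivative-based least squares (Levenberg-Marquardt via
#' `minpack.lm::nlsLM`) of leaf length against thermal time. By default
#' `t0` is fixed at 0 (sowing): free estimates of `t0` are often negative
#' and biologically meaningless. The ordering constraint `tm < te` is
#' enforced by fitting `(Lm, tm, dte)` with `te = tm + dte`, `dte > 0`.
#' On convergence failure the fit restarts from deterministically
#' perturbed starting values (up to `max_restarts` times).
#'
#' @param data Data frame with one leaf's measurements (at least 5 points).
#' @param t,length Column names of thermal time (degree-days) and leaf
#'   length (mm).
#' @param fix_t0 If `TRUE` (default), `t0` is held at `t0`; if `FALSE`,
#'   `t0` is a free parameter.
#' @param t0 Value at which `t0` is fixed (default 0 = sowing).
#' @param start Optional [growth_params()] starting values; computed by
#'   [initial_guess()] when omitted.
#' @param max_iter Maximum optimizer iterations per attempt.
#' @param tol Relative SSE convergence tolerance.
#' @param max_restarts Maximum restarts from perturbed starting values.
#' @param allow_duplicate_t Permit repeated thermal times (pooled
#'   replicate fitting); off for a single leaf's series.
#'
#' @return An object of class `growth_fit`: fitted [growth_params()],
#'   fitted values, residuals, `sse`, `r_squared`, `converged` flag,
#'   iteration count and the starting values used. Supports
#'   [generics::tidy()], [generics::glance()], [generics::augment()] and
#'   `ggplot2::autoplot()`.
#' @examples
#' p <- growth_params(535, 0, 167, 231)
#' d <- simulate_leaf_series(p, t = seq(0, 238, by = 14), sd = 5, seed = 1)
#' fit <- fit_growth(d)
#' glance(fit)
#' @export
fit_growth <- function(data, t = "t", length = "length",
                       fix_t0 = TRUE, t0 = 0, start = NULL,
                       max_iter = 200, tol = 1e-10, max_restarts = 5,
                       allow_duplicate_t = FALSE) {
  ser <- check_series(data, t, length, min_points = 5,
                      allow_duplicates = allow_duplicate_t)
  if (is.null(start)) start <- initial_guess(ser, t0 = t0)
  stopifnot(inherits(start, "growth_params"))
  tt <- ser$t; L <- ser$length
  tmax <- max(tt)
  eps <- 1e-6 * max(tmax, 1)

  if (fix_t0) {
    par0 <- c(Lm = start$Lm, tm = start$tm, dte = start$te - start$tm)
    lower <- c(eps, t0 + eps, eps)
    upper <- c(10 * max(L), 2 * tmax, 2 * tmax)
    to_params <- function(p) {
      growth_params(Lm = p[["Lm"]], t0 = t0, tm = p[["tm"]],
                    te = p[["tm"]] + p[["dte"]])
    }
  } else {
    par0 <- c(Lm = start$Lm, t0 = start$t0,
              dtm = max(start$tm - start$t0, eps),
              dte = start$te - start$tm)
    lower <- c(eps, min(tt) - tmax, eps, eps)
    upper <- c(10 * max(L), tmax, 2 * tmax, 2 * tmax)
    to_params <- function(p) {
      growth_params(Lm = p[["Lm"]], t0 = p[["t0"]],
                    tm = p[["t0"]] + p[["dtm"]],
                    te = p[["t0"]] + p[["dtm"]] + p[["dte"]])
    }
  }
  run_bounded_ls(
    par0 = par0, lower = lower, upper = upper, to_params = to_params,
    predict_fn = beta_length, obs = L, x = tt, data = ser,
    start = start, max_iter = max_iter, tol = tol,
    max_restarts = max_restarts, class = "growth_fit",
    extra = list(fix_t0 = fix_t0)
  )
}

#' Fit a sigmoid to a cell-length profile
#'
#' Fits cell length (um) against position along the leaf axis (mm from
#' the base) with the extended beta sigmoid (default) or one of three
#' benchmark four-parameter sigmoid families (Weibull, Gompertz,
#' logistic). Same bounded least-squares and restart contract as
#' [fit_growth()].
#'
#' @param data Data frame with one profile (at least 8 points).
#' @param family Model family: `"beta"` (extended beta sigmoid) or
#'   `"weibull"`, `"gompertz"`, `"logistic"`.
#' @param position,cell_length Column names for position (mm) and cell
#'   length (um).
#' @inheritParams fit_growth
#'
#' @return An object of class `cell_fit` (and `growth_fit` machinery):
#'   fitted parameters ([cell_profile_params()] for `"beta"`,
#'   [sigmoid_family()] otherwise), residuals, `sse`, `r_squared`,
#'   `converged`, iterations.
#' @examples
#' cp <- cell_profile_params(10.9, 118.5, 21.3, 43.4)
#' d <- simulate_cell_profile(cp, p = seq(0.5, 60, by = 0.5),
#'                            cv = 0.25, seed = 7)
#' fit <- fit_cell_profile(d)
#' glance(fit)
#' @export
fit_cell_profile <- function(data,
                             family = c("beta", "weibull", "gompertz",
                                        "logistic"),
                             position = "position",
                             cell_length = "cell_length",
                             max_iter = 200, tol = 1e-10,
                             max_restarts = 5) {
  family <- match.arg(family)
  ser <- check_series(data, position, cell_length, min_points = 8)
  names(ser) <- c("position", "cell_length")
  pp <- ser$position; len <- ser$cell_length
  if (any(len <= 0)) stop("cell lengths must be positive", call. = FALSE)
  if (diff(range(len)) == 0) {
    stop("degenerate profile: all cell lengths equal", call. = FALSE)
  }
  pmax_ <- max(pp)
  eps <- 1e-6 * max(pmax_, 1)
  # cell lengths scatter strongly; starting heuristics use a smoothed
  # profile so single outliers cannot drag the start values
  sm <- if (length(len) >= 7) stats::runmed(len, 5) else len
  Lb0 <- max(min(sm), 1e-3)
  Lm0 <- 1.05 * max(sm)
  Pe0 <- pp[which(sm >= 0.95 * max(sm))[1]]
  rates <- diff(sm) / diff(pp)
  k <- which.max(rates)
  Pm0 <- (pp[k] + pp[k + 1]) / 2
  if (Pe0 <= Pm0) Pe0 <- Pm0 + 0.25 * diff(range(pp))
  half_p <- pp[which(sm >= Lb0 + 0.5 * (max(sm) - Lb0))[1]]

  if (family == "beta") {
    par0 <- c(Lb = Lb0, dLm = Lm0 - Lb0, Pm = Pm0, dPe = Pe0 - Pm0)
    lower <- c(1e-6, 1e-6, 1e-6, eps)
    upper <- c(max(len), 10 * max(len), 2 * pmax_, 2 * pmax_)
    to_params <- function(p) {
      cell_profile_params(Lb = p[["Lb"]], Lm = p[["Lb"]] + p[["dLm"]],
                          Pm = p[["Pm"]], Pe = p[["Pm"]] + p[["dPe"]])
    }
    predict_fn <- cell_length_at
  } else {
    x0_0 <- if (family == "weibull") max(half_p, eps) else half_p
    k0 <- if (family == "weibull") 2 else 4 * max(rates) / (Lm0 - Lb0)
    par0 <- c(Lb = Lb0, dLm = Lm0 - Lb0, x0 = x0_0, k = max(k0, 1e-3))
    lower <- c(1e-6, 1e-6, if (family == "weibull") eps else -2 * pmax_,
               1e-6)
    upper <- c(max(len), 10 * max(len), 2 * pmax_, Inf)
    to_params <- function(p) {
      sigmoid_family(family, Lb = p[["Lb"]], Lm = p[["Lb"]] + p[["dLm"]],
                     x0 = p[["x0"]], k = p[["k"]])
    }
    predict_fn <- sigmoid_at
  }
  fit <- run_bounded_ls(
    par0 = par0, lower = lower, upper = upper, to_params = to_params,
    predict_fn = predict_fn, obs = len, x = pp, data = ser,
    start = to_params(par0), max_iter = max_iter, tol = tol,
    max_restarts = max_restarts, class = "cell_fit",
    extra = list(family = family)
  )
  fit
}

# shared bounded least-squares driver with deterministic restarts
run_bounded_ls <- function(par0, lower, upper, to_params, predict_fn,
                           obs, x, data, start, max_iter, tol,
                           max_restarts, class, extra = list()) {
  sse_of <- function(p) {
    sum((obs - predict_fn(to_params(p), x))^2)
  }
  clamp <- function(p) pmin(pmax(p, lower), upper)
  sse0 <- sse_of(clamp(par0))

  # nlsLM needs the model expressed through a function of named parameters
  do_fit <- function(p_start) {
    df <- data.frame(.x = x, .y = obs)
    pred <- function(...) {
      p <- unlist(list(...))
      predict_fn(to_params(p), df$.x)
    }
    # build formula .y ~ pred(Lm = Lm, tm = tm, ...)
    pn <- names(p_start)
    args <- paste(sprintf("%s = %s", pn, pn), collapse = ", ")
    fml <- stats::as.formula(paste0(".y ~ pred(", args, ")"))
    tryCatch(
      minpack.lm::nlsLM(
        fml, data = df, start = as.list(p_start),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = max_iter, ftol = tol)
      ),
      error = function(e) NULL
    )
  }

  # always explore the first few deterministic starts (the least-squares
  # surface is multimodal for noisy sigmoid data), keep the lowest SSE;
  # extend up to max_restarts only while no start has succeeded
  best <- NULL
  best_sse <- Inf
  iters <- 0L
  restarts_used <- 0L
  min_starts <- min(2L, max_restarts)
  for (r in 0:max_restarts) {
    p_try <- if (r == 0) clamp(par0) else {
      clamp(par0 * perturb_factors(r, length(par0)))
    }
    nls_fit <- do_fit(p_try)
    if (!is.null(nls_fit)) {
      p_hat <- stats::coef(nls_fit)
      s <- sse_of(p_hat)
      if (is.finite(s) && s < best_sse) {
        best <- p_hat
        best_sse <- s
        iters <- nls_fit$convInfo$finIter
      }
    }
    restarts_used <- r
    ok <- best_sse <= sse0 + 1e-12 * (1 + sse0)
    if (ok && r >= min_starts) break
  }

  converged <- !is.null(best) && best_sse <= sse0 + 1e-12 * (1 + sse0)
  if (is.null(best)) {
    best <- clamp(par0)
    best_sse <- sse0
  }
  params <- to_params(best)
  fitted <- predict_fn(params, x)
  resid <- obs - fitted
  sst <- sum((obs - mean(obs))^2)
  r2 <- if (sst > 0) 1 - best_sse / sst else NA_real_

  structure(
    c(list(params = params, data = data, fitted = fitted,
           residuals = resid, sse = best_sse, r_squared = r2,
           converged = converged, iterations = as.integer(iters),
           restarts = restarts_used, start = start),
      extra),
    class = c(class, "beta_fit")
  )
}

#' @export
print.beta_fit <- function(x, ...) {
  kind <- if (inherits(x, "cell_fit")) "Cell-length profile fit"
          else "Leaf growth fit"
  cat(kind, if (!is.null(x$family)) sprintf("(%s)", x$family), "\n")
  print(x$params)
  cat(sprintf("  n = %d, SSE = %.4g, R^2 = %.4f, converged = %s\n",
              length(x$residuals), x$sse, x$r_squared, x$converged))
  invisible(x)
}

#' Goodness of fit of predicted against observed values
#'
#' Residual sum of squares and the coefficient of determination
#' `R^2 = 1 - SSE / SStot`, with the total sum of squares taken about the
#' observed mean (the centred definition).
#'
#' @param observed,fitted Numeric vectors of equal length.
#' @return A tibble with columns `sse` and `r_squared`.
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4))  # SSE 1, R^2 0.5
#' @export
goodness_of_fit <- function(observed, fitted) {
  stopifnot(is.numeric(observed), is.numeric(fitted),
            length(observed) == length(fitted))
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("R^2 undefined: observations have zero variance", call. = FALSE)
  }
  sse <- sum((observed - fitted)^2)
  tibble::tibble(sse = sse, r_squared = 1 - sse / sst)
}

#' Pooled regression of fitted on observed values
#'
#' Ordinary least-squares line through the pooled (observed, fitted)
#' pairs of one or more fits: the standard whole-experiment check that
#' the fitted curves track the measurements (slope near 1, intercept near
#' 0, R^2 near 1).
#'
#' @param fits A list of `growth_fit`/`cell_fit` objects, a single fit,
#'   or a data frame with columns `observed` and `fitted`.
#' @return A tibble with columns `slope`, `intercept`, `r_squared`, `n`.
#' @export
predicted_vs_observed <- function(fits) {
  if (inherits(fits, "beta_fit")) fits <- list(fits)
  if (is.data.frame(fits)) {
    stopifnot(all(c("observed", "fitted") %in% names(fits)))
    pooled <- tibble::tibble(observed = fits$observed, fitted = fits$fitted)
  } else {
    stopifnot(is.list(fits), length(fits) > 0)
    pooled <- purrr::map_dfr(fits, function(f) {
      tibble::tibble(observed = f$data[[2]], fitted = f$fitted)
    })
  }
  if (nrow(pooled) < 2) {
    stop("need at least 2 pooled points for regression", call. = FALSE)
  }
  m <- stats::lm(fitted ~ observed, data = pooled)
  sst <- sum((pooled$fitted - mean(pooled$fitted))^2)
  sse <- sum(stats::residuals(m)^2)
  tibble::tibble(
    slope = unname(stats::coef(m)[2]),
    intercept = unname(stats::coef(m)[1]),
    r_squared = if (sst > 0) 1 - sse / sst else 1,
    n = nrow(pooled)
  )
}

#' Finite-difference (calculated) leaf elongation rates
#'
#' Empirical LER profile: length increase between consecutive
#' measurements divided by the thermal-time interval, reported at the
#' interval midpoints. The maximum of this profile is the "calculated
#' LERmax" that can be compared with the model-estimated LERmax.
#'
#' @inheritParams fit_growth
#' @return A tibble with columns `t_mid` (degree-days) and `ler`
#'   (mm per degree-day), one row per interval.
#' @examples
#' empirical_ler(data.frame(t = c(0, 10, 20), length = c(0, 50, 150)))
#' @export
empirical_ler <- function(data, t = "t", length = "length") {
  stopifnot(is.data.frame(data))
  if (!all(c(t, length) %in% names(data))) {
    stop("data must contain the t and length columns", call. = FALSE)
  }
  tt <- as.numeric(data[[t]]); L <- as.numeric(data[[length]])
  if (length(tt) < 2) stop("need at least 2 points", call. = FALSE)
  if (is.unsorted(tt, strictly = TRUE)) {
    stop("thermal times must be strictly increasing", call. = FALSE)
  }
  tibble::tibble(
    t_mid = (tt[-1] + tt[-length(tt)]) / 2,
    ler = diff(L) / diff(tt)
  )
}
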