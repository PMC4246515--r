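#' Student's t-test between two groups of a derived parameter
#'
#' Two-sided Student's t-test with pooled variance (equal-variance
#' assumption, `df = n1 + n2 - 2`), plus the percent difference of group
#' means relative to the first group. Welch's unequal-variance test is
#' available behind `welch = TRUE`.
#'
#' @param a,b Numeric vectors of per-leaf values (each `n >= 2`).
#' @param welch Use Welch's t-test instead of the pooled-variance test.
#' @return A tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `percent_diff` (= `(mean_b - mean_a) / mean_a * 100`).
#' @examples
#' ttest_two_groups(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
ttest_two_groups <- function(a, b, welch = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b))
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  tst <- stats::t.test(a, b, var.equal = !welch)
  tibble::tibble(
    t = unname(tst$statistic),
    df = unname(tst$parameter),
    p_value = tst$p.value,
    mean_a = mean(a),
    mean_b = mean(b),
    percent_diff = (mean(b) - mean(a)) / mean(a) * 100
  )
}

#' One-way ANOVA with Scheffe post hoc contrasts
#'
#' Compares a derived parameter across three or more groups: one-way
#' ANOVA (F and p), Scheffe-adjusted pairwise contrasts, and a compact
#' letter display in which groups sharing no letter differ at level
#' `alpha`. For two groups, use [ttest_two_groups()] (signalled by an
#' error).
#'
#' The Scheffe p-value of the pairwise contrast between groups i and j is
#' `P(F(k-1, N-k) >= F_ij / (k-1))` with
#' `F_ij = (mean_i - mean_j)^2 / (MSE (1/n_i + 1/n_j))`; it is never
#' smaller than the unadjusted pairwise p-value (the test is
#' conservative).
#'
#' @param data Data frame of per-leaf values.
#' @param value,group Column names of the response and the group label.
#' @param alpha Significance level for the letter display.
#' @return A list of class `anova_scheffe`: `anova` (one-row tibble `F`,
#'   `df1`, `df2`, `p_value`), `pairwise` (tibble `group1`, `group2`,
#'   `diff`, `p_scheffe`), `letters` (tibble `group`, `mean`, `letters`),
#'   `alpha`.
#' @examples
#' d <- data.frame(group = rep(c("g1", "g2", "g3"), each = 4),
#'                 y = c(rnorm(4), rnorm(4), rnorm(4, 5)))
#' anova_scheffe(d, value = "y")
#' @export
anova_scheffe <- function(data, value, group = "group", alpha = 0.05) {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  y <- as.numeric(data[[value]])
  g <- factor(data[[group]])
  keep <- is.finite(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 3) {
    stop("fewer than 3 groups: use ttest_two_groups()", call. = FALSE)
  }
  if (any(table(g) < 2)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  fit <- stats::aov(y ~ g)
  # near-zero residual variance (separation forced to machine precision)
  # triggers base R's "essentially perfect fit" note; the F and p are
  # still the quantities we want
  atab <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  mse <- atab["Residuals", "Mean Sq"]
  df2 <- atab["Residuals", "Df"]
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)

  pairs <- utils::combn(levels(g), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    d <- means[[g1]] - means[[g2]]
    f_ij <- d^2 / (mse * (1 / ns[[g1]] + 1 / ns[[g2]]))
    tibble::tibble(
      group1 = g1, group2 = g2, diff = d,
      p_scheffe = stats::pf(f_ij / (k - 1), k - 1, df2,
                            lower.tail = FALSE)
    )
  })

  letters_tbl <- tibble::tibble(
    group = names(sort(means)),
    mean = as.numeric(sort(means)),
    letters = unname(compact_letters(names(sort(means)), pw, alpha))
  )

  structure(list(
    anova = tibble::tibble(
      F = atab["g", "F value"], df1 = atab["g", "Df"], df2 = df2,
      p_value = atab["g", "Pr(>F)"]),
    pairwise = pw,
    letters = letters_tbl,
    alpha = alpha
  ), class = "anova_scheffe")
}

#' @export
print.anova_scheffe <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_value))
  cat(sprintf("Scheffe post hoc at alpha = %g:\n", x$alpha))
  print(x$letters)
  invisible(x)
}

# compact letter display: insert-and-absorb over the significant-
# difference graph. `groups` come ordered by mean; each letter column is
# a set of groups among which no pair differs at alpha.
compact_letters <- function(groups, pairwise, alpha) {
  sig <- pairwise[pairwise$p_scheffe < alpha, , drop = FALSE]
  cols <- list(groups)
  for (r in seq_len(nrow(sig))) {
    g1 <- sig$group1[r]; g2 <- sig$group2[r]
    nxt <- list()
    for (cc in cols) {
      if (all(c(g1, g2) %in% cc)) {
        nxt <- c(nxt, list(setdiff(cc, g1)), list(setdiff(cc, g2)))
      } else {
        nxt <- c(nxt, list(cc))
      }
    }
    nxt <- nxt[lengths(nxt) > 0]
    # absorb: a column contained in another is redundant
    keep <- rep(TRUE, length(nxt))
    for (i in seq_along(nxt)) for (j in seq_along(nxt)) {
      if (i != j && keep[i] && keep[j] &&
          all(nxt[[i]] %in% nxt[[j]]) &&
          (length(nxt[[i]]) < length(nxt[[j]]) || i > j)) {
        keep[i] <- FALSE
      }
    }
    cols <- nxt[keep]
  }
  ord <- order(vapply(cols, function(cc) min(match(cc, groups)),
                      numeric(1)))
  cols <- cols[ord]
  vapply(groups, function(g) {
    paste0(letters[which(vapply(cols, function(cc) g %in% cc,
                                logical(1)))], collapse = "")
  }, character(1))
}

#' Compare derived parameters between groups of a results table
#'
#' Convenience wrapper over [ttest_two_groups()] (two groups) and
#' [anova_scheffe()] (three or more) applied to one or more numeric
#' columns of a [run_batch()] results table. Non-converged rows are
#' dropped first.
#'
#' @param results Results tibble from [run_batch()].
#' @param params Character vector of result columns to compare (default:
#'   every numeric derived/fitted column present).
#' @param group Grouping column.
#' @param alpha Significance level.
#' @param welch Use Welch's t-test for two-group comparisons.
#' @return A tibble, one row per parameter: test used, statistic, p-value
#'   and (two groups) percent difference, or (3+ groups) the letter
#'   display collapsed to a string.
#' @export
compare_groups <- function(results, params = NULL, group = "group",
                           alpha = 0.05, welch = FALSE) {
  stopifnot(is.data.frame(results), group %in% names(results))
  ok <- if ("converged" %in% names(results)) {
    results[!is.na(results$converged) & results$converged, , drop = FALSE]
  } else results
  if (is.null(params)) {
    skip <- c(group, "leaf_id", "n_points", "iterations", "sse",
              "converged", "error", "threshold")
    params <- setdiff(names(ok)[vapply(ok, is.numeric, logical(1))], skip)
  }
  glabs <- unique(ok[[group]])
  purrr::map_dfr(params, function(p) {
    if (length(glabs) == 2) {
      a <- ok[[p]][ok[[group]] == glabs[1]]
      b <- ok[[p]][ok[[group]] == glabs[2]]
      res <- ttest_two_groups(a, b, welch = welch)
      tibble::tibble(parameter = p, test = "t", statistic = res$t,
                     p_value = res$p_value,
                     percent_diff = res$percent_diff,
                     letters = NA_character_)
    } else {
      res <- anova_scheffe(ok, value = p, group = group, alpha = alpha)
      tibble::tibble(parameter = p, test = "anova_scheffe",
                     statistic = res$anova$F,
                     p_value = res$anova$p_value,
                     percent_diff = NA_real_,
                     letters = paste(sprintf("%s:%s", res$letters$group,
                                             res$letters$letters),
                                     collapse = " "))
    }
  })
}
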