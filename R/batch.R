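#' Read a long-format measurement table
#'
#' Reads a delimited file of leaf-growth or cell-profile measurements in
#' long format (one measurement per row) and validates each series
#' against its invariants. Rows or series that fail validation are
#' dropped with a logged reason (available through
#' `attr(x, "rejected")`); an empty result is an error.
#'
#' Expected columns: `leaf_id`, `group`, then the abscissa and value
#' columns — `t` (degree-days) and `length` (mm) for `mode = "growth"`,
#' `position` (mm) and `cell_length` (um) for `mode = "cells"`. Column
#' names are configurable.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension, override with `delim`).
#' @param mode `"growth"` or `"cells"`.
#' @param leaf_id,group Identifier column names.
#' @param abscissa,value Measurement column names; defaults depend on
#'   `mode`.
#' @param delim Field delimiter; inferred when `NULL`.
#'
#' @return A tibble with standardised columns (`leaf_id`, `group`, and
#'   the mode's abscissa/value), sorted within series, with attributes
#'   `mode` and `rejected` (a tibble of leaf_id/reason pairs).
#' @export
read_measurements <- function(path, mode = c("growth", "cells"),
                              leaf_id = "leaf_id", group = "group",
                              abscissa = NULL, value = NULL,
                              delim = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  }
  defaults <- if (mode == "growth") c("t", "length")
              else c("position", "cell_length")
  if (is.null(abscissa)) abscissa <- defaults[1]
  if (is.null(value)) value <- defaults[2]

  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- c(leaf_id, group, abscissa, value)
  if (!all(need %in% names(raw))) {
    stop("missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  tab <- tibble::tibble(
    leaf_id = as.character(raw[[leaf_id]]),
    group = as.character(raw[[group]]),
    x = suppressWarnings(as.numeric(raw[[abscissa]])),
    y = suppressWarnings(as.numeric(raw[[value]]))
  )
  rejected <- tibble::tibble(leaf_id = character(), reason = character())
  bad_row <- is.na(tab$x) | is.na(tab$y) | tab$y < 0 | tab$x < 0
  if (any(bad_row)) {
    rejected <- dplyr::bind_rows(rejected, tibble::tibble(
      leaf_id = tab$leaf_id[bad_row],
      reason = "row rejected: missing, unparseable or negative value"))
    tab <- tab[!bad_row, , drop = FALSE]
  }
  # duplicate (id, abscissa) pairs invalidate the whole series
  dup_ids <- unique(tab$leaf_id[duplicated(tab[c("leaf_id", "x")])])
  if (length(dup_ids)) {
    rejected <- dplyr::bind_rows(rejected, tibble::tibble(
      leaf_id = dup_ids, reason = "series rejected: duplicate abscissa"))
    tab <- tab[!tab$leaf_id %in% dup_ids, , drop = FALSE]
  }
  if (nrow(tab) == 0) {
    stop("no valid measurements after validation", call. = FALSE)
  }
  for (r in seq_len(nrow(rejected))) {
    message(rejected$leaf_id[r], ": ", rejected$reason[r])
  }
  tab <- dplyr::arrange(tab, .data$leaf_id, .data$x)
  names(tab) <- c("leaf_id", "group", defaults)
  attr(tab, "mode") <- mode
  attr(tab, "rejected") <- rejected
  tab
}

#' Convert a wide measurement sheet to long format
#'
#' Spreadsheet-style sheets often hold one leaf per row with one column
#' per measurement time/position (column names are the abscissa values).
#' This reshapes such a table into the long format the batch functions
#' expect.
#'
#' @param data Wide data frame: identifier columns plus numeric-named
#'   measurement columns.
#' @param id_cols Character vector of identifier columns to keep.
#' @param abscissa,value Output column names.
#' @return A long tibble with `id_cols`, `abscissa` and `value` columns.
#' @export
wide_to_long <- function(data, id_cols = c("leaf_id", "group"),
                         abscissa = "t", value = "length") {
  stopifnot(is.data.frame(data), all(id_cols %in% names(data)))
  meas <- setdiff(names(data), id_cols)
  out <- tidyr::pivot_longer(data, cols = dplyr::all_of(meas),
                             names_to = abscissa, values_to = value)
  out[[abscissa]] <- as.numeric(out[[abscissa]])
  tidyr::drop_na(out, dplyr::all_of(c(abscissa, value)))
}

#' Fit and derive over a whole experiment
#'
#' Runs the full per-leaf pipeline over a long-format measurement table:
#' optional thermal-time conversion, model fit, goodness of fit, and
#' extraction of derived parameters. Every input leaf yields exactly one
#' output row; a leaf whose fit fails is flagged (`converged = FALSE`,
#' `error` message) rather than aborting the batch. The run is
#' deterministic: identical input and configuration give an identical
#' results table.
#'
#' @param table Long-format measurement tibble (see
#'   [read_measurements()]): columns `leaf_id`, `group`, plus `t`/`length`
#'   (growth mode) or `position`/`cell_length` (cells mode). Growth-mode
#'   tables may instead carry a `day` column plus `temp_log`/`base_temp`
#'   for conversion.
#' @param mode `"growth"` or `"cells"`; taken from the table's `mode`
#'   attribute when present.
#' @param pool If `TRUE`, replicates within a group are pooled and fitted
#'   jointly (one row per group); per-leaf fitting is the default.
#' @param temp_log,base_temp Optional daily temperature log and base
#'   temperature for day-to-thermal-time conversion (growth mode).
#' @param family Cell-profile model family (cells mode).
#' @param zone_threshold Division-zone cell-length threshold, um
#'   (cells mode).
#' @param ... Passed to [fit_growth()] / [fit_cell_profile()] and, for
#'   growth mode, to [derive_growth()] (e.g. `fractions`, `lengths`,
#'   `led_pairs`, `steady_fracs`, `day_equiv`, `fix_t0`).
#'
#' @return A results tibble, one row per leaf (or per group when
#'   pooled): identifiers, fitted parameters, `r_squared`, `sse`,
#'   `converged`, `error`, and all derived quantities.
#' @examples
#' exp <- simulate_experiment(n = c(3, 3), seed = 1)
#' res <- run_batch(exp, mode = "growth")
#' res[, c("leaf_id", "Lm", "r_squared", "converged")]
#' @export
run_batch <- function(table, mode = NULL, pool = FALSE,
                      temp_log = NULL, base_temp = NULL,
                      family = "beta", zone_threshold = 40, ...) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("empty measurement table", call. = FALSE)
  if (is.null(mode)) mode <- attr(table, "mode") %||% "growth"
  mode <- match.arg(mode, c("growth", "cells"))
  if (!all(c("leaf_id", "group") %in% names(table))) {
    stop("table must contain leaf_id and group columns", call. = FALSE)
  }

  if (mode == "growth" && !is.null(temp_log)) {
    stopifnot(!is.null(base_temp))
    table <- add_thermal_time(table, temp_log, base_temp)
  }

  dots <- list(...)
  derive_args <- dots[names(dots) %in%
    c("fractions", "lengths", "led_pairs", "steady_fracs", "day_equiv")]
  fit_args <- dots[!names(dots) %in% names(derive_args)]

  if (pool) {
    table$leaf_id <- table$group
  }
  keys <- dplyr::distinct(table, .data$leaf_id, .data$group)

  rows <- purrr::pmap_dfr(keys, function(leaf_id, group) {
    ser <- table[table$leaf_id == leaf_id & table$group == group, ,
                 drop = FALSE]
    base <- tibble::tibble(leaf_id = leaf_id, group = group,
                           n_points = nrow(ser))
    res <- tryCatch({
      if (mode == "growth") {
        fit <- do.call(fit_growth,
                       c(list(data = ser, allow_duplicate_t = pool),
                         fit_args))
        drv <- do.call(derive_growth, c(list(params = fit$params),
                                        derive_args))
        # tm and te already sit among the fitted parameters
        drv <- drv[setdiff(names(drv), c("tm", "te"))]
        dplyr::bind_cols(
          tibble::as_tibble(unclass(fit$params)),
          glance(fit)[c("r_squared", "sse", "converged", "iterations")],
          tibble::tibble(error = NA_character_),
          drv)
      } else {
        fit <- do.call(fit_cell_profile,
                       c(list(data = ser, family = family), fit_args))
        par_tbl <- if (family == "beta") {
          tibble::as_tibble(unclass(fit$params))
        } else {
          tibble::as_tibble(unclass(fit$params)[c("Lb", "Lm", "x0", "k")])
        }
        zones <- if (family == "beta" &&
                     zone_threshold > fit$params$Lb &&
                     zone_threshold < fit$params$Lm) {
          zone_lengths(fit$params, zone_threshold)
        } else {
          tibble::tibble(division_zone = NA_real_,
                         elongation_zone = NA_real_,
                         threshold = zone_threshold)
        }
        dplyr::bind_cols(
          par_tbl,
          glance(fit)[c("r_squared", "sse", "converged", "iterations")],
          tibble::tibble(error = NA_character_),
          zones)
      }
    }, error = function(e) {
      tibble::tibble(converged = FALSE, error = conditionMessage(e))
    })
    dplyr::bind_cols(base, res)
  })

  n_ok <- sum(rows$converged, na.rm = TRUE)
  message(sprintf("run_batch: %d/%d series converged", n_ok, nrow(rows)))
  rows
}

#' Write a batch results table to disk
#'
#' Writes the results tibble as a delimited file with a header and a
#' stable column order; numeric values keep full precision (at least 6
#' significant digits survive a read-back round trip).
#'
#' @param results Non-empty results tibble from [run_batch()].
#' @param path Output file path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) stop("empty results table", call. = FALSE)
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(results, path, progress = FALSE)
  } else {
    readr::write_csv(results, path, progress = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
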