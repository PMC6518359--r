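#' Symmetric percent difference
#'
#' `200 * (x - ref) / (x + ref)`: the mean-relative percent difference
#' used throughout the comparison engine.  Antisymmetric in its arguments
#' and bounded in (-200, 200) for positive inputs.
#'
#' @param x,ref Positive values (vectorized).
#' @return Percent difference.
#' @export
#' @examples
#' percent_difference(1830, 1320)  # 32.38...
percent_difference <- function(x, ref) {
  if (any(x + ref == 0)) {
    abort("degenerate denominator: x + ref = 0", class = "petiq_validation_error")
  }
  200 * (x - ref) / (x + ref)
}

# round half away from zero, matching printed 1-decimal table style
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a dose table
#'
#' Loads a regions-by-configurations dose table: a `region` column, an
#' optional `unit` column, and one positive numeric column per
#' reconstruction configuration.  Malformed cells are reported with their
#' line number.
#'
#' @param path CSV path; defaults to the packaged table of printed dose
#'   estimates (tumor in mGy/MBq, organs in mSv/MBq).
#' @return A `dose_table` tibble.
#' @export
read_dose_table <- function(path = petiq_extdata("table1_doses.csv")) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"region" %in% names(df)) {
    abort("dose table must have a 'region' column", class = "petiq_io_error")
  }
  cfg <- setdiff(names(df), c("region", "unit"))
  for (cc in cfg) {
    bad <- which(!is.finite(df[[cc]]) | df[[cc]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("non-positive or missing dose in column '%s', line(s) %s",
                    cc, paste(bad + 1, collapse = ", ")),
            class = "petiq_io_error")
    }
  }
  structure(tibble::as_tibble(df), config_columns = cfg,
            class = c("dose_table", class(df)))
}

#' Percent-difference comparison against a reference configuration
#'
#' Expresses every configuration column of a dose table as the symmetric
#' percent difference against a reference (gold standard) column.  The
#' reference column is dropped from the output; values are kept at full
#' precision, with rounding (half away from zero, 1 decimal) applied only
#' by [write_comparison()] or via `rounded = TRUE`.
#'
#' @param table A [read_dose_table()] result (or compatible data frame).
#' @param ref_column Name of the reference configuration column.
#' @param rounded Round to 1 decimal (rendering convention)?
#' @return A `comparison_table` tibble: `region` plus one percent-
#'   difference column per non-reference configuration.
#' @export
#' @examples
#' cmp <- compare_to_reference(read_dose_table(), "osem2d_it1")
#' cmp[cmp$region == "Tumor", "osem2d_it10"]
compare_to_reference <- function(table, ref_column = "osem2d_it1",
                                 rounded = FALSE) {
  cfg <- attr(table, "config_columns") %||%
    setdiff(names(table), c("region", "unit"))
  if (!ref_column %in% cfg) {
    abort(paste0("reference column '", ref_column, "' not found"),
          class = "petiq_lookup_error")
  }
  ref <- table[[ref_column]]
  out <- tibble::tibble(region = table$region)
  for (cc in setdiff(cfg, ref_column)) {
    pd <- percent_difference(table[[cc]], ref)
    out[[cc]] <- if (rounded) round_half_away(pd, 1) else pd
  }
  structure(out, ref_column = ref_column,
            class = c("comparison_table", class(out)))
}

#' @rdname compare_to_reference
#' @param x A `comparison_table`.
#' @param path Output CSV path.
#' @export
write_comparison <- function(x, path) {
  out <- dplyr::mutate(tibble::as_tibble(x),
                       dplyr::across(dplyr::where(is.numeric),
                                     ~ round_half_away(.x, 1)))
  readr::write_csv(out, path)
  invisible(path)
}

#' Range and relative spread of a dose series
#'
#' `rel_spread_percent = 100 * (max - min) / min` over a positive series.
#'
#' @param series Non-empty positive numeric vector.
#' @return A one-row tibble: `min`, `max`, `rel_spread_percent`.
#' @export
#' @examples
#' range_spread(c(923, 1830))  # spread 98.3%
range_spread <- function(series) {
  if (length(series) == 0) abort("empty series", class = "petiq_validation_error")
  if (any(series <= 0)) {
    abort("series must be positive", class = "petiq_validation_error")
  }
  tibble::tibble(min = min(series), max = max(series),
                 rel_spread_percent = 100 * (max(series) - min(series)) / min(series))
}

#' Normalize a series by its maximum
#'
#' Divides by the maximum so the largest element maps to 1; order is
#' preserved.
#'
#' @param series Numeric vector with positive maximum.
#' @return The normalized vector.
#' @export
normalize_by_max <- function(series) {
  m <- max(series)
  if (!is.finite(m) || m <= 0) {
    abort("series maximum must be positive", class = "petiq_validation_error")
  }
  series / m
}

#' Coefficient of determination
#'
#' Squared Pearson correlation between two series (e.g. normalized RC
#' versus normalized %ID/g across reconstruction configurations).
#'
#' @param x,y Numeric vectors, length >= 3, non-zero variance.
#' @return r-squared.
#' @export
coefficient_of_determination <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    abort("need >= 3 paired observations", class = "petiq_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in input", class = "petiq_validation_error")
  }
  cor(x, y)^2
}
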