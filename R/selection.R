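#' Selection criterion on the RC-NU trade-off
#'
#' The selection rule for an optimal reconstruction configuration: the
#' 3 mm-rod recovery coefficient must lie strictly inside
#' `(rc_low, rc_high)` and the non-uniformity strictly below
#' `nu_max_percent`.  Boundary values fail (strict inequalities).
#'
#' @param rc_low,rc_high Open RC interval (default 0.9-1.0).
#' @param nu_max_percent NU upper bound in percent SD (default 10).
#' @param rc_rod_mm Rod diameter the RC refers to (default 3 mm).
#' @return A `criterion_config` object.
#' @export
criterion_config <- function(rc_low = 0.9, rc_high = 1.0,
                             nu_max_percent = 10, rc_rod_mm = 3) {
  if (rc_low >= rc_high) abort("rc_low must be below rc_high",
                               class = "petiq_validation_error")
  if (nu_max_percent <= 0) abort("nu_max_percent must be positive",
                                 class = "petiq_validation_error")
  structure(list(rc_low = rc_low, rc_high = rc_high,
                 nu_max_percent = nu_max_percent, rc_rod_mm = rc_rod_mm),
            class = "criterion_config")
}

criterion_rc_column <- function(cfg) sprintf("rc_%smm", format(cfg$rc_rod_mm))

#' Apply the RC-NU selection criterion to configuration entries
#'
#' Flags every entry whose RC (for the criterion rod) and NU satisfy
#' `rc_low < RC < rc_high` and `NU < nu_max_percent`.  Entries with a
#' missing metric are flagged unevaluable rather than dropped.
#'
#' @param entries Data frame with one row per reconstruction configuration
#'   carrying an RC column (`rc_3mm` by default) and `nu_percent`; the
#'   stacked output of [nu4_iq_report()] fits directly.
#' @param cfg A [criterion_config()].
#' @return An object of class `selection_result`: the input tibble with
#'   logical `passes` and `evaluable` columns, plus attribute `selected`
#'   (the passing subset ordered by NU ascending) and the criterion used.
#' @export
#' @examples
#' entries <- tibble::tibble(config = c("osem_it1", "osem_it10"),
#'                           rc_3mm = c(0.92, 1.4), nu_percent = c(7, 22))
#' apply_rc_nu_criterion(entries)
apply_rc_nu_criterion <- function(entries, cfg = criterion_config()) {
  entries <- tibble::as_tibble(entries)
  rc_col <- criterion_rc_column(cfg)
  if (!rc_col %in% names(entries) || !"nu_percent" %in% names(entries)) {
    abort(sprintf("entries must carry '%s' and 'nu_percent' columns", rc_col),
          class = "petiq_validation_error")
  }
  rc <- entries[[rc_col]]
  nu <- entries[["nu_percent"]]
  evaluable <- is.finite(rc) & is.finite(nu)
  passes <- evaluable & rc > cfg$rc_low & rc < cfg$rc_high &
    nu < cfg$nu_max_percent
  out <- dplyr::mutate(entries, passes = passes, evaluable = evaluable)
  selected <- dplyr::arrange(dplyr::filter(out, .data$passes),
                             .data$nu_percent)
  structure(out, selected = selected, criterion = cfg,
            class = c("selection_result", class(out)))
}

#' RC-NU trade-off table
#'
#' One row per (configuration, correction level) with the criterion RC,
#' the NU, and the pass flag -- the tabular form behind the RC-versus-NU
#' trade-off scatter.  CSV-serializable as-is.
#'
#' @inheritParams apply_rc_nu_criterion
#' @return A tibble with columns `config`, `correction` (if present),
#'   `rc`, `nu_percent`, `passes`.
#' @export
tradeoff_table <- function(entries, cfg = criterion_config()) {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0) {
    out <- tibble::tibble(config = character(), rc = double(),
                          nu_percent = double(), passes = logical())
    attr(out, "criterion") <- cfg
    class(out) <- c("tradeoff_table", class(out))
    return(out)
  }
  res <- apply_rc_nu_criterion(entries, cfg)
  keep <- intersect(c("config", "correction"), names(res))
  out <- dplyr::select(tibble::as_tibble(res), dplyr::all_of(keep),
                       rc = dplyr::all_of(criterion_rc_column(cfg)),
                       "nu_percent", "passes")
  attr(out, "criterion") <- cfg
  class(out) <- c("tradeoff_table", class(out))
  out
}

#' @rdname autoplot.selection_result
#' @exportS3Method ggplot2::autoplot
autoplot.tradeoff_table <- function(object, cfg = attr(object, "criterion"),
                                    ...) {
  autoplot.selection_result(object, cfg = cfg, ...)
}

#' Plot the RC-NU trade-off with the selection box
#'
#' @param object A [tradeoff_table()] result (or anything
#'   [apply_rc_nu_criterion()] accepts).
#' @param cfg Criterion drawn as the shaded acceptance box.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.selection_result <- function(object, cfg = attr(object, "criterion"),
                                      ...) {
  cfg <- cfg %||% criterion_config()
  df <- tibble::as_tibble(object)
  rc_col <- criterion_rc_column(cfg)
  if (!"rc" %in% names(df) && rc_col %in% names(df)) {
    df$rc <- df[[rc_col]]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rc, y = .data$nu_percent)) +
    ggplot2::annotate("rect", xmin = cfg$rc_low, xmax = cfg$rc_high,
                      ymin = 0, ymax = cfg$nu_max_percent,
                      fill = "red", alpha = 0.12, colour = "red") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$passes)) +
    ggplot2::labs(x = sprintf("Recovery coefficient (%g mm rod)", cfg$rc_rod_mm),
                  y = "Non-uniformity (%SD)", colour = "passes")
}
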