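#' Peak concentration in an ROI
#'
#' Extracts the maximum voxel value inside an ROI mask, with its voxel
#' index for audit.
#'
#' @param img A [volume_3d()].
#' @param mask Logical voxel mask, non-empty.
#' @return A list with `value` and `position` (array index row).
#' @export
roi_max_concentration <- function(img, mask) {
  if (!any(mask)) abort("empty ROI", class = "petiq_validation_error")
  v <- img$values
  v[!mask] <- -Inf
  idx <- arrayInd(which.max(v), dim(v))
  list(value = v[idx], position = idx)
}

#' Percent injected dose per gram
#'
#' `100 * concentration / (injected * density)`: the standard preclinical
#' uptake unit, with tissue density 1 g/mL by default.
#'
#' @param conc_Bq_per_mL Activity concentration (Bq/mL).
#' @param injected_Bq Injected activity (Bq, > 0).
#' @param density_g_per_mL Tissue density (default 1).
#' @return %ID/g.
#' @export
percent_id_per_gram <- function(conc_Bq_per_mL, injected_Bq,
                                density_g_per_mL = 1) {
  if (any(injected_Bq <= 0)) {
    abort("injected activity must be positive", class = "petiq_validation_error")
  }
  100 * conc_Bq_per_mL / (injected_Bq * density_g_per_mL)
}

#' Remove or restore physical decay correction on a TAC
#'
#' `decay_uncorrect()` multiplies a decay-corrected curve by
#' \eqn{e^{-\lambda t}} and flips its flag; `decay_correct()` is the exact
#' inverse.  Both refuse double application: dose integration must see
#' decay-uncorrected data exactly once.
#'
#' @param tac A tibble with `time_h`, `value`, `decay_corrected` columns.
#' @param lambda_phys Decay constant (1/h); defaults to the TAC's own
#'   attribute, else Cu-64.
#' @return The transformed TAC tibble.
#' @export
decay_uncorrect <- function(tac, lambda_phys = NULL) {
  lambda_phys <- lambda_phys %||% attr(tac, "lambda_phys") %||% cu64_lambda()
  if (!all(tac$decay_corrected)) {
    abort("TAC is already decay-uncorrected", class = "petiq_validation_error")
  }
  tac$value <- tac$value * exp(-lambda_phys * tac$time_h)
  tac$decay_corrected <- FALSE
  tac
}

#' @rdname decay_uncorrect
#' @export
decay_correct <- function(tac, lambda_phys = NULL) {
  lambda_phys <- lambda_phys %||% attr(tac, "lambda_phys") %||% cu64_lambda()
  if (any(tac$decay_corrected)) {
    abort("TAC is already decay-corrected", class = "petiq_validation_error")
  }
  tac$value <- tac$value * exp(lambda_phys * tac$time_h)
  tac$decay_corrected <- TRUE
  tac
}

#' Cumulated activity from a decay-uncorrected TAC
#'
#' Area under the decay-uncorrected curve in value-units x hours, with the
#' fixed integration conventions: the value is held constant from t = 0
#' back to the first time point (contribution `value[1] * t[1]`), the
#' observed span is integrated by the trapezoidal rule, and after the last
#' point the curve is assumed to follow pure physical decay
#' (analytic tail `value[n] / lambda`).
#'
#' @param tac Tibble with `time_h` and `value` (any activity-like unit);
#'   if a `decay_corrected` column is present it must be all `FALSE`.
#' @param lambda_phys Physical decay constant (1/h) for the tail.
#' @return Cumulated activity, in value-units x h.
#' @export
#' @examples
#' tt <- seq(0, 200, by = 0.05)
#' tac <- tibble::tibble(time_h = tt, value = 10 * exp(-cu64_lambda() * tt))
#' cumulated_activity(tac) * cu64_lambda() / 10  # ~1
cumulated_activity <- function(tac, lambda_phys = NULL) {
  lambda_phys <- lambda_phys %||% attr(tac, "lambda_phys") %||% cu64_lambda()
  if (!is.null(tac[["decay_corrected"]]) && any(tac[["decay_corrected"]])) {
    abort("cumulated activity requires a decay-uncorrected TAC",
          class = "petiq_validation_error")
  }
  t <- tac$time_h
  v <- tac$value
  if (length(t) < 2) abort("need at least two time points",
                           class = "petiq_validation_error")
  if (is.unsorted(t, strictly = TRUE)) {
    abort("time points must be strictly increasing", class = "petiq_validation_error")
  }
  if (any(v < 0)) abort("negative activity values", class = "petiq_validation_error")
  n <- length(t)
  head_part <- v[1] * t[1]
  trap <- sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
  tail_part <- v[n] / lambda_phys
  head_part + trap + tail_part
}

#' Residence time
#'
#' \eqn{\tau = \tilde A / A_0}: cumulated activity divided by the injected
#' activity, in hours.
#'
#' @param cumulated Cumulated activity (activity-units x h).
#' @param injected Injected activity in the same activity units (> 0).
#' @return Residence time in hours.
#' @export
residence_time <- function(cumulated, injected) {
  if (any(injected <= 0)) {
    abort("injected activity must be positive", class = "petiq_validation_error")
  }
  cumulated / injected
}

#' Residence time straight from a %ID/g TAC
#'
#' Converts a decay-uncorrected %ID/g curve to the fraction of injected
#' dose in the region (`value * mass_g / 100`) and integrates it with
#' [cumulated_activity()]; because the curve is already a fraction of
#' A0, the integral is the residence time directly.
#'
#' @param tac A `tac` tibble in %ID/g (decay-uncorrected).
#' @param mass_g Region mass in grams (default: the TAC's attribute).
#' @param lambda_phys Decay constant for the tail.
#' @return Residence time in hours.
#' @export
residence_time_from_tac <- function(tac, mass_g = NULL, lambda_phys = NULL) {
  mass_g <- mass_g %||% attr(tac, "mass_g")
  if (is.null(mass_g) || mass_g <= 0) {
    abort("region mass must be positive", class = "petiq_validation_error")
  }
  frac <- tac
  frac$value <- tac$value * mass_g / 100
  cumulated_activity(frac, lambda_phys)
}

#' Fit a power law to a sphere-model S-value table
#'
#' Least squares of `log S = log a + b log m` on a table of sphere masses
#' and S-values, giving the interpolant \eqn{S(m) = a m^b}.  The
#' non-linear (power-law) interpolation is used because, for the convex
#' decreasing S-versus-mass relationship, straight-line interpolation
#' between tabulated masses overestimates S.
#'
#' @param table Tibble with columns `mass_g` (strictly increasing) and
#'   `s_mGy_per_MBq_h` (strictly decreasing), at least 3 rows.
#' @return A `sphere_svalue_fit` with elements `a`, `b`, `model` (the
#'   underlying `lm`), and `table`; supports [predict()][s_value()],
#'   `tidy()` and `glance()`.
#' @export
fit_sphere_svalue <- function(table) {
  if (!all(c("mass_g", "s_mGy_per_MBq_h") %in% names(table))) {
    abort("table needs columns mass_g and s_mGy_per_MBq_h",
          class = "petiq_validation_error")
  }
  if (nrow(table) < 3) {
    abort("need at least 3 S-value points", class = "petiq_validation_error")
  }
  if (is.unsorted(table$mass_g, strictly = TRUE)) {
    abort("masses must be strictly increasing", class = "petiq_validation_error")
  }
  if (is.unsorted(rev(table$s_mGy_per_MBq_h), strictly = TRUE)) {
    abort("S-values must be strictly decreasing in mass",
          class = "petiq_validation_error")
  }
  fit <- lm(log(s_mGy_per_MBq_h) ~ log(mass_g), data = table)
  structure(list(a = exp(coef(fit)[[1]]), b = coef(fit)[[2]],
                 model = fit, table = tibble::as_tibble(table)),
            class = "sphere_svalue_fit")
}

#' Evaluate a fitted sphere S-value at a mass
#'
#' @param fit A [fit_sphere_svalue()] result.
#' @param mass_g Sphere mass in grams (> 0).  Masses outside the fitted
#'   table's hull are allowed but flagged with a warning.
#' @return S in mGy/(MBq h).
#' @export
s_value <- function(fit, mass_g) {
  if (any(mass_g <= 0)) abort("mass must be positive",
                              class = "petiq_validation_error")
  hull <- range(fit$table$mass_g)
  if (any(mass_g < hull[1] | mass_g > hull[2])) {
    warn("mass outside the fitted S-value table; extrapolating the power law")
  }
  fit$a * mass_g^fit$b
}

#' @export
print.sphere_svalue_fit <- function(x, ...) {
  cat(sprintf("<sphere_svalue_fit> S(m) = %.4g * m^%.4g over %g-%g g (%d points)\n",
              x$a, x$b, min(x$table$mass_g), max(x$table$mass_g),
              nrow(x$table)))
  invisible(x)
}

#' @rdname fit_sphere_svalue
#' @param x A `sphere_svalue_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sphere_svalue_fit <- function(x, ...) {
  # exact power-law tables fit perfectly; silence lm's perfect-fit notice
  cf <- suppressWarnings(summary(x$model)$coefficients)
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b),
                 std.error = c(x$a * cf[1, 2], cf[2, 2]))
}

#' @rdname fit_sphere_svalue
#' @exportS3Method generics::glance
glance.sphere_svalue_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 nobs = nrow(x$table))
}

#' Sphere-model tumor absorbed dose
#'
#' Dose per unit injected activity: \eqn{\tau \times S(m)}, with the tumor
#' mass from its volume under the 1 g/mL density assumption.
#'
#' @param tau_h Tumor residence time (h).
#' @param mass_g Tumor mass (g, > 0).
#' @param fit A [fit_sphere_svalue()] result.
#' @return Absorbed dose in mGy/MBq.
#' @export
tumor_absorbed_dose <- function(tau_h, mass_g, fit) {
  if (any(mass_g <= 0)) abort("mass must be positive",
                              class = "petiq_validation_error")
  tau_h * s_value(fit, mass_g)
}

#' Read an organ S-factor matrix
#'
#' Loads a (target x source) S-factor table with organ masses and tissue
#' weighting factors.  The CSV carries one row per target organ: a
#' `target` column, one numeric column per source organ, and `mass_g` and
#' `weight` columns.  Validated invariants: self-dose dominates every row
#' and the tissue weights sum to 1.
#'
#' @param path CSV path; defaults to the packaged synthetic fixture
#'   (clearly labeled synthetic: it is not any reference human phantom).
#' @return An `organ_smatrix`: list with `S` (matrix, mGy/(MBq h)),
#'   `masses_g`, `weights`.
#' @export
read_organ_smatrix <- function(path = petiq_extdata("smatrix_synthetic.csv")) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  sources <- setdiff(names(df), c("target", "mass_g", "weight"))
  S <- as.matrix(df[sources])
  rownames(S) <- df$target
  if (!all(sources %in% df$target)) {
    abort("every source column must also be a target row",
          class = "petiq_validation_error")
  }
  for (tg in intersect(rownames(S), colnames(S))) {
    if (S[tg, tg] < max(S[tg, ])) {
      abort(sprintf("self-dose must dominate row '%s'", tg),
            class = "petiq_validation_error")
    }
  }
  if (abs(sum(df$weight) - 1) > 1e-6) {
    abort("tissue weighting factors must sum to 1",
          class = "petiq_validation_error")
  }
  structure(list(S = S, masses_g = setNames(df$mass_g, df$target),
                 weights = setNames(df$weight, df$target)),
            class = "organ_smatrix")
}

#' Organ dose table from residence times
#'
#' MIRD-style assembly: per-target dose
#' \eqn{D_T = \sum_s \tau_s S(T \leftarrow s)} (mSv/MBq) and the
#' tissue-weighted sum \eqn{\sum_T w_T D_T} reported as the effective
#' dose.  The computation is linear in every residence time.
#'
#' @param res Tibble with `region` and `tau_h` columns (source organs).
#' @param smat An [read_organ_smatrix()] result.
#' @return A `dose_report`: tibble of per-target `dose_mSv_per_MBq` with
#'   the effective dose and provenance as attributes.
#' @export
organ_dose <- function(res, smat) {
  missing <- setdiff(res$region, colnames(smat$S))
  if (length(missing) > 0) {
    abort(paste("no S-matrix column for source region(s):",
                paste(missing, collapse = ", ")),
          class = "petiq_lookup_error")
  }
  tau <- setNames(res$tau_h, res$region)
  dose <- as.numeric(smat$S[, names(tau), drop = FALSE] %*% tau)
  out <- tibble::tibble(target = rownames(smat$S), dose_mSv_per_MBq = dose)
  attr(out, "effective_dose_mSv_per_MBq") <-
    sum(smat$weights[out$target] * dose)
  attr(out, "sources") <- res
  class(out) <- c("dose_report", class(out))
  out
}

#' @export
print.dose_report <- function(x, ...) {
  NextMethod()
  cat(sprintf("# effective dose: %.4g mSv/MBq\n",
              attr(x, "effective_dose_mSv_per_MBq")))
  invisible(x)
}

#' Scale mouse residence times to a human phantom
#'
#' Default relative-organ-mass scaling:
#' \deqn{\tau_{human} = \tau_{mouse} \times
#'   \frac{m_{organ,human}/m_{body,human}}{m_{organ,mouse}/m_{body,mouse}}.}
#' A region named `total_body` is invariant under this rule.  The strategy
#' name is recorded on the result for provenance.
#'
#' @param res Tibble with `region`, `tau_h`.
#' @param mouse_masses,human_masses Tibbles with `region`, `mass_g`,
#'   including a `total_body` row.
#' @param strategy Only `"relative_organ_mass"` is implemented.
#' @return The scaled residence-time tibble.
#' @export
scale_mouse_to_human <- function(res, mouse_masses, human_masses,
                                 strategy = "relative_organ_mass") {
  strategy <- match.arg(strategy)
  lookup <- function(masses, region) {
    m <- masses$mass_g[match(region, masses$region)]
    if (any(is.na(m))) {
      abort(paste("missing mass entries for:",
                  paste(region[is.na(m)], collapse = ", ")),
            class = "petiq_lookup_error")
    }
    m
  }
  mb_m <- lookup(mouse_masses, "total_body")
  mb_h <- lookup(human_masses, "total_body")
  out <- res
  out$tau_h <- res$tau_h *
    (lookup(human_masses, res$region) / mb_h) /
    (lookup(mouse_masses, res$region) / mb_m)
  attr(out, "scaling_strategy") <- strategy
  out
}
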