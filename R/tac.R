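#' Default imaging schedule
#'
#' Hours post-injection at which PET data are acquired; defaults to the
#' four-point antibody schedule 2, 15, 40, 64 h.
#'
#' @param times_h Strictly increasing vector of hours (first >= 0).
#' @return A numeric vector of class `timepoint_schedule`.
#' @export
timepoint_schedule <- function(times_h = c(2, 15, 40, 64)) {
  if (is.unsorted(times_h, strictly = TRUE) || times_h[1] < 0) {
    abort("times must be strictly increasing and non-negative",
          class = "petiq_validation_error")
  }
  structure(times_h, class = "timepoint_schedule")
}

#' Mouse biodistribution kinetics for a Cu-64 antibody
#'
#' Per-region biexponential biological curves
#' \deqn{b(t) = A_1 e^{-k_{clear} t} + A_2 e^{-k_{uptake} t}}
#' in %ID/g, with \eqn{A_2 < 0} producing the slow tumor uptake phase
#' typical of an intact antibody (peak near 40 h for the default tumor
#' parameters).  Physical decay is applied separately via `lambda_phys`.
#' Region masses (g) convert %ID/g to the fraction of the injected dose
#' residing in the region.
#'
#' @param regions Tibble with columns `region`, `A1`, `k_clear` (1/h),
#'   `A2`, `k_uptake` (1/h), `mass_g`; the default set emulates a
#'   tumor-bearing mouse.
#' @param injected_activity_MBq Injected activity (default 14.8 MBq,
#'   i.e. 400 uCi).
#' @param lambda_phys Physical decay constant (1/h); defaults to Cu-64.
#' @return A `mouse_kinetics_spec` object.
#' @export
mouse_kinetics_spec <- function(regions = NULL,
                                injected_activity_MBq = 14.8,
                                lambda_phys = cu64_lambda()) {
  regions <- regions %||% tibble::tribble(
    ~region,   ~A1, ~k_clear, ~A2,  ~k_uptake, ~mass_g,
    "tumor",    25,  0.010,   -25,   0.08,      0.2,
    "liver",    18,  0.015,   -8,    0.30,      1.3,
    "kidneys",   9,  0.020,   -4,    0.50,      0.4,
    "spleen",   12,  0.012,   -6,    0.25,      0.1,
    "lungs",     8,  0.018,   -4,    0.40,      0.15,
    "brain",     1,  0.010,   -0.6,  0.30,      0.4,
    "stomach",   4,  0.020,   -2,    0.40,      0.5,
    "intestines", 5, 0.018,   -2.5,  0.35,      2.0
  )
  needed <- c("region", "A1", "k_clear", "A2", "k_uptake", "mass_g")
  if (!all(needed %in% names(regions))) {
    abort(paste("kinetics table needs columns:", paste(needed, collapse = ", ")),
          class = "petiq_validation_error")
  }
  if (any(regions$k_clear <= 0) || any(regions$k_uptake <= 0)) {
    abort("rate constants must be positive", class = "petiq_validation_error")
  }
  if (injected_activity_MBq <= 0) {
    abort("injected activity must be positive", class = "petiq_validation_error")
  }
  structure(list(regions = tibble::as_tibble(regions),
                 injected_activity_MBq = injected_activity_MBq,
                 lambda_phys = lambda_phys),
            class = "mouse_kinetics_spec")
}

kinetics_row <- function(kin, region) {
  row <- dplyr::filter(kin$regions, .data$region == !!region)
  if (nrow(row) != 1) {
    abort(paste0("unknown region '", region, "'"), class = "petiq_lookup_error")
  }
  row
}

# biological curve in %ID/g (no physical decay)
biological_uptake <- function(kin, region, t_h) {
  row <- kinetics_row(kin, region)
  row$A1 * exp(-row$k_clear * t_h) + row$A2 * exp(-row$k_uptake * t_h)
}

#' Generate a decay-uncorrected organ time-activity curve
#'
#' Samples the region's biological curve at the scheduled times and applies
#' physical decay: `value(t) = b(t) * exp(-lambda * t)`, in %ID/g.  A
#' multiplicative log-normal noise term with coefficient of variation
#' `noise_cv` emulates measurement scatter (0 = noiseless).
#'
#' @param kin A [mouse_kinetics_spec()].
#' @param sched A [timepoint_schedule()] (or plain numeric hours).
#' @param region Region name present in the kinetics spec.
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param seed Seed used when `noise_cv > 0`.
#' @return A `tac` tibble: `region`, `time_h`, `value` (%ID/g),
#'   `decay_corrected` (all `FALSE`), with the injected activity, region
#'   mass, and lambda as attributes.
#' @export
#' @examples
#' generate_organ_tac(mouse_kinetics_spec(), region = "tumor")
generate_organ_tac <- function(kin, sched = timepoint_schedule(),
                               region = "tumor", noise_cv = 0, seed = 1L) {
  t_h <- as.numeric(sched)
  bio <- biological_uptake(kin, region, t_h)
  val <- bio * exp(-kin$lambda_phys * t_h)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mult <- withr::with_seed(as.integer(seed),
                             exp(stats::rnorm(length(val), -sdlog^2 / 2, sdlog)))
    val <- val * mult
  }
  out <- tibble::tibble(region = region, time_h = t_h, value = val,
                        decay_corrected = FALSE)
  attr(out, "injected_activity_MBq") <- kin$injected_activity_MBq
  attr(out, "mass_g") <- kinetics_row(kin, region)$mass_g
  attr(out, "lambda_phys") <- kin$lambda_phys
  attr(out, "units") <- "%ID/g"
  class(out) <- c("tac", class(out))
  out
}

#' Analytic residence time for a kinetics region
#'
#' Closed-form residence time implied by the biexponential model: with
#' fraction-of-injected-dose curve
#' \eqn{f(t) = m/100\,(A_1 e^{-k_c t} + A_2 e^{-k_u t})} and physical decay
#' \eqn{e^{-\lambda t}},
#' \deqn{\tau = \frac{m}{100}\left(\frac{A_1}{k_c + \lambda} +
#'       \frac{A_2}{k_u + \lambda}\right).}
#' Serves as the independent oracle for the numeric TAC-integration chain.
#'
#' @inheritParams generate_organ_tac
#' @return Residence time in hours.
#' @export
analytic_residence_time <- function(kin, region) {
  row <- kinetics_row(kin, region)
  (row$mass_g / 100) * (row$A1 / (row$k_clear + kin$lambda_phys) +
                          row$A2 / (row$k_uptake + kin$lambda_phys))
}
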