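#' Michaelis-Menten rate
#'
#' Saturation rate `v = kcat * E0 * S / (Km + S)`.
#'
#' @param S_uM Substrate concentration(s), micromolar.
#' @param Km_uM Michaelis constant, micromolar (> 0).
#' @param kcat_s Turnover number, s^-1.
#' @param E0_uM Total enzyme, micromolar (default 1, giving rates in s^-1 per
#'   enzyme).
#'
#' @return Rates, micromolar per second (or s^-1 per enzyme when `E0_uM = 1`).
#' @export
#' @examples
#' michaelis_menten_rate(77, Km_uM = 77, kcat_s = 0.38)  # half-maximal
michaelis_menten_rate <- function(S_uM, Km_uM, kcat_s, E0_uM = 1) {
  if (Km_uM <= 0) abort("`Km_uM` must be > 0", class = "chitokin_invalid_parameter")
  kcat_s * E0_uM * S_uM / (Km_uM + S_uM)
}

#' Fit Michaelis-Menten parameters to initial-rate data
#'
#' Nonlinear least squares (Levenberg-Marquardt) estimation of Km and Vmax
#' from substrate-concentration vs initial-rate data; kcat is Vmax divided by
#' the enzyme concentration. With exactly two distinct concentrations the
#' two-parameter system is solved algebraically instead.
#'
#' @param data Data frame with columns `substrate_uM` and `rate` (micromolar
#'   per second, or s^-1 per enzyme if rates are already normalized).
#' @param enzyme_total_uM Total enzyme, micromolar; default 1 (rates treated
#'   as already normalized, so kcat = Vmax).
#'
#' @return An object of class `mm_fit` with `Km_uM`, `kcat_s`,
#'   `kcat_over_Km` (M^-1 s^-1), `Vmax`, standard errors where estimable,
#'   and the underlying `nls` fit (when one was run).
#' @export
#' @examples
#' d <- tibble::tibble(substrate_uM = c(25, 50, 100, 200, 400, 500))
#' d$rate <- michaelis_menten_rate(d$substrate_uM, 77, 0.38)
#' fit_michaelis_menten(d)
fit_michaelis_menten <- function(data, enzyme_total_uM = 1) {
  if (!all(c("substrate_uM", "rate") %in% names(data))) {
    abort("`data` needs columns `substrate_uM` and `rate`",
          class = "chitokin_invalid_input")
  }
  data <- data[is.finite(data$substrate_uM) & is.finite(data$rate), ]
  S <- data$substrate_uM
  v <- data$rate
  if (any(S < 0)) {
    abort("substrate concentrations must be >= 0", class = "chitokin_invalid_input")
  }
  if (all(v == 0)) {
    abort("all rates are zero; Km and kcat are unidentifiable",
          class = "chitokin_unidentifiable_fit")
  }
  nuniq <- length(unique(S[S > 0]))
  if (nuniq < 2) {
    abort("need at least 2 distinct non-zero substrate concentrations",
          class = "chitokin_unidentifiable_fit")
  }
  se <- c(Km_uM = NA_real_, Vmax = NA_real_)
  if (nuniq == 2 && length(S[S > 0]) == 2) {
    # exact algebraic solution of the 2x2 system
    i <- order(S[S > 0])
    Sp <- S[S > 0][i]; vp <- v[S > 0][i]
    Km <- Sp[1] * Sp[2] * (vp[2] - vp[1]) / (vp[1] * Sp[2] - vp[2] * Sp[1])
    Vmax <- vp[1] * (Km + Sp[1]) / Sp[1]
    fit <- NULL
  } else {
    Vm0 <- 1.05 * max(v)
    Km0 <- S[which.min(abs(v - max(v) / 2))]
    if (!is.finite(Km0) || Km0 <= 0) Km0 <- stats::median(S[S > 0])
    fit <- minpack.lm::nlsLM(
      rate ~ Vmax * substrate_uM / (Km + substrate_uM),
      data = data,
      start = list(Vmax = Vm0, Km = Km0),
      lower = c(Vmax = 0, Km = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    cf <- stats::coef(fit)
    Vmax <- unname(cf["Vmax"]); Km <- unname(cf["Km"])
    ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                    error = function(e) NULL)
    if (!is.null(ses)) se <- c(Km_uM = unname(ses["Km"]), Vmax = unname(ses["Vmax"]))
  }
  if (!is.finite(Km) || Km <= 0) {
    abort("fit produced a non-positive Km; design is degenerate",
          class = "chitokin_unidentifiable_fit")
  }
  kcat <- Vmax / enzyme_total_uM
  structure(
    list(Km_uM = Km, kcat_s = kcat,
         kcat_over_Km = catalytic_efficiency(Km, kcat),
         Vmax = Vmax, enzyme_total_uM = enzyme_total_uM,
         se = se, fit = fit, data = as_tibble(data)),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> Km =", format(x$Km_uM, digits = 4), "uM, kcat =",
      format(x$kcat_s, digits = 4), "s^-1, kcat/Km =",
      format(x$kcat_over_Km, digits = 5), "M^-1 s^-1\n")
  invisible(x)
}

#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("Km_uM", "kcat_s"),
    estimate = c(x$Km_uM, x$kcat_s),
    std.error = c(unname(x$se["Km_uM"]),
                  unname(x$se["Vmax"]) / x$enzyme_total_uM)
  )
}

#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(Km_uM = x$Km_uM, kcat_s = x$kcat_s, kcat_over_Km = x$kcat_over_Km,
         n = nrow(x$data))
}

# round half away from zero, the convention used for reported integer
# efficiencies and fold ratios
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Catalytic efficiency kcat/Km
#'
#' @param Km_uM Michaelis constant, micromolar (> 0).
#' @param kcat_s Turnover number, s^-1.
#' @param rounded Round half-away-from-zero to integer M^-1 s^-1, the
#'   convention for reported tables (default `FALSE`).
#'
#' @return kcat/Km in M^-1 s^-1 (vectorised).
#' @export
#' @examples
#' catalytic_efficiency(77, 0.38, rounded = TRUE)  # 4935
catalytic_efficiency <- function(Km_uM, kcat_s, rounded = FALSE) {
  if (any(Km_uM <= 0)) {
    abort("`Km_uM` must be > 0", class = "chitokin_invalid_parameter")
  }
  eff <- kcat_s / (Km_uM * 1e-6)
  if (rounded) round_half_away(eff) else eff
}

#' Fold ratio of two catalytic efficiencies
#'
#' @param numerator,denominator Efficiencies, M^-1 s^-1; denominator > 0.
#' @param rounded Round half-away-from-zero to the nearest integer fold
#'   (default `TRUE`, the report convention).
#'
#' @return The fold difference.
#' @export
#' @examples
#' efficiency_ratio(4935, 465)  # 11
efficiency_ratio <- function(numerator, denominator, rounded = TRUE) {
  if (any(denominator <= 0)) {
    abort("`denominator` must be > 0", class = "chitokin_invalid_parameter")
  }
  r <- numerator / denominator
  if (rounded) round_half_away(r) else r
}

#' Published steady-state kinetic constants of the V. harveyi GlcNAcases
#'
#' The reported Km, kcat and kcat/Km of VhNag1 (pNP-GlcNAc only) and VhNag2
#' (pNP-GlcNAc and the chitooligosaccharides GlcNAc_2..GlcNAc_6), used as
#' the preset parameterisation of the kinetic model (kcat per substrate is
#' allocated to the cleavage constant k_plus1) and as ground truth for the
#' synthetic initial-rate generator.
#'
#' @return A tibble with columns `substrate`, `enzyme`, `Km_uM`, `kcat_s`
#'   and `kcat_over_Km_printed` (the reported integer value).
#' @export
#' @examples
#' vhnag2_kinetic_table()
vhnag2_kinetic_table <- function() {
  tibble(
    substrate = c("pNP-GlcNAc", "pNP-GlcNAc", "GlcNAc2", "GlcNAc3",
                  "GlcNAc4", "GlcNAc5", "GlcNAc6"),
    enzyme = c("VhNag1", rep("VhNag2", 6)),
    Km_uM = c(172, 77, 179, 441, 329, 496, 421),
    kcat_s = c(0.08, 0.38, 0.01, 0.10, 0.10, 0.09, 0.07),
    kcat_over_Km_printed = c(465, 4935, 56, 228, 304, 181, 166)
  )
}
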