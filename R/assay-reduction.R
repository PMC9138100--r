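#' Correct raw betalain absorbances for coloured impurities
#'
#' Applies the von Elbe three-wavelength correction to a microplate reading.
#' From absorbances at 538 nm (`a`, betacyanin maximum), 476 nm (`b`,
#' betaxanthin maximum) and 600 nm (`c`, impurity estimate):
#' \deqn{X = 1.095 (a - c), \quad Z = a - X, \quad Y = b - Z - X/3.1}
#' where `X` is the betanin absorbance corrected for coloured impurities,
#' `Y` the corrected vulgaxanthin-I absorbance and `Z` the impurity
#' absorbance. Negative corrected values are possible with noisy readings;
#' they are flagged, not clamped, so that QC can surface instrument problems.
#'
#' @param a,b,c absorbances (AU) at 538, 476 and 600 nm; vectors are
#'   processed elementwise.
#' @return a data.frame with columns `X`, `Y`, `Z` and logical `flag_negative`
#'   (TRUE where any corrected absorbance is negative).
#' @examples
#' betalain_correct(0.5, 0.4, 0.1)
#' @export
betalain_correct <- function(a, b, c) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(!is.finite(c)))
    stop("non-finite absorbance", call. = FALSE)
  n <- max(length(a), length(b), length(c))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  X <- 1.095 * (a - c)
  Z <- a - X
  Y <- b - Z - X / 3.1
  data.frame(X = X, Y = Y, Z = Z,
             flag_negative = X < 0 | Y < 0 | Z < 0)
}

#' Pigment concentration from a corrected absorbance
#'
#' Converts a corrected absorbance into a pigment concentration in
#' mg/100 mL: \deqn{C = A_{corr} \cdot F \cdot 1000 / A^{1\%}} with `F` the
#' dilution factor (25 and 12.5 are the documented microplate presets) and
#' `A1pct` the absorbance coefficient of a 1% (w/v) solution: 1120 for
#' betanin (betacyanins), 750 for vulgaxanthin-I (betaxanthins).
#'
#' @param corrected_abs corrected absorbance (AU), e.g. `X` or `Y` from
#'   [betalain_correct()].
#' @param F_dilution dilution factor, > 0.
#' @param A1pct absorbance coefficient, > 0.
#' @return concentration in mg/100 mL (same length as `corrected_abs`).
#' @examples
#' pigment_concentration(0.438, 25, 1120)
#' @export
pigment_concentration <- function(corrected_abs, F_dilution, A1pct) {
  if (any(!is.finite(corrected_abs))) stop("non-finite absorbance", call. = FALSE)
  if (any(F_dilution <= 0)) stop("dilution factor must be > 0", call. = FALSE)
  if (any(A1pct <= 0)) stop("absorbance coefficient must be > 0", call. = FALSE)
  corrected_abs * F_dilution * 1000 / A1pct
}

#' Absorbance coefficients of the betalain reference pigments
#'
#' `A1pct` of betanin (1120) and vulgaxanthin-I (750), the constants used to
#' express total betacyanins and betaxanthins in equivalents of the two
#' reference pigments.
#' @return named numeric vector with elements `betanin` and `vulgaxanthin`.
#' @export
pigment_constants <- function() c(betanin = 1120, vulgaxanthin = 750)

#' DPPH radical-scavenging percentage
#'
#' \deqn{DPPH\% = 100 (A_{control} - A_{sample}) / A_{control}} computed from
#' 515 nm absorbances of the blank and the extract sample. Bounded in
#' `[0, 100]` on valid input.
#'
#' @param a_control blank absorbance (AU), > 0.
#' @param a_sample sample absorbance (AU), >= 0.
#' @return percent inhibition.
#' @export
dpph_percent <- function(a_control, a_sample) {
  if (any(!is.finite(a_control)) || any(!is.finite(a_sample)))
    stop("non-finite absorbance", call. = FALSE)
  if (any(a_control <= 0)) stop("control absorbance must be > 0", call. = FALSE)
  if (any(a_sample < 0)) stop("sample absorbance must be >= 0", call. = FALSE)
  100 * (a_control - a_sample) / a_control
}

#' Fit a linear standard curve
#'
#' Ordinary least-squares line `signal ~ concentration` for standards such as
#' gallic acid (Folin-Ciocalteu, GAE) or Trolox (ABTS/RP/BCB equivalents).
#'
#' @param concentration,signal numeric vectors of standards (>= 2 distinct
#'   concentrations).
#' @param standard_name free-text name of the calibration standard.
#' @return an object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r2` and `standard_name`.
#' @seealso [apply_calibration()]
#' @export
fit_calibration <- function(concentration, signal, standard_name = "standard") {
  if (length(concentration) != length(signal) || length(concentration) < 2L)
    stop("need >= 2 (concentration, signal) standards", call. = FALSE)
  if (length(unique(concentration)) < 2L)
    stop("degenerate design: all concentrations identical", call. = FALSE)
  fit <- stats::lm(signal ~ concentration)
  cf <- stats::coef(fit)
  r2 <- if (stats::var(signal) > 0) summary(fit)$r.squared else 1
  structure(list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
                 r2 = r2, standard_name = standard_name),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve (%s): signal = %.6g * conc + %.6g (r2 = %.4f)\n",
              x$standard_name, x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Invert a standard curve
#'
#' Maps an observed signal back to a concentration in the standard's units:
#' `(signal - intercept) / slope`.
#'
#' @param curve a [fit_calibration()] result.
#' @param signal observed signal(s).
#' @return concentration(s) in units of the calibration standard.
#' @export
apply_calibration <- function(curve, signal) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("cannot invert a zero-slope curve", call. = FALSE)
  (signal - curve$intercept) / curve$slope
}

#' Reduce a panel of raw betalain absorbances
#'
#' Convenience wrapper: corrects a table of (a538, a476, a600) triplets and
#' returns betacyanin and betaxanthin concentrations in mg/100 mL. An
#' optional `scale` hook (e.g. extract volume over sample mass) converts the
#' per-volume result to a per-mass basis when that arithmetic is known.
#'
#' @param panel data.frame with columns `a538`, `a476`, `a600` and optionally
#'   `F` (dilution factor per well).
#' @param F_dilution dilution factor used where the panel has no `F` column.
#' @param scale optional multiplicative factor applied to both concentrations.
#' @return data.frame with the corrected absorbances, concentrations
#'   (`betacyanin`, `betaxanthin`, mg/100 mL before `scale`) and QC flags.
#' @export
reduce_absorbance_panel <- function(panel, F_dilution = 25, scale = 1) {
  need <- c("a538", "a476", "a600")
  if (!all(need %in% colnames(panel)))
    stop("panel must have columns a538, a476, a600", call. = FALSE)
  Fv <- if ("F" %in% colnames(panel)) panel$F else rep(F_dilution, nrow(panel))
  corr <- betalain_correct(panel$a538, panel$a476, panel$a600)
  k <- pigment_constants()
  corr$betacyanin <- pigment_concentration(corr$X, Fv, k[["betanin"]]) * scale
  corr$betaxanthin <- pigment_concentration(corr$Y, Fv, k[["vulgaxanthin"]]) * scale
  corr
}
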