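# Two-state duplex melting thermodynamics.
#
# Model: non-self-complementary strands A + B <-> AB at equal concentration,
# total single-strand concentration Ct (both strands summed). At the melting
# temperature the association constant satisfies K(Tm) = 4/Ct, giving the
# linear relationship 1/Tm = (R ln(Ct/4) + dS)/dH. All internal energies are
# in cal; dH is reported in kcal/mol, dS in cal/(mol K).

# gas constant, cal/(mol K)
R_GAS <- 1.987204

KELVIN0 <- 273.15

#' Equilibrium duplex fraction of a two-state melt
#'
#' Fraction of strands paired at temperature `T_K` for a non-self-complementary
#' duplex with association enthalpy `dH` and entropy `dS`, both strands present
#' at `Ct/2` each. Solves `K(T) (Ct/2 - x)^2 = x` for the duplex concentration
#' `x` and returns `alpha = 2 x / Ct`, with `K(T) = exp(-(dH*1000 - T dS)/(R T))`.
#'
#' @param dH association enthalpy, kcal/mol (negative for a stable duplex)
#' @param dS association entropy, cal/(mol K)
#' @param Ct total single-strand concentration, mol/L (sum of both strands)
#' @param T_K absolute temperature(s), K
#' @return duplex fraction(s) in `[0, 1]`, strictly decreasing in temperature
#'   when `dH < 0`
#' @examples
#' two_state_fraction(-118.8, -350.9, 6e-6, 310.15)
#' @export
two_state_fraction <- function(dH, dS, Ct, T_K) {
  stopifnot(is.numeric(dH), is.numeric(dS), is.numeric(Ct), is.numeric(T_K))
  if (!all(is.finite(c(dH, dS, Ct, T_K)))) {
    stop("non-finite thermodynamic parameters")
  }
  if (any(Ct <= 0)) stop("Ct must be > 0")
  if (any(T_K <= 0)) stop("temperature must be > 0 K")
  lnK <- -(dH * 1000 - T_K * dS) / (R_GAS * T_K)
  # b = K * Ct; alpha = (b + 1 - sqrt(2 b + 1)) / b, stable for small b via
  # the conjugate form and for huge b via the asymptotic 1 - sqrt(2/b)
  lnb <- lnK + log(Ct)
  alpha <- numeric(length(lnb))
  big <- lnb > 500
  alpha[big] <- 1 - sqrt(2) * exp(-lnb[big] / 2)
  b <- exp(lnb[!big])
  s <- sqrt(2 * b + 1)
  # (b + 1 - s)/b == b/(b + 1 + s), which avoids cancellation at small b
  alpha[!big] <- b / (b + 1 + s)
  pmin(pmax(alpha, 0), 1)
}

#' Predict the melting temperature from van't Hoff parameters
#'
#' Inverts the concentration relationship `1/Tm = (R ln(Ct/4) + dS)/dH`
#' (energies in cal). The returned temperature is where the duplex fraction
#' equals one half.
#'
#' @inheritParams two_state_fraction
#' @return list with `tm_K` and `tm_C`
#' @examples
#' predict_tm(-118.8, -350.9, 6e-6)
#' @export
predict_tm <- function(dH, dS, Ct) {
  if (!all(is.finite(c(dH, dS, Ct)))) stop("non-finite parameters")
  if (dH == 0) stop("dH must be nonzero")
  if (Ct <= 0) stop("Ct must be > 0")
  denom <- dS + R_GAS * log(Ct / 4)
  tm_K <- dH * 1000 / denom
  if (!is.finite(tm_K) || tm_K <= 0) {
    stop("parameter set does not define a physical melting temperature")
  }
  list(tm_K = tm_K, tm_C = tm_K - KELVIN0)
}

#' Standard Gibbs free energy of duplex formation
#'
#' `dG = dH - T dS / 1000`, reported in kcal/mol. At 310.15 K this is the
#' conventional dG(37 C) of hybridization thermodynamics.
#'
#' @inheritParams two_state_fraction
#' @param T_K absolute temperature, K (default 310.15, i.e. 37 C)
#' @return dG in kcal/mol
#' @examples
#' gibbs_free_energy(-118.8, -350.9) # about -10.0 kcal/mol
#' @export
gibbs_free_energy <- function(dH, dS, T_K = 310.15) {
  stopifnot(is.numeric(dH), is.numeric(dS), is.numeric(T_K))
  if (any(T_K <= 0)) stop("temperature must be > 0 K")
  dH - T_K * dS / 1000
}

#' Melting temperature difference
#'
#' Tm of a test duplex minus Tm of its reference duplex, rounded to one
#' decimal place as conventionally tabulated.
#'
#' @param tm_test_C,tm_reference_C melting temperatures in degrees C
#' @return delta Tm in degrees C (1 d.p.)
#' @examples
#' delta_tm(58.6, 66.2)
#' @export
delta_tm <- function(tm_test_C, tm_reference_C) {
  if (!all(is.finite(c(tm_test_C, tm_reference_C)))) {
    stop("non-finite Tm input")
  }
  round(tm_test_C - tm_reference_C, 1)
}

#' C3'-endo sugar pucker percentage from a J(1'-2') coupling
#'
#' Empirical two-state ribose conformer estimate: the C3'-endo (north,
#' A-form-like) population is `100 - 10 J` percent, where `J` is the
#' H1'-H2' three-bond coupling constant in Hz, clamped to `[0, 100]`.
#'
#' @param j_coupling_hz J(1'-2') in Hz, nonnegative
#' @return list with `j_coupling_hz`, `c3_endo_percent` and a `clamped` flag
#' @examples
#' c3_endo_percent(8.8) # 12 percent C3'-endo
#' @export
c3_endo_percent <- function(j_coupling_hz) {
  stopifnot(is.numeric(j_coupling_hz), length(j_coupling_hz) == 1L)
  if (!is.finite(j_coupling_hz) || j_coupling_hz < 0) {
    stop("J coupling must be a nonnegative finite number of Hz")
  }
  raw <- 100 - 10 * j_coupling_hz
  pct <- min(max(raw, 0), 100)
  list(
    j_coupling_hz = j_coupling_hz,
    c3_endo_percent = pct,
    clamped = !identical(raw, pct)
  )
}

#' Construct a melting curve
#'
#' One UV-melting trace: absorbance at 260 nm over an ascending temperature
#' grid, together with the total single-strand concentration of the sample.
#'
#' @param temperature_C strictly increasing temperatures (degrees C), >= 10 points
#' @param absorbance_au absorbances (arbitrary units), same length
#' @param total_strand_conc_M total single-strand concentration Ct, mol/L
#' @param label free-text metadata (sequence, buffer)
#' @return object of class `melting_curve`
#' @export
melting_curve <- function(temperature_C, absorbance_au, total_strand_conc_M,
                          label = "") {
  stopifnot(is.numeric(temperature_C), is.numeric(absorbance_au))
  if (length(temperature_C) < 10L) stop("melting curve needs >= 10 points")
  if (length(temperature_C) != length(absorbance_au)) {
    stop("temperature and absorbance lengths differ")
  }
  if (any(diff(temperature_C) <= 0)) {
    stop("temperatures must be strictly increasing")
  }
  if (!all(is.finite(absorbance_au))) stop("absorbances must be finite")
  if (!is.finite(total_strand_conc_M) || total_strand_conc_M <= 0) {
    stop("Ct must be a positive concentration in mol/L")
  }
  structure(
    list(
      temperature_C = as.numeric(temperature_C),
      absorbance_au = as.numeric(absorbance_au),
      total_strand_conc_M = total_strand_conc_M,
      label = as.character(label)
    ),
    class = "melting_curve"
  )
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf(
    "UV melting curve%s: %d points, %.1f-%.1f C, Ct = %.3g M\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    length(x$temperature_C), min(x$temperature_C), max(x$temperature_C),
    x$total_strand_conc_M
  ))
  invisible(x)
}

#' Extract the melting temperature from a melting curve
#'
#' `method = "derivative"` (default) smooths the trace with a cubic smoothing
#' spline (smoothing parameter by generalized cross-validation) and returns
#' the temperature of the maximum first derivative, the inflection point of
#' the sigmoid. `method = "two_state_fit"` fits the full dual-baseline
#' two-state model `A(T) = alpha(T) (m_ds T + b_ds) + (1 - alpha(T)) (m_ss T +
#' b_ss)` by nonlinear least squares, with alpha parameterized by (Tm, dH) at
#' the curve's Ct, and returns the fitted Tm.
#'
#' A curve with no interior derivative maximum (flat or still melting at the
#' grid edge) raises a "no transition detected" error.
#'
#' @param curve a [melting_curve]
#' @param method `"derivative"` or `"two_state_fit"`
#' @return object of class `tm_estimate`: `tm_C`, `method`, `diagnostics`
#' @export
extract_tm <- function(curve, method = c("derivative", "two_state_fit")) {
  stopifnot(inherits(curve, "melting_curve"))
  method <- match.arg(method)
  if (diff(range(curve$absorbance_au)) < 1e-12) {
    stop("no transition detected: absorbance is constant")
  }
  est <- switch(method,
    derivative = tm_derivative(curve),
    two_state_fit = tm_two_state_fit(curve)
  )
  structure(
    list(tm_C = est$tm_C, method = method, diagnostics = est$diagnostics),
    class = "tm_estimate"
  )
}

#' @export
print.tm_estimate <- function(x, ...) {
  cat(sprintf("Tm = %.2f C (method: %s)\n", x$tm_C, x$method))
  invisible(x)
}

tm_derivative <- function(curve) {
  sp <- tryCatch(
    stats::smooth.spline(curve$temperature_C, curve$absorbance_au, cv = FALSE),
    error = function(e) stop("no transition detected: ", conditionMessage(e))
  )
  grid <- seq(min(curve$temperature_C), max(curve$temperature_C),
              length.out = 2001L)
  d1 <- stats::predict(sp, grid, deriv = 1L)$y
  i <- which.max(d1)
  if (i <= 2L || i >= length(grid) - 1L) {
    stop("no transition detected: derivative maximum at grid boundary")
  }
  # quadratic refinement around the discrete maximum
  num <- d1[i - 1L] - d1[i + 1L]
  den <- d1[i - 1L] - 2 * d1[i] + d1[i + 1L]
  shift <- if (abs(den) > 0) 0.5 * num / den else 0
  step <- grid[2L] - grid[1L]
  list(
    tm_C = grid[i] + shift * step,
    diagnostics = list(spar = sp$spar, df = sp$df, max_deriv = d1[i])
  )
}

tm_two_state_fit <- function(curve) {
  start_tm <- tm_derivative(curve)$tm_C
  Ct <- curve$total_strand_conc_M
  tC <- curve$temperature_C
  ab <- curve$absorbance_au
  n <- length(tC)
  lo <- ab[seq_len(max(3L, n %/% 5))]
  hi <- ab[seq.int(n - max(3L, n %/% 5) + 1L, n)]
  model <- function(tm_C, dH, m_ds, b_ds, m_ss, b_ss) {
    tm_K <- tm_C + KELVIN0
    dS <- dH * 1000 / tm_K - R_GAS * log(Ct / 4)
    a <- two_state_fraction(dH, dS, Ct, tC + KELVIN0)
    a * (m_ds * tC + b_ds) + (1 - a) * (m_ss * tC + b_ss)
  }
  fit <- minpack.lm::nlsLM(
    ab ~ model(tm_C, dH, m_ds, b_ds, m_ss, b_ss),
    start = list(tm_C = start_tm, dH = -80, m_ds = 0, b_ds = mean(lo),
                 m_ss = 0, b_ss = mean(hi)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  if (cf[["tm_C"]] <= min(tC) || cf[["tm_C"]] >= max(tC)) {
    stop("no transition detected: fitted Tm outside the temperature range")
  }
  list(
    tm_C = unname(cf[["tm_C"]]),
    diagnostics = list(coefficients = cf,
                       rss = sum(stats::residuals(fit)^2))
  )
}

#' Van't Hoff fit of the concentration dependence of Tm
#'
#' Ordinary least squares of `1/Tm` against `log10(Ct/4)` across a
#' concentration series. The slope gives the association enthalpy
#' `dH = R ln(10) / slope` and the intercept `dS = intercept * dH`
#' (cal units internally; dH reported in kcal/mol). dG at 37 C is derived
#' with [gibbs_free_energy].
#'
#' @param ct_M total single-strand concentrations, mol/L (>= 2 distinct)
#' @param tm_K melting temperatures, K, same length
#' @return object of class `vant_hoff_fit` with fields `dH_kcal_per_mol`,
#'   `dS_cal_per_mol_K`, `dG37_kcal_per_mol`, `slope`, `intercept`,
#'   `r_squared`, `n_points`
#' @examples
#' tm <- vapply(c(6, 12, 18, 24) * 1e-6,
#'              function(ct) predict_tm(-118.8, -350.9, ct)$tm_K, 0)
#' fit <- vant_hoff_fit(c(6, 12, 18, 24) * 1e-6, tm)
#' coef(fit)
#' @export
vant_hoff_fit <- function(ct_M, tm_K) {
  stopifnot(is.numeric(ct_M), is.numeric(tm_K))
  if (length(ct_M) != length(tm_K)) stop("ct_M and tm_K lengths differ")
  if (length(ct_M) < 2L) stop("need >= 2 (Ct, Tm) pairs")
  if (any(ct_M <= 0) || any(tm_K <= 0)) stop("Ct and Tm must be positive")
  if (length(unique(ct_M)) < 2L) {
    stop("singular design: need >= 2 distinct concentrations")
  }
  x <- log10(ct_M / 4)
  y <- 1 / tm_K
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope == 0) stop("degenerate regression slope")
  dH_cal <- R_GAS * log(10) / slope
  dS <- intercept * dH_cal
  dH <- dH_cal / 1000
  structure(
    list(
      dH_kcal_per_mol = dH,
      dS_cal_per_mol_K = dS,
      dG37_kcal_per_mol = gibbs_free_energy(dH, dS, 310.15),
      slope = slope,
      intercept = intercept,
      r_squared = {
        rss <- sum(stats::residuals(fit)^2)
        tss <- sum((y - mean(y))^2)
        if (tss > 0) 1 - rss / tss else NA_real_
      },
      n_points = length(ct_M),
      data = data.frame(ct_M = ct_M, tm_K = tm_K)
    ),
    class = "vant_hoff_fit"
  )
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat("Van't Hoff fit of 1/Tm vs log10(Ct/4)\n")
  cat(sprintf("  dH  = %8.1f kcal/mol\n", x$dH_kcal_per_mol))
  cat(sprintf("  dS  = %8.1f cal/(mol K)\n", x$dS_cal_per_mol_K))
  cat(sprintf("  dG(37 C) = %5.1f kcal/mol\n", x$dG37_kcal_per_mol))
  cat(sprintf("  n = %d concentrations, R^2 = %.6f\n",
              x$n_points, x$r_squared))
  invisible(x)
}

#' @export
coef.vant_hoff_fit <- function(object, ...) {
  c(dH_kcal_per_mol = object$dH_kcal_per_mol,
    dS_cal_per_mol_K = object$dS_cal_per_mol_K,
    dG37_kcal_per_mol = object$dG37_kcal_per_mol)
}

#' Predict Tm at new concentrations from a van't Hoff fit
#'
#' @param object a [vant_hoff_fit]
#' @param ct_M concentrations, mol/L (default: the fitted ones)
#' @param ... unused
#' @return melting temperatures in K
#' @export
predict.vant_hoff_fit <- function(object, ct_M = object$data$ct_M, ...) {
  vapply(ct_M, function(ct) {
    predict_tm(object$dH_kcal_per_mol, object$dS_cal_per_mol_K, ct)$tm_K
  }, numeric(1L))
}

#' Read a melting-curve CSV
#'
#' Expects columns `temperature_C`, `absorbance`, `curve_id`, with per-curve
#' total strand concentrations supplied either in a `ct_M` column or as a
#' named vector. `ct_mode = "per-strand"` doubles the supplied values (the
#' convention where a series is quoted per strand and Ct sums both strands).
#'
#' @param path CSV path
#' @param ct_M optional named vector of concentrations per curve_id, mol/L
#' @param ct_mode `"total"` (values already total) or `"per-strand"`
#' @return list of [melting_curve]
#' @export
read_melting_curves <- function(path, ct_M = NULL,
                                ct_mode = c("total", "per-strand")) {
  ct_mode <- match.arg(ct_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature_C", "absorbance", "curve_id")
  if (!all(need %in% names(df))) {
    stop("melting-curve CSV must have columns: ",
         paste(need, collapse = ", "))
  }
  ids <- unique(df$curve_id)
  lapply(ids, function(id) {
    sub <- df[df$curve_id == id, , drop = FALSE]
    ct <- if (!is.null(ct_M)) {
      unname(ct_M[[as.character(id)]])
    } else if ("ct_M" %in% names(df)) {
      sub$ct_M[1L]
    } else {
      stop("no concentration for curve ", id,
           ": supply ct_M or a ct_M column")
    }
    if (ct_mode == "per-strand") ct <- 2 * ct
    melting_curve(sub$temperature_C, sub$absorbance, ct,
                  label = as.character(id))
  })
}
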