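## Michaelis-Menten fitting with parameter SDs, catalytic efficiency with
## ratio error propagation, and competitive-inhibition Ki from the
## apparent-Km secondary plot.

#' Bundle a kinetic dataset
#'
#' @param substrate_conc substrate concentrations, mM (>= 4 distinct
#'   levels; replicates allowed).
#' @param initial_velocity matched initial velocities.  By default these
#'   are already normalized by enzyme concentration (v/\[E\], 1/s) so the
#'   fitted Vmax is kcat directly; pass `enzyme_conc` to normalize raw
#'   velocities here.
#' @param enzyme_conc optional enzyme concentration in the same units as
#'   the raw velocities' numerator.
#' @return a `kinetic_dataset` data frame (columns S, v).
#' @export
kinetic_dataset <- function(substrate_conc, initial_velocity,
                            enzyme_conc = NULL) {
  S <- as.numeric(substrate_conc); v <- as.numeric(initial_velocity)
  if (length(S) != length(v))
    stop_plp("plpscreen_data_error", "S and v lengths differ")
  if (any(S < 0))
    stop_plp("plpscreen_data_error", "negative substrate concentration")
  if (length(unique(S)) < 4)
    stop_plp("plpscreen_data_error",
             "need at least 4 distinct substrate levels (have %d)",
             length(unique(S)))
  if (!is.null(enzyme_conc)) v <- v / enzyme_conc
  structure(data.frame(S = S, v = v),
            class = c("kinetic_dataset", "data.frame"))
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of `v = kcat * S / (Km + S)`.  Starting values
#' are the maximum observed velocity and the substrate level nearest
#' half-maximal velocity.  Parameter standard deviations come from the
#' covariance of the fit; the catalytic efficiency kcat/Km (Km converted
#' mM to M) carries the propagated ratio error.
#'
#' @param data a [kinetic_dataset()] (or data frame with S (mM) and
#'   v (1/s)).
#' @return `mm_fit` list: `kcat`, `Km` (mM), `sd_kcat`, `sd_Km`,
#'   `efficiency` (1/s/M), `sd_efficiency`, and the `fit` object.
#' @export
fit_michaelis_menten <- function(data) {
  S <- data$S; v <- data$v
  if (all(v == 0))
    stop_plp("plpscreen_data_error", "all velocities are zero")
  if (length(unique(S)) < 2)
    stop_plp("plpscreen_fit_error", "a single substrate level cannot be fit")
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(S[S > 0])
  start <- list(kcat = vmax0, Km = km0)
  df <- data.frame(S = S, v = v)
  fit <- tryCatch(
    stats::nls(v ~ kcat * S / (Km + S), data = df, start = start,
               control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                            minFactor = 1e-12,
                                            scaleOffset = 1)),
    error = function(e)
      tryCatch(minpack.lm::nlsLM(v ~ kcat * S / (Km + S), data = df,
                                 start = start,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 200)),
               error = function(e2)
                 stop_plp("plpscreen_fit_error",
                          "Michaelis-Menten fit failed: %s",
                          conditionMessage(e2))))
  co <- summary(fit)$coefficients
  kcat <- co["kcat", "Estimate"]; Km <- co["Km", "Estimate"]
  if (!is.finite(kcat) || !is.finite(Km) || kcat <= 0 || Km <= 0)
    stop_plp("plpscreen_fit_error",
             "fit converged to non-positive parameters (kcat=%.3g, Km=%.3g)",
             kcat, Km)
  sd_kcat <- co["kcat", "Std. Error"]; sd_Km <- co["Km", "Std. Error"]
  eff <- catalytic_efficiency(kcat, Km, sd_kcat, sd_Km)
  structure(list(kcat = kcat, Km = Km, sd_kcat = sd_kcat, sd_Km = sd_Km,
                 efficiency = eff$efficiency,
                 sd_efficiency = eff$sd, fit = fit), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("kcat = %.4g +/- %.2g 1/s;  Km = %.4g +/- %.2g mM\n",
              x$kcat, x$sd_kcat, x$Km, x$sd_Km))
  cat(sprintf("kcat/Km = %.4g +/- %.2g 1/s/M\n",
              x$efficiency, x$sd_efficiency))
  invisible(x)
}

#' Catalytic efficiency with propagated ratio error
#'
#' `efficiency = kcat / (Km * 1e-3)` (Km in mM converted to M), with the
#' standard ratio error
#' `sd = efficiency * sqrt((sd_kcat/kcat)^2 + (sd_Km/Km)^2)`.
#'
#' @param kcat turnover number, 1/s.
#' @param Km Michaelis constant, mM.
#' @param sd_kcat,sd_Km standard deviations of the fit parameters.
#' @return list with `efficiency` (1/s/M) and `sd`.
#' @export
catalytic_efficiency <- function(kcat, Km, sd_kcat = 0, sd_Km = 0) {
  if (!is.finite(kcat) || !is.finite(Km) || kcat <= 0 || Km <= 0)
    stop_plp("plpscreen_value_error", "kcat and Km must be positive")
  eff <- kcat / (Km * 1e-3)
  sd <- eff * sqrt((sd_kcat / kcat)^2 + (sd_Km / Km)^2)
  list(efficiency = eff, sd = sd)
}

#' Competitive-inhibition Ki from the apparent-Km secondary plot
#'
#' For competitive inhibition the apparent Km grows linearly with
#' inhibitor: `Km_app = Km0 * (1 + [I] / Ki)` at constant Vmax.  A
#' linear regression of apparent Km on `[I]` gives `Ki = Km0 / slope`.
#'
#' @param inhibitor_concs inhibitor concentrations, mM (>= 3 levels,
#'   including 0).
#' @param apparent_Km matched apparent Km values, mM.
#' @param Km0 uninhibited Km, mM; defaults to the fitted intercept.
#' @return list with `Ki` (mM), `slope`, `intercept`, and the `lm` fit.
#' @export
fit_competitive_ki <- function(inhibitor_concs, apparent_Km, Km0 = NULL) {
  I <- as.numeric(inhibitor_concs); K <- as.numeric(apparent_Km)
  if (length(I) != length(K) || length(I) < 3)
    stop_plp("plpscreen_data_error",
             "need >= 3 matched inhibitor levels")
  if (!any(I == 0))
    stop_plp("plpscreen_data_error", "series must include [I] = 0")
  fit <- stats::lm(K ~ I)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop_plp("plpscreen_model_mismatch_error",
             "apparent Km does not increase with inhibitor (slope %.3g); not competitive",
             slope)
  Km0 <- Km0 %||% intercept
  list(Ki = Km0 / slope, slope = slope, intercept = intercept, fit = fit)
}
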