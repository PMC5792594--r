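#' Fit Michaelis-Menten kinetics by nonlinear least squares
#'
#' Fits `v = Vmax * S / (Km + S)` with Levenberg-Marquardt
#' (minpack.lm), initialized from a Lineweaver-Burk double-reciprocal
#' linear fit; a few bounded restarts with perturbed starts are attempted
#' on non-convergence. `kcat = Vmax / enzyme_conc`; standard errors come
#' from the Jacobian at the optimum. Units: concentrations in uM, rates in
#' uM/s, so kcat is in 1/s.
#'
#' @param data a `kinetic_dataset` from [simulate_kinetics()], or a
#'   data.frame/list with `conc` (or `S_uM`) and `rate` (or
#'   `rate_uM_per_s`); needs >= 3 distinct substrate concentrations.
#' @param enzyme_conc enzyme concentration in uM; taken from the dataset
#'   when omitted.
#' @return object of class `kinetic_fit`: list with km, vmax, kcat, se_km,
#'   se_vmax, r2, n, km_at_bound flag.
#' @export
fit_michaelis_menten <- function(data, enzyme_conc = NULL) {
  S <- if (!is.null(data$conc)) data$conc else data$S_uM
  v <- if (!is.null(data$rate)) data$rate else data$rate_uM_per_s
  if (is.null(S) || is.null(v)) stop("data must provide conc/S_uM and rate/rate_uM_per_s")
  if (is.null(enzyme_conc)) enzyme_conc <- data$enzyme_conc
  if (is.null(enzyme_conc) || enzyme_conc <= 0) {
    stop("a positive enzyme_conc is required to report kcat")
  }
  if (length(unique(S)) < 3) {
    stop("need at least 3 distinct substrate concentrations")
  }
  if (any(S <= 0)) stop("substrate concentrations must be positive")

  # Lineweaver-Burk initialization on the strictly positive rates
  pos <- v > 0
  start <- NULL
  if (sum(pos) >= 2) {
    lb <- stats::lm(I(1 / v[pos]) ~ I(1 / S[pos]))
    vmax0 <- 1 / coef(lb)[[1]]
    km0 <- coef(lb)[[2]] * vmax0
    if (is.finite(vmax0) && is.finite(km0) && vmax0 > 0 && km0 > 0) {
      start <- list(Vmax = vmax0, Km = km0)
    }
  }
  if (is.null(start)) start <- list(Vmax = 1.2 * max(v), Km = stats::median(S))

  df <- data.frame(S = S, v = v)
  fit <- NULL
  tries <- list(c(1, 1), c(0.5, 2), c(2, 0.5), c(1, 0.1), c(1, 10))
  for (f in tries) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                        start = list(Vmax = start$Vmax * f[1],
                                     Km = start$Km * f[2]),
                        lower = c(Vmax = 1e-12, Km = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("Michaelis-Menten fit did not converge after bounded restarts ",
         "(n = ", length(S), ", rate range = [", min(v), ", ", max(v), "])")
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((v - mean(v))^2)
  km_at_bound <- est[["Km"]] <= 1e-10 || est[["Km"]] >= 1e6 * max(S)
  if (km_at_bound) warning("Km estimate is at a bound; fit may be unreliable")
  structure(list(km = est[["Km"]], vmax = est[["Vmax"]],
                 kcat = est[["Vmax"]] / enzyme_conc,
                 se_km = unname(se[["Km"]]), se_vmax = unname(se[["Vmax"]]),
                 r2 = r2, n = length(S), enzyme_conc = enzyme_conc,
                 km_at_bound = km_at_bound),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d): Km = %.4g uM (SE %.2g), ",
              x$n, x$km, x$se_km))
  cat(sprintf("Vmax = %.4g uM/s (SE %.2g), kcat = %.4g 1/s, R2 = %.4f\n",
              x$vmax, x$se_vmax, x$kcat, x$r2))
  invisible(x)
}

# round half away from zero, for display figures like the 1.68-fold change
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fermentation yield and partition summary
#'
#' Pure accounting over reported quantities: total titer as the sum of
#' component titers (also reported to nearest-hundred precision), specific
#' yield (mg per g dry cell weight) when a DCW is given, fold change over a
#' baseline specific yield (displayed rounded half-up to 2 decimals; the
#' raw ratio is kept), and the intracellular/extracellular split.
#'
#' @param component_titers named numeric vector of product titers, mg/L
#'   (non-negative).
#' @param dcw dry cell weight, g/L (optional).
#' @param specific_yield specific yield in mg/gDCW; computed as
#'   `total_titer / dcw` when omitted and `dcw` is given.
#' @param baseline_specific_yield baseline for the fold change (mg/gDCW).
#' @param extracellular_fraction percentage of product secreted, in
#'   `[0, 100]` (optional).
#' @return object of class `yield_summary`.
#' @export
yield_metrics <- function(component_titers = NULL, dcw = NULL,
                          specific_yield = NULL,
                          baseline_specific_yield = NULL,
                          extracellular_fraction = NULL) {
  out <- list()
  if (!is.null(component_titers)) {
    if (any(component_titers < 0)) stop("titers must be non-negative")
    out$component_titers <- component_titers
    out$total_titer <- sum(component_titers)
    out$total_titer_nearest_hundred <- round_half_up(out$total_titer / 100) * 100
  }
  if (is.null(specific_yield) && !is.null(dcw) && !is.null(out$total_titer)) {
    if (dcw <= 0) stop("dcw must be positive")
    specific_yield <- out$total_titer / dcw
  }
  out$specific_yield <- specific_yield
  if (!is.null(baseline_specific_yield)) {
    if (baseline_specific_yield == 0) stop("baseline specific yield is zero")
    if (is.null(specific_yield)) stop("specific_yield needed for fold change")
    out$fold_change_raw <- specific_yield / baseline_specific_yield
    out$fold_change <- round_half_up(out$fold_change_raw, 2)
  }
  if (!is.null(extracellular_fraction)) {
    if (extracellular_fraction < 0 || extracellular_fraction > 100) {
      stop("extracellular_fraction must be in [0, 100]")
    }
    out$fraction_extracellular <- extracellular_fraction
    out$fraction_intracellular <- 100 - extracellular_fraction
    stopifnot(abs(out$fraction_intracellular + out$fraction_extracellular - 100)
              <= 1e-9)
  }
  structure(out, class = "yield_summary")
}

#' @export
print.yield_summary <- function(x, ...) {
  if (!is.null(x$total_titer)) {
    cat(sprintf("Total titer: %.4g mg/L (~%g mg/L)\n", x$total_titer,
                x$total_titer_nearest_hundred))
  }
  if (!is.null(x$specific_yield)) {
    cat(sprintf("Specific yield: %.4g mg/gDCW\n", x$specific_yield))
  }
  if (!is.null(x$fold_change)) {
    cat(sprintf("Fold change over baseline: %.2f\n", x$fold_change))
  }
  if (!is.null(x$fraction_intracellular)) {
    cat(sprintf("Intracellular %.1f%% / extracellular %.1f%%\n",
                x$fraction_intracellular, x$fraction_extracellular))
  }
  invisible(x)
}
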