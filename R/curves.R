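# DSF Boltzmann melts, steady-state SPR affinity, logistic IC50 fits, and
# the affinity comparison table.

#' Generic fitted-curve container
#'
#' @param model_name Model label.
#' @param params Named numeric estimates.
#' @param se Named standard errors (same names as `params`).
#' @param residual_norm Euclidean norm of residuals at the optimum.
#' @param converged Logical; when `FALSE` the parameters are unreliable.
#' @param meta Optional list of fit metadata.
#' @return A `curve_fit_result`.
#' @export
curve_fit_result <- function(model_name, params, se, residual_norm,
                             converged, meta = list()) {
  se <- se[names(params)]
  if (any(!is.na(se) & se < 0)) stop("standard errors must be >= 0",
                                     call. = FALSE)
  structure(list(model_name = model_name, params = params, se = se,
                 residual_norm = residual_norm, converged = converged,
                 meta = meta),
            class = "curve_fit_result")
}

#' @export
print.curve_fit_result <- function(x, ...) {
  cat(sprintf("<curve_fit_result> %s (%s)\n", x$model_name,
              if (x$converged) "converged" else "NOT converged"))
  for (nm in names(x$params)) {
    cat(sprintf("  %-10s %.6g +/- %.3g\n", nm, x$params[[nm]], x$se[[nm]]))
  }
  invisible(x)
}

nls_fit_result <- function(fit, model_name, meta = list()) {
  s <- summary(fit)
  est <- stats::coef(fit)
  se <- s$coefficients[names(est), "Std. Error"]
  curve_fit_result(model_name = model_name, params = est, se = se,
                   residual_norm = sqrt(sum(stats::resid(fit)^2)),
                   converged = fit$convInfo$isConv, meta = meta)
}

# ---- DSF ------------------------------------------------------------------

#' Boltzmann sigmoid for thermal melts
#'
#' `F(T) = F_min + (F_max - F_min) / (1 + exp((Tm - T)/s))`
#'
#' @param temperature_c Temperature, Celsius.
#' @param f_min,f_max Fluorescence plateaus.
#' @param tm Melting temperature (inflection point), Celsius.
#' @param slope Transition width, Celsius.
#' @return Fluorescence values.
#' @export
boltzmann_melt <- function(temperature_c, f_min, f_max, tm, slope) {
  f_min + (f_max - f_min) / (1 + exp((tm - temperature_c) / slope))
}

#' Fit a Boltzmann melt to a DSF curve
#'
#' @param curve Data frame with columns `temperature_c` (strictly
#'   increasing) and `fluorescence`.
#' @param window Optional `c(lo, hi)` temperature window (Celsius) to
#'   restrict the fit; default uses the full sweep up to the fluorescence
#'   maximum (post-peak quench is not part of the two-state transition).
#' @return [curve_fit_result()] with `tm`, `slope`, `f_min`, `f_max`.
#' @export
fit_boltzmann_melt <- function(curve, window = NULL) {
  stopifnot(all(c("temperature_c", "fluorescence") %in% names(curve)))
  tt <- curve$temperature_c
  if (any(diff(tt) <= 0)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  ff <- curve$fluorescence
  peak <- which.max(ff)
  keep <- seq_len(max(peak, 4L))
  if (!is.null(window)) keep <- which(tt >= window[1L] & tt <= window[2L])
  tt <- tt[keep]; ff <- ff[keep]
  if (max(ff) - min(ff) <= .Machine$double.eps * 100 * max(abs(ff), 1)) {
    return(curve_fit_result("boltzmann_melt",
                            params = c(tm = NA_real_, slope = NA_real_,
                                       f_min = NA_real_, f_max = NA_real_),
                            se = rep(NA_real_, 4),
                            residual_norm = NA_real_, converged = FALSE,
                            meta = list(reason = "flat curve")))
  }
  start <- list(f_min = stats::quantile(ff, 0.02, names = FALSE),
                f_max = stats::quantile(ff, 0.98, names = FALSE),
                tm = tt[which.min(abs(ff - (min(ff) + max(ff)) / 2))],
                slope = diff(range(tt)) / 20)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ff ~ boltzmann_melt(tt, f_min, f_max, tm, slope),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(curve_fit_result("boltzmann_melt",
                            params = c(tm = NA_real_, slope = NA_real_,
                                       f_min = NA_real_, f_max = NA_real_),
                            se = rep(NA_real_, 4),
                            residual_norm = NA_real_, converged = FALSE,
                            meta = list(reason = "fit did not converge")))
  }
  res <- nls_fit_result(fit, "boltzmann_melt",
                        meta = list(n_points = length(tt)))
  res$params <- res$params[c("tm", "slope", "f_min", "f_max")]
  res$se <- res$se[c("tm", "slope", "f_min", "f_max")]
  res
}

#' Melting-temperature shift
#'
#' Signed shift `Tm(with ligand) - Tm(apo)`, Celsius; negative shifts are
#' reported as such (destabilization).
#'
#' @param tm_with_ligand,tm_apo Melting temperatures, Celsius.
#' @return Numeric shift, Celsius.
#' @export
delta_tm <- function(tm_with_ligand, tm_apo) tm_with_ligand - tm_apo

# ---- SPR ------------------------------------------------------------------

#' Fit steady-state SPR responses
#'
#' Fits the hyperbolic saturation model `R(C) = R_max C / (Kd + C)` by
#' least squares. Concentration units are preserved in the fitted Kd.
#'
#' @param responses Data frame with columns `concentration` and `response`;
#'   at least 5 concentrations including a zero (blank) point.
#' @return [curve_fit_result()] with `kd` and `r_max`; a bounded-Kd
#'   warning is raised when no saturation is reached within the probed
#'   range (fitted Kd above the maximal concentration), and
#'   `meta$kd_bound` records the bound.
#' @export
fit_spr_affinity <- function(responses) {
  stopifnot(all(c("concentration", "response") %in% names(responses)))
  conc <- responses$concentration
  if (length(unique(conc)) < 5L || !any(conc == 0)) {
    stop("need >= 5 concentrations including a zero blank", call. = FALSE)
  }
  resp <- responses$response
  start <- list(r_max = max(resp),
                kd = stats::median(conc[conc > 0]))
  fit <- minpack.lm::nlsLM(resp ~ r_max * conc / (kd + conc), start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  out <- nls_fit_result(fit, "spr_steady_state")
  out$params <- out$params[c("kd", "r_max")]
  out$se <- out$se[c("kd", "r_max")]
  kd_bound <- NA_real_
  if (out$params[["kd"]] > max(conc)) {
    kd_bound <- max(conc)
    warning(sprintf(
      "no saturation within the probed range; Kd is a lower bound > %.3g",
      kd_bound), call. = FALSE)
  }
  out$meta$kd_bound <- kd_bound
  out
}

# ---- IC50 -----------------------------------------------------------------

#' Logistic inhibition model on log10 concentration
#'
#' `Y = 1 / (1 + 10^((logIC50 - x) * n_hill))` with
#' `x = log10(concentration)`; at `x = logIC50`, `Y = 0.5` for any slope.
#'
#' @param log10_conc log10 of inhibitor concentration.
#' @param log_ic50 log10 of the IC50 (same units as concentration).
#' @param n_hill Slope factor.
#' @return Normalized activity values.
#' @export
ic50_logistic <- function(log10_conc, log_ic50, n_hill) {
  1 / (1 + 10^((log_ic50 - log10_conc) * n_hill))
}

#' Fit the logistic IC50 model to a dose-response series
#'
#' The independent variable of the logistic is log10 concentration (the
#' conventional reading of the dose term in the fitted equation, which is
#' otherwise dimensionally inconsistent); zero-concentration points cannot
#' enter the log transform and are dropped with a note in `meta`.
#'
#' @param activity Data frame with columns `concentration` (>= 0) and
#'   `activity` (normalized, roughly in `[0, 1]`).
#' @return [curve_fit_result()] with `ic50` (concentration units) and
#'   `n_hill`; `meta$log_ic50_se` carries the SE on the log scale.
#' @export
fit_ic50 <- function(activity) {
  stopifnot(all(c("concentration", "activity") %in% names(activity)))
  n_zero <- sum(activity$concentration == 0)
  act <- activity[activity$concentration > 0, , drop = FALSE]
  if (nrow(act) < 4L) {
    stop("need at least 4 positive-concentration points", call. = FALSE)
  }
  x <- log10(act$concentration)
  y <- act$activity
  start <- list(log_ic50 = x[which.min(abs(y - 0.5))], n_hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ ic50_logistic(x, log_ic50, n_hill), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(curve_fit_result("ic50_logistic",
                            params = c(ic50 = NA_real_, n_hill = NA_real_),
                            se = rep(NA_real_, 2), residual_norm = NA_real_,
                            converged = FALSE,
                            meta = list(reason = "non-sigmoidal data")))
  }
  est <- stats::coef(fit)
  s <- summary(fit)$coefficients
  ic50 <- 10^est[["log_ic50"]]
  se_log <- s["log_ic50", "Std. Error"]
  curve_fit_result(
    "ic50_logistic",
    params = c(ic50 = ic50, n_hill = est[["n_hill"]]),
    se = c(ic50 = ic50 * log(10) * se_log,          # delta method
           n_hill = s["n_hill", "Std. Error"]),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    converged = fit$convInfo$isConv,
    meta = list(dose_scale = "log10 concentration",
                n_zero_dropped = n_zero, log_ic50_se = se_log))
}

# ---- Affinity comparison table --------------------------------------------

#' Build an inhibitor-by-state affinity table
#'
#' Collects labelled affinity fits into a matrix-shaped table (one row per
#' inhibitor, one Kd column per state) with fold-difference columns for
#' requested state pairs. Bounded entries (fits whose `meta$kd_bound` is
#' set) render as `"> limit"` and are excluded from fold arithmetic.
#'
#' @param fits Data frame with columns `inhibitor`, `state`, `kd`, `se`,
#'   and optionally `kd_bound` (`NA` unless the fit is a lower bound).
#'   Typically assembled from [fit_one_site()] or [fit_spr_affinity()]
#'   results.
#' @param fold_pairs Named list of `c(numerator_state, denominator_state)`
#'   pairs; each yields a fold column `fold_<name>`.
#' @param digits Significant digits used when rendering `kd_text`.
#' @return Data frame, one row per inhibitor, with numeric `kd_<state>`
#'   columns, rendered `kd_text_<state>` columns, and fold columns.
#' @export
build_affinity_table <- function(fits, fold_pairs = list(), digits = 3) {
  req <- c("inhibitor", "state", "kd", "se")
  stopifnot(all(req %in% names(fits)))
  if (nrow(fits) == 0L) {
    return(data.frame(inhibitor = character(0)))
  }
  if (!"kd_bound" %in% names(fits)) fits$kd_bound <- NA_real_
  key <- paste(fits$inhibitor, fits$state, sep = "\r")
  if (anyDuplicated(key)) {
    stop(errorCondition(
      "duplicate (inhibitor, state) labels in fits",
      class = c("cdkstates_ambiguous_label", "error", "condition")))
  }
  inhibitors <- unique(fits$inhibitor)
  states <- unique(fits$state)
  out <- data.frame(inhibitor = inhibitors)
  get_row <- function(inh, st) fits[fits$inhibitor == inh & fits$state == st,
                                    , drop = FALSE]
  for (st in states) {
    kd_col <- rep(NA_real_, length(inhibitors))
    txt_col <- rep(NA_character_, length(inhibitors))
    for (i in seq_along(inhibitors)) {
      r <- get_row(inhibitors[i], st)
      if (nrow(r) == 1L) {
        if (!is.na(r$kd_bound)) {
          txt_col[i] <- sprintf("> %s", format(signif(r$kd_bound, digits),
                                               big.mark = ","))
        } else {
          kd_col[i] <- r$kd
          txt_col[i] <- sprintf("%s +/- %s", signif(r$kd, digits),
                                signif(r$se, 2))
        }
      }
    }
    out[[paste0("kd_", st)]] <- kd_col
    out[[paste0("kd_text_", st)]] <- txt_col
  }
  for (nm in names(fold_pairs)) {
    pr <- fold_pairs[[nm]]
    num <- out[[paste0("kd_", pr[1L])]]
    den <- out[[paste0("kd_", pr[2L])]]
    out[[paste0("fold_", nm)]] <- num / den
  }
  out
}
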