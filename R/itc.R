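# One-set-of-sites ITC: forward simulation with perfusion-displacement
# bookkeeping, nonlinear least-squares fit, thermodynamic signatures,
# fold-selectivity arithmetic.

#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.9872e-3

#' ITC injection schedule
#'
#' Defaults mirror the study protocol: 100 uM titrant injected into a
#' 200 uL cell at 10 uM titrand, one 0.5 uL priming injection followed by
#' 19 x 2 uL injections, at 30 C (303.15 K).
#'
#' @param cell_volume_ul Cell volume in microlitres.
#' @param cell_conc_m Titrand (macromolecule) concentration, molar.
#' @param syringe_conc_m Titrant (ligand) concentration, molar.
#' @param injection_volumes_ul Ordered injection volumes, microlitres.
#' @param temperature_k Temperature, Kelvin.
#' @return An `injection_schedule`.
#' @export
injection_schedule <- function(cell_volume_ul = 200,
                               cell_conc_m = 10e-6,
                               syringe_conc_m = 100e-6,
                               injection_volumes_ul = c(0.5, rep(2, 19)),
                               temperature_k = 303.15) {
  stopifnot(cell_volume_ul > 0, cell_conc_m > 0, syringe_conc_m > 0,
            length(injection_volumes_ul) > 0,
            all(injection_volumes_ul > 0), temperature_k > 0)
  structure(
    list(cell_volume_ul = cell_volume_ul, cell_conc_m = cell_conc_m,
         syringe_conc_m = syringe_conc_m,
         injection_volumes_ul = injection_volumes_ul,
         temperature_k = temperature_k),
    class = "injection_schedule"
  )
}

#' One-set-of-sites binding parameters
#'
#' @param kd Dissociation constant, molar.
#' @param dh Binding enthalpy, kcal per mol of injectant.
#' @param n Stoichiometry (sites per titrand molecule).
#' @param baseline Dilution-heat offset, microcalories per injection.
#' @return A `one_site_params`.
#' @export
one_site_params <- function(kd, dh, n = 1, baseline = 0) {
  stopifnot(kd > 0, n > 0)
  structure(list(kd = kd, dh = dh, n = n, baseline = baseline),
            class = "one_site_params")
}

#' Simulate a one-set-of-sites ITC experiment
#'
#' Per injection, the cell contents are first diluted by the
#' perfusion-displacement rule (each injection of volume dV expels the
#' fraction dV/V0 of the cell contents at their pre-mixing composition),
#' the titrant is added, the single-site equilibrium is solved from the
#' binding quadratic, and the differential heat is
#' dH x (change in moles of complex in the cell) + baseline.
#'
#' @param params A [one_site_params()].
#' @param schedule An [injection_schedule()].
#' @return `itc_isotherm`: `schedule`, `heats` (ucal per injection),
#'   `molar_ratio` (cumulative titrant/titrand in cell), plus a `details`
#'   data frame (per-injection total/bound/free concentrations) used by
#'   mass-balance checks.
#' @export
simulate_itc <- function(params, schedule) {
  stopifnot(inherits(params, "one_site_params"),
            inherits(schedule, "injection_schedule"))
  v0 <- schedule$cell_volume_ul
  mt <- schedule$cell_conc_m      # titrand (macromolecule) in cell
  xt <- 0                         # titrant in cell
  pl_prev <- 0                    # complex concentration before injection
  n_inj <- length(schedule$injection_volumes_ul)
  heats <- numeric(n_inj); ratio <- numeric(n_inj)
  det_mt <- numeric(n_inj); det_xt <- numeric(n_inj); det_pl <- numeric(n_inj)
  v0_l <- v0 * 1e-6
  for (i in seq_len(n_inj)) {
    dv <- schedule$injection_volumes_ul[i]
    f <- dv / v0
    mt_new <- mt * (1 - f)
    xt_new <- xt * (1 - f) + schedule$syringe_conc_m * f
    pl <- one_site_bound(params$kd, params$n, mt_new, xt_new)
    # moles of complex expelled carry the pre-mixing composition
    dmoles <- (pl - pl_prev * (1 - f)) * v0_l
    heats[i] <- params$dh * 1e9 * dmoles + params$baseline
    mt <- mt_new; xt <- xt_new; pl_prev <- pl
    ratio[i] <- xt / mt
    det_mt[i] <- mt; det_xt[i] <- xt; det_pl[i] <- pl
  }
  structure(
    list(schedule = schedule, heats = heats, molar_ratio = ratio,
         details = data.frame(total_titrand = det_mt, total_titrant = det_xt,
                              bound = det_pl)),
    class = "itc_isotherm"
  )
}

# Complex concentration from the single-site quadratic:
# PL^2 - PL (n Mt + Xt + Kd) + n Mt Xt = 0, smaller root.
one_site_bound <- function(kd, n, mt, xt) {
  b <- n * mt + xt + kd
  disc <- b^2 - 4 * n * mt * xt
  (b - sqrt(max(disc, 0))) / 2
}

#' @export
print.itc_isotherm <- function(x, ...) {
  cat(sprintf(
    "<itc_isotherm> %d injections, molar ratio %.2f-%.2f, heats %.2f..%.2f ucal\n",
    length(x$heats), min(x$molar_ratio), max(x$molar_ratio),
    x$heats[1L], x$heats[length(x$heats)]))
  invisible(x)
}

#' Fit the one-set-of-sites model to an ITC isotherm
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [simulate_itc()]
#' against the observed injection heats over (Kd, dH, n, baseline). The
#' priming injection (the first, when its volume is smaller than the
#' median injection volume) is excluded from the residuals, as is
#' universal ITC practice. Kd is fitted on a log scale to keep it
#' positive. When the isotherm carries no Kd information (c-value
#' n.[cell]/Kd below 1, or the fitted Kd beyond half the maximal titrant
#' concentration probed) a bounded-affinity warning is raised and the
#' result flagged, mirroring the "> limit" convention of affinity tables.
#'
#' @param isotherm An `itc_isotherm`.
#' @param init Optional [one_site_params()] initialization. Defaults:
#'   n = 1, dH = sign of the largest-magnitude heat x 5 kcal/mol, Kd = the
#'   titrant concentration at half-saturation, baseline 0.
#' @param fix_n Fix stoichiometry at its initial value instead of
#'   floating it.
#' @param fit_baseline Float the dilution-heat offset (default TRUE).
#' @return A [curve_fit_result()] with parameters `kd` (molar), `dh`
#'   (kcal/mol), `n`, `baseline` (ucal), and metadata `kd_bound`
#'   (molar lower bound, `NA` unless bounded) and `c_value`.
#' @export
fit_one_site <- function(isotherm, init = NULL, fix_n = FALSE,
                         fit_baseline = TRUE) {
  stopifnot(inherits(isotherm, "itc_isotherm"))
  sch <- isotherm$schedule
  vols <- sch$injection_volumes_ul
  use <- rep(TRUE, length(vols))
  if (length(vols) > 1L && vols[1L] < stats::median(vols)) use[1L] <- FALSE
  if (sum(use) < 6L) {
    stop("need at least 6 usable injections to fit", call. = FALSE)
  }
  obs <- isotherm$heats
  if (is.null(init)) {
    dh0 <- sign(obs[use][which.max(abs(obs[use]))]) * 5
    xt_half <- isotherm$details$total_titrant[use][
      which.min(abs(cumsum(obs[use]) - sum(obs[use]) / 2))]
    kd0 <- max(xt_half - sch$cell_conc_m, sch$cell_conc_m / 20)
    init <- one_site_params(kd = kd0, dh = dh0, n = 1, baseline = 0)
  }
  par0 <- c(log_kd = log(init$kd), dh = init$dh)
  if (!fix_n) par0 <- c(par0, n = init$n)
  if (fit_baseline) par0 <- c(par0, baseline = init$baseline)
  resid_fun <- function(p) {
    pars <- one_site_params(
      kd = exp(p[["log_kd"]]), dh = p[["dh"]],
      n = if (fix_n) init$n else max(p[["n"]], 1e-6),
      baseline = if (fit_baseline) p[["baseline"]] else init$baseline)
    simulate_itc(pars, sch)$heats[use] - obs[use]
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  p <- fit$par
  est <- c(kd = exp(p[["log_kd"]]), dh = p[["dh"]],
           n = if (fix_n) init$n else p[["n"]],
           baseline = if (fit_baseline) p[["baseline"]] else init$baseline)
  se_raw <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    rep(NA_real_, length(p))
  })
  names(se_raw) <- names(p)
  se <- c(kd = unname(se_raw["log_kd"] * est[["kd"]]),  # delta method
          dh = unname(se_raw["dh"]),
          n = if (fix_n) 0 else unname(se_raw["n"]),
          baseline = if (fit_baseline) unname(se_raw["baseline"]) else 0)
  converged <- fit$info %in% 1:4
  c_value <- est[["n"]] * sch$cell_conc_m / est[["kd"]]
  max_xt <- max(isotherm$details$total_titrant)
  kd_bound <- NA_real_
  if (c_value < 1 || est[["kd"]] > max_xt / 2) {
    kd_bound <- max_xt / 2
    warning(sprintf(
      "Kd is not determined by this isotherm (c-value %.2g); report as > %.3g M",
      c_value, kd_bound), call. = FALSE)
  }
  curve_fit_result(
    model_name = "itc_one_set_of_sites",
    params = est, se = se,
    residual_norm = sqrt(sum(fit$fvec^2)),
    converged = converged,
    meta = list(kd_bound = kd_bound, c_value = c_value,
                n_injections_used = sum(use), fix_n = fix_n))
}

#' Thermodynamic signature of binding
#'
#' Decomposes the binding free energy at temperature T:
#' dG = R T ln(Kd) (kcal/mol, negative for sub-molar Kd), and
#' -T dS = dG - dH, so dG = dH + (-T dS) by construction.
#'
#' @param kd Dissociation constant, molar.
#' @param dh Binding enthalpy, kcal/mol.
#' @param temperature_k Temperature, Kelvin (default 303.15).
#' @return `thermo_signature` with `dg`, `dh`, `minus_tds`, `temperature_k`.
#' @export
thermo_signature <- function(kd, dh, temperature_k = 303.15) {
  stopifnot(kd > 0, temperature_k > 0)
  dg <- R_KCAL * temperature_k * log(kd)
  structure(list(dg = dg, dh = dh, minus_tds = dg - dh,
                 temperature_k = temperature_k),
            class = "thermo_signature")
}

#' @export
print.thermo_signature <- function(x, ...) {
  cat(sprintf(
    "<thermo_signature> dG = %.2f, dH = %.2f, -TdS = %.2f kcal/mol at %.2f K\n",
    x$dg, x$dh, x$minus_tds, x$temperature_k))
  invisible(x)
}

#' Fold selectivity between two affinities
#'
#' @param kd_a,kd_b Dissociation constants (same units).
#' @param rounding `"none"`, `"nearest_ten"`, or `"one_sig_fig"`.
#' @return `kd_a / kd_b`, optionally rounded.
#' @export
selectivity_ratio <- function(kd_a, kd_b,
                              rounding = c("none", "nearest_ten",
                                           "one_sig_fig")) {
  rounding <- match.arg(rounding)
  stopifnot(kd_a > 0, kd_b > 0)
  fold <- kd_a / kd_b
  switch(rounding,
    none = fold,
    nearest_ten = round(fold / 10) * 10,
    one_sig_fig = signif(fold, 1))
}
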