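# DSF / SPR / IC50 fitters and the affinity table.

test_that("Boltzmann melt fit recovers a noiseless Tm to high precision", {
  curve <- gen_melt(tm = 51.5, slope = 1.8, f_min = 5, f_max = 120)
  fit <- fit_boltzmann_melt(curve)
  expect_true(fit$converged)
  expect_equal(fit$params[["tm"]], 51.5, tolerance = 0.01 / 51.5)
  expect_equal(fit$params[["slope"]], 1.8, tolerance = 1e-3)
})

test_that("a temperature shift is recovered as the fitted delta Tm", {
  apo <- gen_melt(tm = 51.5, noise_sd = 0.2, seed = 4)
  holo <- apo
  holo$temperature_c <- holo$temperature_c + 8.9
  tm_apo <- fit_boltzmann_melt(apo)$params[["tm"]]
  tm_holo <- fit_boltzmann_melt(holo)$params[["tm"]]
  expect_equal(delta_tm(tm_holo, tm_apo), 8.9, tolerance = 0.05 / 8.9)
})

test_that("delta Tm is a signed subtraction", {
  expect_equal(delta_tm(60.4, 51.5), 8.9)
  expect_equal(delta_tm(46.3, 48.9), -2.6)
  expect_equal(delta_tm(50, 50), 0)
})

test_that("non-increasing temperatures and flat curves are rejected", {
  curve <- gen_melt()
  rev_curve <- curve[nrow(curve):1, ]
  expect_error(fit_boltzmann_melt(rev_curve), "strictly increasing")
  flat <- data.frame(temperature_c = 25:95, fluorescence = 7)
  fit <- fit_boltzmann_melt(flat)
  expect_false(fit$converged)
})

test_that("SPR affinity fit recovers noiseless parameters", {
  dat <- gen_spr(kd = 43, r_max = 100)
  fit <- fit_spr_affinity(dat)
  expect_true(fit$converged)
  expect_equal(fit$params[["kd"]], 43, tolerance = 1e-3)
  expect_equal(fit$params[["r_max"]], 100, tolerance = 1e-3)
  # half-saturation identity on the fitted curve
  kd <- fit$params[["kd"]]; rmax <- fit$params[["r_max"]]
  expect_equal(rmax * kd / (kd + kd), rmax / 2)
})

test_that("a coarse grid search brackets the SPR least-squares optimum", {
  dat <- gen_spr(kd = 43, r_max = 100, noise_sd = 2, seed = 6)
  fit <- fit_spr_affinity(dat)
  sse <- function(kd, rmax) {
    sum((dat$response - rmax * dat$concentration /
           (kd + dat$concentration))^2)
  }
  sse_fit <- sse(fit$params[["kd"]], fit$params[["r_max"]])
  grid <- expand.grid(kd = seq(10, 100, by = 2),
                      rmax = seq(80, 120, by = 1))
  sse_grid <- mapply(sse, grid$kd, grid$rmax)
  expect_lte(sse_fit, min(sse_grid) + 1e-9)
})

test_that("SPR fits need a proper dose ladder and warn without saturation", {
  expect_error(fit_spr_affinity(data.frame(concentration = c(1, 2, 3),
                                           response = c(1, 2, 3))),
               ">= 5")
  shallow <- gen_spr(kd = 1e6, r_max = 100,
                     concentration = spr_dilution_series())
  expect_warning(fit <- fit_spr_affinity(shallow), "lower bound")
  expect_false(is.na(fit$meta$kd_bound))
})

test_that("the logistic passes through 0.5 exactly at the IC50", {
  expect_equal(ic50_logistic(log10(100), log10(100), 1), 0.5)
  expect_equal(ic50_logistic(log10(100), log10(100), -2.7), 0.5)
  dat <- gen_ic50(ic50 = 100, n_hill = 1)
  fit <- fit_ic50(dat)
  ic50 <- fit$params[["ic50"]]
  expect_equal(ic50_logistic(log10(ic50), log10(ic50),
                             fit$params[["n_hill"]]), 0.5)
})

test_that("IC50 fit recovers noiseless parameters", {
  fit <- fit_ic50(gen_ic50(ic50 = 100, n_hill = 1))
  expect_true(fit$converged)
  expect_equal(fit$params[["ic50"]], 100, tolerance = 1e-3)
  expect_equal(fit$params[["n_hill"]], 1, tolerance = 1e-3)
  expect_equal(fit$meta$dose_scale, "log10 concentration")
})

test_that("IC50 is recovered within 15% at 2% noise over 50 replicates", {
  rel_err <- vapply(1:50, function(s) {
    dat <- gen_ic50(ic50 = 100, n_hill = 1, noise_sd = 0.02,
                    seed = 2000 + s)
    fit <- fit_ic50(dat)
    abs(fit$params[["ic50"]] / 100 - 1)
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.15)
})

test_that("affinity tables render folds and bounded entries", {
  fits <- data.frame(
    inhibitor = c("Dinaciclib", "Dinaciclib", "SU9516", "SU9516"),
    state = c("CDK1", "CDK1B", "CDK1", "CDK1B"),
    kd = c(955, 32, NA, 234),
    se = c(246, 2, NA, 20),
    kd_bound = c(NA, NA, 20000, NA))
  tab <- build_affinity_table(
    fits, fold_pairs = list(cdk1_free_vs_bound = c("CDK1", "CDK1B")))
  din <- tab[tab$inhibitor == "Dinaciclib", ]
  expect_equal(din$fold_cdk1_free_vs_bound, 955 / 32, tolerance = 1e-12)
  expect_equal(round(din$fold_cdk1_free_vs_bound, 1), 29.8)
  su <- tab[tab$inhibitor == "SU9516", ]
  expect_match(su$kd_text_CDK1, "^> 20,000")
  expect_true(is.na(su$kd_CDK1))        # excluded from fold arithmetic
  expect_true(is.na(su$fold_cdk1_free_vs_bound))
})

test_that("empty and ambiguous affinity inputs are handled", {
  empty <- build_affinity_table(
    data.frame(inhibitor = character(0), state = character(0),
               kd = numeric(0), se = numeric(0)))
  expect_equal(nrow(empty), 0L)
  dup <- data.frame(inhibitor = c("a", "a"), state = c("s", "s"),
                    kd = c(1, 2), se = c(0.1, 0.1))
  expect_error(build_affinity_table(dup),
               class = "cdkstates_ambiguous_label")
})
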