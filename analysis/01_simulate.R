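#!/usr/bin/env Rscript
# Stage 1: generate every input of the comparative analysis.
#
# Four toy kinase structures carry planted inter-lobe contact counts
# matching the four states under comparison (cyclin-free CDK1 and CDK2,
# CDK1-cyclin B, CDK2-cyclin A); the biophysics CSVs are drawn from the
# one-set-of-sites / Boltzmann / hyperbolic / logistic models at the
# tabulated ground truths with experiment-scale noise. Everything is
# seeded; truth sidecars (*.truth.json) are written next to each file.
#
# Usage: Rscript analysis/01_simulate.R [--seed N] [--out results/sim]

suppressMessages(library(cdkstates))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "results/sim")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("-- structures: planting per-state inter-lobe contact counts")
planted <- c(cyclin_free_cdk1 = 104, cdk1_cyclin_b = 133,
             cyclin_free_cdk2 = 141, cdk2_cyclin_a = 145)
for (i in seq_along(planted)) {
  st <- names(planted)[i]
  gen_toy_kinase(planted[[i]], seed = seed * 100L + i,
                 path = file.path(out, paste0(st, ".pdb")))
  message(sprintf("   %s: %d contacts planted", st, planted[[i]]))
}

message("-- ITC: AZD5438 and Dinaciclib isotherms at tabulated Kd truths")
itc_truths <- list(
  azd5438_cdk1b = 70, azd5438_cdk2a = 4, azd5438_cdk1 = 4400,
  azd5438_cdk2 = 26, dinaciclib_cdk1 = 955, dinaciclib_cdk2 = 41)
sch <- injection_schedule()
for (i in seq_along(itc_truths)) {
  nm <- names(itc_truths)[i]
  truth <- one_site_params(kd = itc_truths[[i]] * 1e-9, dh = -9, n = 1)
  noise <- 0.02 * max(abs(simulate_itc(truth, sch)$heats))
  gen_itc(truth, sch, noise_sd = noise, seed = seed * 1000L + i,
          path = file.path(out, paste0("itc_", nm, ".csv")))
  message(sprintf("   %s: Kd %g nM", nm, itc_truths[[i]]))
}

message("-- DSF melts (25-95 C), SPR dose series, IC50 titration")
gen_melt(tm = 51.5, noise_sd = 1, seed = seed + 21L,
         path = file.path(out, "dsf_cdk2_apo.csv"))
gen_melt(tm = 60.4, noise_sd = 1, seed = seed + 22L,
         path = file.path(out, "dsf_cdk2_azd5438.csv"))
gen_melt(tm = 48.9, noise_sd = 1, seed = seed + 23L,
         path = file.path(out, "dsf_cdk1_apo.csv"))
gen_melt(tm = 46.3, noise_sd = 1, seed = seed + 24L,
         path = file.path(out, "dsf_cdk1_azd5438.csv"))
gen_spr(kd = 43, r_max = 100, noise_sd = 1, seed = seed + 31L,
        path = file.path(out, "spr_azd5438_cdk2.csv"))
invisible(gen_ic50(ic50 = 100, n_hill = 1, noise_sd = 0.02,
                   seed = seed + 41L,
                   path = file.path(out, "ic50_azd5438_cdk2a.csv")))

message("wrote inputs to ", out)
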