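# Generators: determinism, noiseless exactness, planted ground truth,
# format round trips.

test_that("noiseless generators reproduce their models exactly", {
  params <- one_site_params(kd = 70e-9, dh = -9)
  expect_equal(gen_itc(params, noise_sd = 0)$heats,
               simulate_itc(params, injection_schedule())$heats)
  melt <- gen_melt(tm = 51.5, slope = 1.8, f_min = 0, f_max = 100,
                   noise_sd = 0)
  expect_equal(melt$temperature_c, 25:95)
  expect_equal(melt$fluorescence,
               boltzmann_melt(25:95, 0, 100, 51.5, 1.8))
  spr <- gen_spr(kd = 43, r_max = 100, noise_sd = 0)
  expect_equal(spr$response, 100 * spr$concentration /
                 (43 + spr$concentration))
})

test_that("fixed seeds reproduce outputs byte-for-byte", {
  p <- one_site_params(1e-7, -10)
  expect_identical(gen_itc(p, noise_sd = 0.1, seed = 3)$heats,
                   gen_itc(p, noise_sd = 0.1, seed = 3)$heats)
  expect_identical(gen_melt(noise_sd = 1, seed = 5)$fluorescence,
                   gen_melt(noise_sd = 1, seed = 5)$fluorescence)
  a <- gen_toy_kinase(7, seed = 8)$model$atoms
  b <- gen_toy_kinase(7, seed = 8)$model$atoms
  expect_identical(a, b)
  expect_error(gen_itc(p, noise_sd = -1), "noise_sd")
})

test_that("heat noise is centered: residual mean within 3 sigma/sqrt(n)", {
  p <- one_site_params(1e-7, -10)
  sch <- injection_schedule()
  clean <- simulate_itc(p, sch)$heats
  sd_noise <- 0.2
  resid <- vapply(1:1000, function(s) {
    mean(gen_itc(p, sch, noise_sd = sd_noise, seed = s)$heats - clean)
  }, numeric(1))
  expect_lt(abs(mean(resid)), 3 * sd_noise / sqrt(1000))
})

test_that("dose ladders match the standard experimental designs", {
  expect_equal(spr_dilution_series(),
               c(0, 0.05, 0.19, 0.76, 3.05, 12.21, 48.83, 195.31, 781.25,
                 3125, 12500))
  expect_equal(spr_dilution_series(extended = TRUE)[12], 50000)
  doses <- ic50_titration()
  expect_length(doses, 12L)
  expect_equal(min(doses), 0)
  expect_equal(max(doses), 6000)   # 0-6 uM span, nM units
})

test_that("planted contact counts are recovered exactly by the census", {
  zero <- gen_toy_kinase(0, seed = 1)
  expect_equal(contact_census(zero$model, zero$emap, 4.0)$total_contacts, 0L)

  tk <- gen_toy_kinase(104, cutoff = 4.0, seed = 2)
  cc <- contact_census(tk$model, tk$emap, 4.0)
  expect_equal(cc$total_contacts, 104L)
  xyz <- as.matrix(tk$model$atoms[, c("x", "y", "z")])
  a_idx <- which(tk$model$atoms$res_no %in% tk$emap$n_lobe)
  b_idx <- which(tk$model$atoms$res_no %in% tk$emap$c_lobe)
  expect_equal(cc$total_contacts,
               oracle_cross_count(xyz, a_idx, b_idx, 4.0))
  # all unplanted cross pairs clear the margin
  d_cross <- sort(unlist(lapply(a_idx, function(i) {
    sqrt((xyz[b_idx, 1] - xyz[i, 1])^2 + (xyz[b_idx, 2] - xyz[i, 2])^2 +
         (xyz[b_idx, 3] - xyz[i, 3])^2)
  })))
  expect_true(all(d_cross[-(1:104)] >= 4.0 + 0.5))
})

test_that("the census is invariant under rigid motion of the structure", {
  tk <- gen_toy_kinase(33, seed = 4)
  moved <- transform_model(tk$model, euler_rotation(c(0.7, -1.2, 0.3)),
                           c(100, -50, 25))
  expect_equal(contact_census(moved, tk$emap, 4.0)$total_contacts, 33L)
})

test_that("generated structures re-parse from PDB with the same census", {
  path <- tempfile(fileext = ".pdb")
  tk <- gen_toy_kinase(15, seed = 5, path = path)
  expect_true(file.exists(path))
  truth <- jsonlite::read_json(paste0(path, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$n_contacts, 15)
  reread <- read_structure(path, chain_roles = c(A = "kinase"))
  expect_equal(contact_census(reread, tk$emap, 4.0)$total_contacts, 15L)
})

test_that("generated CSVs reload through the standard readers", {
  path <- tempfile(fileext = ".csv")
  gen_itc(one_site_params(1e-7, -10), noise_sd = 0.1, seed = 2, path = path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("injection_volume_uL", "heat_ucal"))
  expect_equal(nrow(df), 20L)
  truth <- jsonlite::read_json(paste0(path, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$kd, 1e-7)
})

test_that("a jitter-free rigid copy is recovered exactly", {
  tk <- gen_toy_kinase(10, seed = 6)
  cp <- gen_rigid_copy(tk$model, angles = c(0.5, 1.1, -0.7),
                       translation = c(10, 20, -5))
  s <- superpose(tk$model, cp$model)
  expect_lt(s$rmsd, 1e-8)
  # the fitted transform inverts the planted one
  expect_equal(s$rotation %*% cp$truth$rotation, diag(3), tolerance = 1e-8)
})

test_that("fitted rmsd tracks the planted jitter magnitude", {
  tk <- gen_toy_kinase(50, residues_per_lobe = 55, seed = 7)  # ~550 atoms
  sigma <- 0.5
  rmsds <- vapply(1:50, function(s) {
    cp <- gen_rigid_copy(tk$model, angles = c(0.2, 0.4, 0.6),
                         translation = c(1, 2, 3), jitter_sd = sigma,
                         seed = 100 + s)
    cdkstates:::kabsch(
      as.matrix(tk$model$atoms[, c("x", "y", "z")]),
      as.matrix(cp$model$atoms[, c("x", "y", "z")]))$rmsd
  }, numeric(1))
  # single-sided per-coordinate jitter sigma -> rmsd ~ sqrt(3) sigma
  expect_equal(mean(rmsds), sqrt(3) * sigma, tolerance = 0.1)
})

test_that("improper transforms and infeasible plants are rejected", {
  tk <- gen_toy_kinase(2, seed = 9)
  reflect <- diag(c(-1, 1, 1))
  expect_error(transform_model(tk$model, reflect), "proper")
  expect_error(gen_toy_kinase(10, contact_dist = 4.5, cutoff = 4),
               "infeasible")
  expect_error(gen_toy_kinase(10, residues_per_lobe = 4), "infeasible")
  expect_error(gen_toy_kinase(-3), "non-negative")
})
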