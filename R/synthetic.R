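# Seeded synthetic-data generators: every input the pipeline consumes can
# be produced here, parameterized and download-free, with ground truth
# recorded alongside (attribute "truth"; sidecar <output>.truth.json when
# written to disk).

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

write_truth_sidecar <- function(path, truth) {
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Generate a synthetic ITC isotherm
#'
#' Simulates the one-set-of-sites forward model under the given schedule
#' and adds i.i.d. Gaussian heat noise. The default schedule mirrors the
#' study protocol (0.5 uL priming + 19 x 2 uL of 100 uM titrant into a
#' 200 uL cell at 10 uM, 30 C).
#'
#' @param params A [one_site_params()] (the ground truth).
#' @param schedule An [injection_schedule()].
#' @param noise_sd Heat noise standard deviation, ucal (>= 0).
#' @param seed Integer seed (`NULL` leaves the RNG stream untouched).
#' @param path Optional CSV output path (`injection_volume_uL, heat_ucal`);
#'   a `.truth.json` sidecar is written next to it.
#' @return An `itc_isotherm` with attribute `truth`.
#' @export
gen_itc <- function(params, schedule = injection_schedule(),
                    noise_sd = 0, seed = NULL, path = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  iso <- simulate_itc(params, schedule)
  if (noise_sd > 0) {
    iso$heats <- iso$heats +
      with_seed(seed, stats::rnorm(length(iso$heats), 0, noise_sd))
  }
  truth <- list(kind = "itc", kd = params$kd, dh = params$dh, n = params$n,
                baseline = params$baseline, noise_sd = noise_sd, seed = seed)
  attr(iso, "truth") <- truth
  if (!is.null(path)) {
    utils::write.csv(
      data.frame(injection_volume_uL = schedule$injection_volumes_ul,
                 heat_ucal = iso$heats),
      path, row.names = FALSE)
    write_truth_sidecar(path, truth)
  }
  iso
}

#' Generate a synthetic DSF melt curve
#'
#' Boltzmann sigmoid over the standard sweep (25 to 95 C in 1 C steps)
#' plus Gaussian noise.
#'
#' @param tm,slope,f_min,f_max Boltzmann parameters (ground truth).
#' @param temperature_c Temperature grid, Celsius.
#' @param noise_sd Fluorescence noise SD (>= 0).
#' @param seed Integer seed.
#' @param path Optional CSV output (`temperature_C, fluorescence`).
#' @return Data frame `temperature_c`, `fluorescence` with attribute
#'   `truth`.
#' @export
gen_melt <- function(tm = 51.5, slope = 1.8, f_min = 0, f_max = 100,
                     temperature_c = 25:95, noise_sd = 0, seed = NULL,
                     path = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  f <- boltzmann_melt(temperature_c, f_min, f_max, tm, slope)
  if (noise_sd > 0) {
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, noise_sd))
  }
  out <- data.frame(temperature_c = temperature_c, fluorescence = f)
  truth <- list(kind = "dsf", tm = tm, slope = slope, f_min = f_min,
                f_max = f_max, noise_sd = noise_sd, seed = seed)
  attr(out, "truth") <- truth
  if (!is.null(path)) {
    utils::write.csv(stats::setNames(out, c("temperature_C", "fluorescence")),
                     path, row.names = FALSE)
    write_truth_sidecar(path, truth)
  }
  out
}

#' Standard SPR concentration ladder
#'
#' Four-fold dilution series emulating the study's multi-cycle dose
#' design: 0, 0.05, 0.19, 0.76, 3.05, 12.21, 48.83, 195.31, 781.25, 3125,
#' 12500 nM, with an optional extra 50000 nM top concentration.
#'
#' @param extended Include the 50000 nM point (used for the weaker-binding
#'   surface).
#' @return Numeric vector of concentrations, nM.
#' @export
spr_dilution_series <- function(extended = FALSE) {
  base <- c(0, 0.05, 0.19, 0.76, 3.05, 12.21, 48.83, 195.31, 781.25,
            3125, 12500)
  if (extended) c(base, 50000) else base
}

#' Generate a synthetic steady-state SPR dose series
#'
#' @param kd,r_max Hyperbolic saturation parameters (ground truth); `kd`
#'   in the same units as `concentration`.
#' @param concentration Dose ladder (default [spr_dilution_series()], nM).
#' @param noise_sd Response noise SD (>= 0).
#' @param seed Integer seed.
#' @param path Optional CSV output (`concentration_nM, response_RU`).
#' @return Data frame `concentration`, `response` with attribute `truth`.
#' @export
gen_spr <- function(kd = 43, r_max = 100,
                    concentration = spr_dilution_series(), noise_sd = 0,
                    seed = NULL, path = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  r <- r_max * concentration / (kd + concentration)
  if (noise_sd > 0) {
    r <- r + with_seed(seed, stats::rnorm(length(r), 0, noise_sd))
  }
  out <- data.frame(concentration = concentration, response = r)
  truth <- list(kind = "spr", kd = kd, r_max = r_max, noise_sd = noise_sd,
                seed = seed)
  attr(out, "truth") <- truth
  if (!is.null(path)) {
    utils::write.csv(stats::setNames(out, c("concentration_nM",
                                            "response_RU")),
                     path, row.names = FALSE)
    write_truth_sidecar(path, truth)
  }
  out
}

#' Standard activity-assay titration
#'
#' Twelve inhibitor doses spanning 0 to 6 uM: a zero point plus a two-fold
#' dilution series from the 6 uM top dose.
#'
#' @return Numeric vector of concentrations, nM (0 and 5.86..6000).
#' @export
ic50_titration <- function() {
  c(0, rev(6000 / 2^(0:10)))
}

#' Generate a synthetic inhibition dose-response series
#'
#' Activity follows the logistic [ic50_logistic()] on log10 concentration;
#' the zero dose is assigned the zero-concentration limit of the model.
#'
#' @param ic50 Ground-truth IC50 (concentration units of the titration).
#' @param n_hill Slope factor.
#' @param concentration Dose ladder (default [ic50_titration()], nM).
#' @param noise_sd Activity noise SD (>= 0).
#' @param seed Integer seed.
#' @param path Optional CSV output (`concentration_uM, activity_fraction`;
#'   concentrations converted from nM).
#' @return Data frame `concentration`, `activity` with attribute `truth`.
#' @export
gen_ic50 <- function(ic50 = 100, n_hill = 1,
                     concentration = ic50_titration(), noise_sd = 0,
                     seed = NULL, path = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  y <- numeric(length(concentration))
  pos <- concentration > 0
  y[pos] <- ic50_logistic(log10(concentration[pos]), log10(ic50), n_hill)
  y[!pos] <- if (n_hill > 0) 0 else 1   # zero-dose limit of the logistic
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  }
  out <- data.frame(concentration = concentration, activity = y)
  truth <- list(kind = "ic50", ic50 = ic50, n_hill = n_hill,
                noise_sd = noise_sd, seed = seed)
  attr(out, "truth") <- truth
  if (!is.null(path)) {
    utils::write.csv(data.frame(concentration_uM = concentration / 1000,
                                activity_fraction = y),
                     path, row.names = FALSE)
    write_truth_sidecar(path, truth)
  }
  out
}

# ---- Toy structures -------------------------------------------------------

#' Generate a toy two-lobe kinase with planted inter-lobe contacts
#'
#' Builds a structure of alanine-like residues (5 heavy atoms each) in two
#' spatially separated blocks labelled as N- and C-lobe, with exactly
#' `n_contacts` inter-lobe heavy-atom pairs strictly below `cutoff`;
#' every other inter-lobe pair is at least `cutoff + margin` apart, by
#' construction. Planted contacts sit at `contact_dist` across a planar
#' interface; contact columns are spaced so no incidental cross pair
#' enters the margin.
#'
#' @param n_contacts Number of planted contacts (>= 0).
#' @param residues_per_lobe Total residues per lobe (at least the number
#'   of planted columns).
#' @param cutoff Census cutoff the plant targets (Angstrom).
#' @param margin Clearance beyond the cutoff for all unplanted pairs.
#' @param contact_dist Planted pair distance (must be `< cutoff`).
#' @param seed Integer seed (bulk residue placement).
#' @param path Optional PDB output path (+ `.truth.json` sidecar).
#' @return List with `model` (a `structure_model`, kinase chain "A"),
#'   `emap` (an `element_map` labelling the two blocks), and `truth`.
#' @export
gen_toy_kinase <- function(n_contacts, residues_per_lobe = NULL,
                           cutoff = 4.0, margin = 0.5, contact_dist = 3.5,
                           seed = NULL, path = NULL) {
  if (n_contacts < 0 || n_contacts != round(n_contacts)) {
    stop("n_contacts must be a non-negative integer", call. = FALSE)
  }
  if (contact_dist >= cutoff) {
    stop("infeasible plant: contact_dist must be < cutoff", call. = FALSE)
  }
  # lateral spacing keeping diagonal planted-to-planted pairs outside
  # cutoff + margin: sqrt(spacing^2 + contact_dist^2) >= cutoff + margin
  spacing <- max(6, sqrt(max((cutoff + margin)^2 - contact_dist^2, 0)) + 2)
  if (is.null(residues_per_lobe)) residues_per_lobe <- max(n_contacts, 1) + 5
  if (residues_per_lobe < max(n_contacts, 1)) {
    stop("infeasible plant: residues_per_lobe < n_contacts", call. = FALSE)
  }
  ncol_grid <- ceiling(sqrt(max(n_contacts, 1)))
  col_xy <- function(k) {
    c(((k - 1) %% ncol_grid) * spacing,
      ((k - 1) %/% ncol_grid) * spacing)
  }
  # alanine-like residue: planted/reference atom CB plus 4 support atoms
  # offset away from the interface plane
  residue_atoms <- function(res_no, center, away) {
    # away = +1: support atoms at larger z; away = -1: smaller z
    offs <- rbind(CB = c(0, 0, 0),
                  CA = c(1.1, 0, 1.3 * away),
                  N  = c(-1.1, 0.4, 1.3 * away),
                  C  = c(0.4, 1.1, 1.5 * away),
                  O  = c(-0.4, -1.1, 1.5 * away))
    data.frame(chain_id = "A", res_no = res_no, ins_code = "",
               res_name = "ALA", atom_name = rownames(offs), element = "C",
               x = center[1L] + offs[, 1L], y = center[2L] + offs[, 2L],
               z = center[3L] + offs[, 3L],
               occupancy = 1, altloc = "", is_hetero = FALSE)
  }
  rows <- list()
  res_no <- 0L
  # lobe A planted residues: CB at z = 0, support atoms below
  for (k in seq_len(n_contacts)) {
    res_no <- res_no + 1L
    xy <- col_xy(k)
    rows[[length(rows) + 1L]] <- residue_atoms(res_no, c(xy, 0), away = -1)
  }
  bulk <- function(n, z_lo, z_hi, away, start_res) {
    out <- list()
    extent <- max(spacing * ncol_grid, 20)
    for (k in seq_len(n)) {
      ctr <- c(stats::runif(1, 0, extent), stats::runif(1, 0, extent),
               stats::runif(1, z_lo, z_hi))
      out[[k]] <- residue_atoms(start_res + k, ctr, away)
    }
    out
  }
  with_seed(seed, {
    n_bulk_a <- residues_per_lobe - n_contacts
    rows <- c(rows, bulk(n_bulk_a, -30, -10, away = -1, start_res = res_no))
    res_no <- res_no + n_bulk_a
    n_lobe_a <- res_no
    for (k in seq_len(n_contacts)) {
      res_no <- res_no + 1L
      xy <- col_xy(k)
      rows[[length(rows) + 1L]] <-
        residue_atoms(res_no, c(xy, contact_dist), away = +1)
    }
    rows <- c(rows,
              bulk(residues_per_lobe - n_contacts,
                   contact_dist + 10 + cutoff + margin,
                   contact_dist + 30, away = +1, start_res = res_no))
    res_no <- res_no + residues_per_lobe - n_contacts
  })
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  n_lobe_a <- residues_per_lobe
  model <- structure_model(
    identifier = sprintf("toy_%d_contacts", n_contacts),
    atoms = atoms, chain_roles = c(A = "kinase"))
  emap <- element_map(
    n_lobe = 1:n_lobe_a, c_lobe = (n_lobe_a + 1L):res_no,
    hinge = integer(0),
    p_loop = 1L, c_helix = 2L, activation_segment = n_lobe_a + 1L,
    beta_sheet_base = 3L,
    r_spine_residues = c(1L, n_lobe_a + 1L),
    c_spine_residues = c(2L, n_lobe_a + 2L),
    gatekeeper = 2L, ploop_tyrosine = 1L,
    activation_glutamate = n_lobe_a + 1L)
  truth <- list(kind = "toy_structure", n_contacts = n_contacts,
                cutoff = cutoff, margin = margin,
                contact_dist = contact_dist, seed = seed)
  if (!is.null(path)) {
    write_structure_pdb(model, path)
    write_truth_sidecar(path, truth)
  }
  list(model = model, emap = emap, truth = truth)
}

#' Rigid (optionally jittered) copy of a structure
#'
#' Applies a proper rigid-body transform built from Euler angles and a
#' translation, then adds seeded isotropic Gaussian coordinate jitter.
#' The ground-truth transform is recorded for recovery tests.
#'
#' @param model A `structure_model`.
#' @param angles Euler angles (radians, ZYX convention), length 3.
#' @param translation Length-3 translation, Angstrom.
#' @param jitter_sd Per-coordinate jitter SD, Angstrom (>= 0).
#' @param seed Integer seed.
#' @return List with `model` (the transformed copy) and `truth`
#'   (`rotation`, `translation`, `jitter_sd`).
#' @export
gen_rigid_copy <- function(model, angles = c(0, 0, 0),
                           translation = c(0, 0, 0), jitter_sd = 0,
                           seed = NULL) {
  if (n_atoms(model) == 0L) stop("model is empty", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  R <- euler_rotation(angles)
  out <- transform_model(model, R, translation)
  if (jitter_sd > 0) {
    with_seed(seed, {
      out$atoms$x <- out$atoms$x + stats::rnorm(n_atoms(out), 0, jitter_sd)
      out$atoms$y <- out$atoms$y + stats::rnorm(n_atoms(out), 0, jitter_sd)
      out$atoms$z <- out$atoms$z + stats::rnorm(n_atoms(out), 0, jitter_sd)
    })
  }
  out$identifier <- paste0(model$identifier, "_copy")
  list(model = out,
       truth = list(rotation = R, translation = translation,
                    jitter_sd = jitter_sd, seed = seed))
}

#' Proper rotation matrix from Euler angles (ZYX convention)
#'
#' @param angles Length-3 numeric, radians.
#' @return 3x3 rotation matrix with determinant +1.
#' @export
euler_rotation <- function(angles) {
  a <- angles[1L]; b <- angles[2L]; g <- angles[3L]
  rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
               byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
               byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(g), -sin(g), 0, sin(g), cos(g)), 3,
               byrow = TRUE)
  rz %*% ry %*% rx
}
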