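# Structural metrics: pairing, superposition, contact census, spines,
# P-loop class, state comparison.

seq50 <- "MENFQKVEKIGEGTYGVVYKARNKLTGEVVALKKIRLDTETEGVPSTAIR"

test_that("identical chains pair residue-for-residue", {
  a <- make_ca_chain(seq50)
  b <- make_ca_chain(seq50)
  p <- pair_calphas(a, b)
  expect_equal(nrow(p), 50L)
  expect_equal(p$fixed_res, p$moving_res)
  expect_true(all(p$identical))
})

test_that("an internal deletion is skipped by the alignment", {
  full <- make_ca_chain(seq50)
  deleted <- paste0(substr(seq50, 1, 20), substr(seq50, 26, 50))
  short <- make_ca_chain(deleted)
  p <- pair_calphas(full, short)
  expect_equal(nrow(p), 45L)
  expect_false(any(21:25 %in% p$fixed_res))
  expect_equal(setdiff(1:50, p$fixed_res), 21:25)
})

test_that("pairing follows sequence, not author numbering", {
  a <- make_ca_chain(seq50, start_res = 1L)
  b <- make_ca_chain(seq50, start_res = 101L)
  p <- pair_calphas(a, b)
  expect_equal(p$moving_res, p$fixed_res + 100L)
  expect_true(all(p$identical))
})

test_that("too few alignable residues raise an insufficient-pairing error", {
  a <- make_ca_chain("AA")
  expect_error(pair_calphas(a, a),
               class = "cdkstates_insufficient_pairing")
})

test_that("self-superposition gives rmsd 0 and the identity rotation", {
  a <- make_ca_chain(seq50)
  s <- superpose(a, a)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)
  expect_equal(abs(det(s$rotation)), 1, tolerance = 1e-6)
  expect_equal(s$n_pairs, 50L)
})

test_that("superposition rmsd is invariant under proper rigid motion", {
  a <- make_ca_chain(seq50)
  set.seed(42)
  for (k in 1:5) {
    R <- euler_rotation(stats::runif(3, -pi, pi))
    moved <- transform_model(a, R, stats::rnorm(3, 0, 20))
    s <- superpose(a, moved)
    expect_lt(s$rmsd, 1e-8)
    expect_equal(det(s$rotation), 1, tolerance = 1e-6)
  }
})

test_that("Kabsch matches the 1-D rotational grid search on planar toys", {
  set.seed(7)
  for (k in 1:5) {
    P <- cbind(matrix(stats::rnorm(8, sd = 4), 4, 2), 0)
    theta <- stats::runif(1, 0, 2 * pi)
    R2 <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2,
                 byrow = TRUE)
    Q <- cbind(t(R2 %*% t(P[, 1:2])) + matrix(stats::rnorm(8, sd = 0.3),
                                              4, 2), 0)
    # moving Q back onto P: pass Q as the moving set
    fit <- cdkstates:::kabsch(P, Q)
    oracle <- grid_search_rmsd(P, Q)
    expect_equal(fit$rmsd, oracle, tolerance = 1e-4)
  }
})

test_that("Kabsch agrees with an independent least-squares fit", {
  a <- make_ca_chain(seq50)
  cp <- gen_rigid_copy(a, angles = c(0.3, -0.8, 1.2),
                       translation = c(4, -7, 2), jitter_sd = 0.4, seed = 5)
  s <- superpose(a, cp$model)
  xyz_f <- as.numeric(t(as.matrix(a$atoms[, c("x", "y", "z")])))
  xyz_m <- as.numeric(t(as.matrix(cp$model$atoms[, c("x", "y", "z")])))
  ref <- bio3d::rmsd(xyz_f, xyz_m, fit = TRUE)
  expect_equal(s$rmsd, ref, tolerance = 1e-3)
})

test_that("degenerate collinear atom sets are rejected", {
  rows <- lapply(1:5, function(i) {
    list(res = i, atom = "CA", xyz = c(i * 1.5, 0, 0))
  })
  a <- make_model(rows)
  expect_error(superpose(a, a), class = "cdkstates_degenerate_input")
})

test_that("contact census counts exactly the sub-cutoff inter-lobe pairs", {
  two <- make_model(list(
    list(res = 1, atom = "CB", xyz = c(0, 0, 0)),
    list(res = 2, atom = "CB", xyz = c(0, 0, 3.5))))
  em <- element_map(n_lobe = 1L, c_lobe = 2L, hinge = integer(0),
                    p_loop = 1L, c_helix = 1L, activation_segment = 2L,
                    beta_sheet_base = 1L, r_spine_residues = c(1L, 2L),
                    c_spine_residues = c(1L, 2L), gatekeeper = 1L,
                    ploop_tyrosine = 1L, activation_glutamate = 2L)
  expect_equal(contact_census(two, em, 4.0)$total_contacts, 1L)

  boundary <- make_model(list(
    list(res = 1, atom = "CB", xyz = c(0, 0, 0)),
    list(res = 2, atom = "CB", xyz = c(0, 0, 4.0))))
  expect_equal(contact_census(boundary, em, 4.0)$total_contacts, 0L)
})

test_that("grid census equals the all-pairs oracle on random clouds", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(10:300, 1)
    cutoff <- stats::runif(1, 2, 8)
    xyz <- matrix(stats::rnorm(3 * n, sd = 8), n, 3)
    lobe <- sample(c(TRUE, FALSE), n, replace = TRUE)
    lobe[1] <- TRUE; lobe[2] <- FALSE   # both lobes always populated
    rows <- lapply(seq_len(n), function(i) {
      list(res = i, atom = "CB", xyz = xyz[i, ])
    })
    m <- make_model(rows)
    em <- element_map(
      n_lobe = which(lobe), c_lobe = which(!lobe), hinge = integer(0),
      p_loop = which(lobe)[1], c_helix = which(lobe)[1],
      activation_segment = which(!lobe)[1], beta_sheet_base = which(lobe)[1],
      r_spine_residues = c(which(lobe)[1], which(!lobe)[1]),
      c_spine_residues = c(which(lobe)[1], which(!lobe)[1]),
      gatekeeper = which(lobe)[1], ploop_tyrosine = which(lobe)[1],
      activation_glutamate = which(!lobe)[1])
    cc <- contact_census(m, em, cutoff)
    expect_equal(cc$total_contacts,
                 oracle_cross_count(xyz, which(lobe), which(!lobe), cutoff))
    expect_true(all(cc$contact_list$distance < cutoff))
  }
})

test_that("contact count is monotone non-decreasing in the cutoff", {
  tk <- gen_toy_kinase(20, seed = 2)
  counts <- vapply(c(2, 3, 3.6, 4, 5, 8), function(ct) {
    contact_census(tk$model, tk$emap, ct)$total_contacts
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

spine_stack <- function(gaps) {
  # consecutive CB atoms along z separated by the requested gaps
  z <- cumsum(c(0, gaps))
  rows <- unlist(lapply(seq_along(z), function(i) {
    list(list(res = i, atom = "CA", xyz = c(5, 0, z[i])),   # backbone, ignored
         list(res = i, atom = "CB", xyz = c(0, 0, z[i])))
  }), recursive = FALSE)
  make_model(rows)
}

spine_emap <- function(n) {
  element_map(n_lobe = 1:2, c_lobe = 3:max(n, 3), hinge = integer(0),
              p_loop = 1L, c_helix = 2L, activation_segment = 3L,
              beta_sheet_base = 1L, r_spine_residues = seq_len(n),
              c_spine_residues = seq_len(n), gatekeeper = 1L,
              ploop_tyrosine = 1L, activation_glutamate = 3L)
}

test_that("spine assembly follows the link threshold", {
  m <- spine_stack(c(3.8, 3.8, 3.8))
  a <- assess_spine(m, spine_emap(4), spine = "R", link_threshold = 4.5)
  expect_true(a$assembled)
  expect_equal(a$residue_gaps, c(3.8, 3.8, 3.8), tolerance = 1e-12)
  expect_equal(nrow(a$broken_links), 0L)

  b <- assess_spine(spine_stack(c(3.8, 7, 3.8)), spine_emap(4),
                    spine = "R", link_threshold = 4.5)
  expect_false(b$assembled)
  expect_equal(nrow(b$broken_links), 1L)
  expect_equal(b$broken_links$res_a, 2L)
})

test_that("spine gaps equal the exhaustive pairwise minimum", {
  set.seed(3)
  n <- 5
  rows <- list()
  for (i in seq_len(n)) {
    for (atom in c("CB", "CG", "CD")) {
      rows[[length(rows) + 1L]] <-
        list(res = i, atom = atom, xyz = stats::rnorm(3, mean = i * 4, sd = 1))
    }
  }
  m <- make_model(rows)
  a <- assess_spine(m, spine_emap(n), spine = "C", link_threshold = 4.5)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
  for (k in seq_len(n - 1)) {
    ia <- which(m$atoms$res_no == k)
    ib <- which(m$atoms$res_no == k + 1)
    brute <- min(as.matrix(stats::dist(xyz))[ia, ib])
    expect_equal(a$residue_gaps[k], brute, tolerance = 1e-10)
  }
  # assembled flag is monotone in the threshold
  thr <- sort(c(a$residue_gaps, 10))
  assembled <- vapply(thr + 1e-9, function(t) {
    assess_spine(m, spine_emap(n), spine = "C", link_threshold = t)$assembled
  }, logical(1))
  expect_true(all(diff(as.integer(assembled)) >= 0))
})

test_that("spines of fewer than two residues are a configuration error", {
  m <- spine_stack(c(3.8))
  em <- spine_emap(2)
  em$r_spine_residues <- 1L
  expect_error(assess_spine(m, em, spine = "R"), "at least 2")
})

ploop_model <- function(oh_xyz, oe_xyz = c(0, 0, 12)) {
  make_model(list(
    list(res = 15, atom = "OH", element = "O", res_name = "TYR",
         xyz = oh_xyz),
    list(res = 163, atom = "OE1", element = "O", res_name = "GLU",
         xyz = oe_xyz),
    list(res = 163, atom = "OE2", element = "O", res_name = "GLU",
         xyz = oe_xyz + c(1, 0, 0)),
    list(res = 80, atom = "CZ", res_name = "PHE", xyz = c(0, 0, 0)),
    list(res = 81, atom = "CA", xyz = c(1, 0, 0)),
    list(res = 82, atom = "CA", xyz = c(-1, 0, 0))))
}

ploop_emap <- element_map(
  n_lobe = 1:80, c_lobe = 85:200, hinge = 81:84, p_loop = 11:17,
  c_helix = 46:57, activation_segment = 146:173, beta_sheet_base = 78:80,
  r_spine_residues = c(55L, 147L), c_spine_residues = c(18L, 134L),
  gatekeeper = 80L, ploop_tyrosine = 15L, activation_glutamate = 163L)

test_that("P-loop tyrosine near the glutamate classifies popped_out", {
  m <- ploop_model(oh_xyz = c(0, 0, 9.2), oe_xyz = c(0, 0, 12))
  cl <- classify_ploop(m, ploop_emap)
  expect_equal(cl$label, "popped_out")
  expect_lt(cl$d_glu, cl$d_pocket)
  expect_lt(cl$d_glu, 3.5)
})

test_that("P-loop tyrosine at the pocket reference classifies tucked_in", {
  m <- ploop_model(oh_xyz = c(0, 0, 0), oe_xyz = c(0, 0, 15))
  cl <- classify_ploop(m, ploop_emap)
  expect_equal(cl$label, "tucked_in")
})

test_that("ambiguous geometry and missing atoms give indeterminate", {
  far <- ploop_model(oh_xyz = c(0, 30, 8), oe_xyz = c(0, 30, 16))
  expect_equal(classify_ploop(far, ploop_emap)$label, "indeterminate")

  m <- ploop_model(c(0, 0, 9.2))
  m$atoms <- m$atoms[m$atoms$atom_name != "OH", ]
  cl <- classify_ploop(m, ploop_emap)
  expect_equal(cl$label, "indeterminate")
  expect_match(cl$reason, "OH")
})

test_that("the P-loop class is stable under rigid motion", {
  m <- ploop_model(oh_xyz = c(0, 0, 9.2), oe_xyz = c(0, 0, 12))
  before <- classify_ploop(m, ploop_emap)
  moved <- transform_model(m, euler_rotation(c(1.1, 0.4, -2)), c(30, -5, 12))
  after <- classify_ploop(moved, ploop_emap)
  expect_equal(after$label, before$label)
  expect_equal(after$d_glu, before$d_glu, tolerance = 1e-9)
  expect_equal(after$d_pocket, before$d_pocket, tolerance = 1e-9)
})

fake_census <- function(total, cutoff = 4.0) {
  structure(list(cutoff = cutoff, total_contacts = total,
                 per_element_contacts = NULL, contact_list = NULL,
                 identifier = "x"),
            class = "contact_census_result")
}

test_that("state comparison flags the minimum-contact state", {
  censuses <- list(cdk1_cyclin_b = fake_census(133),
                   cdk2_cyclin_a = fake_census(145),
                   cyclin_free_cdk1 = fake_census(104),
                   cyclin_free_cdk2 = fake_census(141))
  tab <- compare_states(censuses)
  expect_equal(tab$state[1], "cyclin_free_cdk1")
  expect_equal(tab$total_contacts, c(104, 133, 141, 145))
  expect_equal(tab$state[tab$is_minimum], "cyclin_free_cdk1")
  # permutation invariance
  tab2 <- compare_states(censuses[c(3, 1, 4, 2)])
  expect_identical(tab, tab2)
})

test_that("ties are reported without a unique minimum", {
  tab <- compare_states(list(a = fake_census(10), b = fake_census(10)))
  expect_true(attr(tab, "tie"))
  expect_equal(sum(tab$is_minimum), 2L)
})

test_that("mixed cutoffs are an incompatible-census error", {
  expect_error(
    compare_states(list(a = fake_census(1, 4), b = fake_census(2, 4.5))),
    class = "cdkstates_incompatible_census")
})
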