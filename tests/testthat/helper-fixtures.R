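# Fixtures are built in code: tiny coordinate files, synthetic chains and
# brute-force oracles shared across the test files.

mini_pdb_text <- c(
  "ATOM      1  N   ALA A   5       1.000   2.000   3.000  1.00 10.00           N",
  "ATOM      2  CA  ALA A   5       2.500   2.100   3.200  1.00 10.00           C",
  "END")

mini_cif_text <- c(
  "data_mini",
  "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
  "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
  "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
  "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
  "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 5 ALA A N 1",
  "ATOM 2 C CA . ALA A 1 1 ? 2.500 2.100 3.200 1.00 10.00 ? 5 ALA A CA 1")

write_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# C-alpha-only chain along a non-degenerate helical curve; one residue per
# letter of `sequence` (one-letter codes), author numbering from start_res.
make_ca_chain <- function(sequence, start_res = 1L, chain = "A",
                          identifier = "synthetic") {
  aa <- strsplit(sequence, "")[[1L]]
  n <- length(aa)
  t <- seq_len(n)
  atoms <- data.frame(
    chain_id = chain, res_no = start_res + t - 1L, ins_code = "",
    res_name = bio3d::aa123(aa), atom_name = "CA", element = "C",
    x = 5 * cos(0.6 * t), y = 5 * sin(0.6 * t), z = 1.5 * t,
    occupancy = 1, altloc = "", is_hetero = FALSE)
  structure_model(identifier, atoms,
                  stats::setNames("kinase", chain))
}

# Build a structure_model from explicit atom rows (list of lists).
make_model <- function(rows, identifier = "fixture",
                       roles = c(A = "kinase")) {
  atoms <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chain_id = r$chain %||% "A", res_no = r$res,
               ins_code = "", res_name = r$res_name %||% "ALA",
               atom_name = r$atom, element = r$element %||% "C",
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               occupancy = r$occ %||% 1, altloc = r$alt %||% "",
               is_hetero = isTRUE(r$het))
  }))
  structure_model(identifier, atoms, roles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) contact oracle: unordered cross pairs strictly below cutoff.
oracle_cross_count <- function(xyz, a_idx, b_idx, cutoff) {
  n <- 0L
  for (i in a_idx) {
    d2 <- (xyz[b_idx, 1] - xyz[i, 1])^2 + (xyz[b_idx, 2] - xyz[i, 2])^2 +
          (xyz[b_idx, 3] - xyz[i, 3])^2
    n <- n + sum(d2 < cutoff^2)
  }
  n
}

# 1-D rotational grid-search RMSD oracle for planar (z = 0) point sets:
# exhaustive search over the in-plane rotation angle with translation
# solved by centroid matching, refined to step `tol`.
grid_search_rmsd <- function(P, Q, tol = 1e-6) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  rmsd_at <- function(theta) {
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2,
                byrow = TRUE)
    sqrt(mean(rowSums((t(R %*% t(Q0[, 1:2])) - P0[, 1:2])^2)))
  }
  lo <- 0; hi <- 2 * pi; step <- 2 * pi / 3600
  while (step > tol) {
    grid <- seq(lo, hi, by = step)
    vals <- vapply(grid, rmsd_at, numeric(1))
    best <- grid[which.min(vals)]
    lo <- best - 2 * step; hi <- best + 2 * step; step <- step / 10
  }
  min(vapply(seq(lo, hi, length.out = 101), rmsd_at, numeric(1)))
}

# Bisection oracle for the single-site equilibrium: solves free ligand X
# from total ligand Xt = X + n Mt X / (Kd + X), returns bound complex.
bisect_bound <- function(kd, n, mt, xt, tol = 1e-16) {
  f <- function(x) x + n * mt * x / (kd + x) - xt
  lo <- 0; hi <- xt
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  xt - (lo + hi) / 2
}
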