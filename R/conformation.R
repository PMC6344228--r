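# Structural metrics: C-alpha pairing, Kabsch superposition, inter-lobe
# contact census, hydrophobic spine assembly, P-loop conformation.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

kinase_heavy_atoms <- function(model, chain = NULL) {
  if (is.null(chain)) chain <- kinase_chain(model)
  sel <- select_atoms(model, chain = chain, heavy_only = TRUE,
                      exclude_hetero = TRUE)
  sel$atoms
}

# ---- C-alpha pairing ------------------------------------------------------

#' Pair residues of two kinase chains by global sequence alignment
#'
#' Aligns the one-letter sequences of the two kinase chains globally
#' (match +1, mismatch 0, gap -1, via Biostrings) and returns the aligned
#' residue pairs. Pairing follows sequence, not author numbering, so
#' renumbered chains pair correctly. Only residues with a C-alpha atom
#' enter the alignment.
#'
#' @param fixed,moving `structure_model` objects, each with a kinase chain.
#' @return Data frame with columns `fixed_res`, `moving_res` (author
#'   residue numbers) and `identical` (same residue type).
#' @export
pair_calphas <- function(fixed, moving) {
  fa <- calpha_table(fixed)
  mb <- calpha_table(moving)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(fa$aa1, collapse = "")),
    Biostrings::AAString(paste(mb$aa1, collapse = "")),
    type = "global",
    substitutionMatrix = unit_substitution_matrix(),
    gapOpening = 0, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  i <- 0L; j <- 0L
  fixed_res <- integer(0); moving_res <- integer(0); ident <- logical(0)
  for (k in seq_along(p)) {
    if (p[k] != "-") i <- i + 1L
    if (s[k] != "-") j <- j + 1L
    if (p[k] != "-" && s[k] != "-") {
      fixed_res  <- c(fixed_res, fa$res_no[i])
      moving_res <- c(moving_res, mb$res_no[j])
      ident <- c(ident, p[k] == s[k])
    }
  }
  pairing <- data.frame(fixed_res = fixed_res, moving_res = moving_res,
                        identical = ident)
  if (nrow(pairing) < 3L) {
    stop(errorCondition(
      sprintf("only %d residue pairs aligned; need at least 3",
              nrow(pairing)),
      class = c("cdkstates_insufficient_pairing", "error", "condition")))
  }
  pairing
}

# One row per residue that has a C-alpha, in chain order.
calpha_table <- function(model) {
  at <- kinase_heavy_atoms(model)
  ca <- at[at$atom_name == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$res_no, ca$ins_code)), , drop = FALSE]
  if (nrow(ca) == 0L) {
    stop("kinase chain of '", model$identifier, "' has no C-alpha atoms",
         call. = FALSE)
  }
  aa1 <- suppressWarnings(bio3d::aa321(ca$res_name))
  aa1[is.na(aa1) | aa1 == ""] <- "X"
  data.frame(res_no = ca$res_no, aa1 = aa1)
}

unit_substitution_matrix <- function() {
  letters20 <- strsplit("ARNDCQEGHILKMFPSTWYVX", "")[[1L]]
  m <- matrix(0, length(letters20), length(letters20),
              dimnames = list(letters20, letters20))
  diag(m) <- 1
  m
}

# ---- Kabsch superposition -------------------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the proper rotation and translation minimizing the RMSD of the
#' moving atom set onto the fixed one over sequence-paired residues.
#' Reflection solutions are rejected by the determinant sign correction.
#'
#' @param fixed,moving `structure_model` objects.
#' @param pairing Residue pairing from [pair_calphas()]; computed if `NULL`.
#' @param atom_set `"calpha"` (default; one atom per paired residue) or
#'   `"all_heavy"` (all heavy atoms with matching names in both paired
#'   residues).
#' @return `superposition_result`: `rmsd` (Angstrom), `n_pairs`, `rotation`
#'   (3x3, det +1), `translation` (length-3), `pairing`.
#' @export
superpose <- function(fixed, moving, pairing = NULL,
                      atom_set = c("calpha", "all_heavy")) {
  atom_set <- match.arg(atom_set)
  if (is.null(pairing)) pairing <- pair_calphas(fixed, moving)
  fa <- kinase_heavy_atoms(fixed)
  mb <- kinase_heavy_atoms(moving)
  P <- NULL; Q <- NULL
  for (k in seq_len(nrow(pairing))) {
    ra <- fa[fa$res_no == pairing$fixed_res[k], , drop = FALSE]
    rb <- mb[mb$res_no == pairing$moving_res[k], , drop = FALSE]
    if (atom_set == "calpha") {
      ra <- ra[ra$atom_name == "CA", , drop = FALSE]
      rb <- rb[rb$atom_name == "CA", , drop = FALSE]
      if (nrow(ra) < 1L || nrow(rb) < 1L) next
      P <- rbind(P, as.matrix(ra[1L, c("x", "y", "z")]))
      Q <- rbind(Q, as.matrix(rb[1L, c("x", "y", "z")]))
    } else {
      shared <- intersect(ra$atom_name, rb$atom_name)
      for (nm in shared) {
        P <- rbind(P, as.matrix(ra[ra$atom_name == nm, c("x", "y", "z")][1L, ]))
        Q <- rbind(Q, as.matrix(rb[rb$atom_name == nm, c("x", "y", "z")][1L, ]))
      }
    }
  }
  if (is.null(P) || nrow(P) < 3L) {
    stop(errorCondition("fewer than 3 matched atom pairs for superposition",
      class = c("cdkstates_insufficient_pairing", "error", "condition")))
  }
  kabsch(P, Q, pairing)
}

# P: fixed coordinates, Q: moving; returns transform mapping Q onto P.
kabsch <- function(P, Q, pairing = NULL) {
  storage.mode(P) <- "double"; storage.mode(Q) <- "double"
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Q0, P0))          # H = Q0^T P0 (3x3)
  if (sv$d[2L] < 1e-10) {
    stop(errorCondition("degenerate (collinear) atom set for superposition",
      class = c("cdkstates_degenerate_input", "error", "condition")))
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cp - as.numeric(R %*% cq)
  Qfit <- t(R %*% t(Q)) + matrix(t_vec, nrow(Q), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Qfit - P)^2)))
  structure(
    list(rmsd = rmsd, n_pairs = nrow(P), rotation = R,
         translation = t_vec, pairing = pairing),
    class = "superposition_result"
  )
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> rmsd = %.4f A over %d atom pairs\n",
              x$rmsd, x$n_pairs))
  invisible(x)
}

#' Apply a proper rigid transform to a structure model
#'
#' @param model A `structure_model`.
#' @param rotation 3x3 rotation matrix (det +1).
#' @param translation Length-3 vector (Angstrom).
#' @return Transformed `structure_model`.
#' @export
transform_model <- function(model, rotation, translation = c(0, 0, 0)) {
  if (abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be proper (det +1)", call. = FALSE)
  }
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new_xyz <- t(rotation %*% t(xyz)) +
    matrix(translation, nrow(xyz), 3, byrow = TRUE)
  model$atoms$x <- new_xyz[, 1L]
  model$atoms$y <- new_xyz[, 2L]
  model$atoms$z <- new_xyz[, 3L]
  model
}

# ---- Inter-lobe contact census --------------------------------------------

#' Census of inter-lobe atomic contacts
#'
#' Counts unordered heavy-atom pairs (a, b) with a in an N-lobe residue and
#' b in a C-lobe residue of the kinase chain at distance strictly below
#' `cutoff`. Intra-lobe pairs never count; ligands, waters and non-kinase
#' chains are excluded. Candidate pairs are found with a cell-list spatial
#' grid whose result is identical to the all-pairs computation.
#'
#' @param model A `structure_model`.
#' @param emap An `element_map` for the kinase chain.
#' @param cutoff Distance cutoff in Angstrom (strict `<`). Default 4.0.
#' @param mode `"lobe_vs_lobe"` tallies one (n_lobe, c_lobe) pair count;
#'   `"element_pairs"` additionally breaks counts down by named element
#'   (P loop, C helix, beta-sheet base, activation segment, remainder).
#' @return `contact_census_result` with `cutoff`, `total_contacts`,
#'   `per_element_contacts` (data frame) and `contact_list` (data frame of
#'   atom pairs and distances).
#' @export
contact_census <- function(model, emap, cutoff = 4.0,
                           mode = c("lobe_vs_lobe", "element_pairs")) {
  mode <- match.arg(mode)
  stopifnot(cutoff > 0)
  at <- kinase_heavy_atoms(model)
  a_idx <- which(at$res_no %in% emap$n_lobe)
  b_idx <- which(at$res_no %in% emap$c_lobe)
  if (mode == "element_pairs") {
    for (el in c("p_loop", "c_helix", "beta_sheet_base",
                 "activation_segment")) {
      if (!any(at$res_no %in% emap[[el]])) {
        warning("element '", el, "' has no atoms in model '",
                model$identifier, "'", call. = FALSE)
      }
    }
  }
  pairs <- grid_cross_pairs(as.matrix(at[, c("x", "y", "z")]),
                            a_idx, b_idx, cutoff)
  if (nrow(pairs) > 0L) {
    contact_list <- data.frame(
      res_a = at$res_no[pairs[, 1L]], atom_a = at$atom_name[pairs[, 1L]],
      res_b = at$res_no[pairs[, 2L]], atom_b = at$atom_name[pairs[, 2L]],
      distance = pairs[, 3L]
    )
  } else {
    contact_list <- data.frame(res_a = integer(0), atom_a = character(0),
                               res_b = integer(0), atom_b = character(0),
                               distance = numeric(0))
  }
  if (mode == "lobe_vs_lobe") {
    per_el <- data.frame(element_a = "n_lobe", element_b = "c_lobe",
                         count = nrow(contact_list))
  } else {
    el_a <- element_label(contact_list$res_a, emap, side = "n")
    el_b <- element_label(contact_list$res_b, emap, side = "c")
    per_el <- as.data.frame(table(element_a = el_a, element_b = el_b),
                            stringsAsFactors = FALSE)
    names(per_el)[3L] <- "count"
    per_el <- per_el[per_el$count > 0L, , drop = FALSE]
    rownames(per_el) <- NULL
  }
  structure(
    list(cutoff = cutoff, total_contacts = nrow(contact_list),
         per_element_contacts = per_el, contact_list = contact_list,
         identifier = model$identifier),
    class = "contact_census_result"
  )
}

#' @export
print.contact_census_result <- function(x, ...) {
  cat(sprintf("<contact_census_result> %s: %d inter-lobe contacts < %.1f A\n",
              x$identifier, x$total_contacts, x$cutoff))
  invisible(x)
}

element_label <- function(res_no, emap, side) {
  named <- if (side == "n") {
    list(p_loop = emap$p_loop, c_helix = emap$c_helix,
         beta_sheet_base = emap$beta_sheet_base)
  } else {
    list(activation_segment = emap$activation_segment, hinge = emap$hinge)
  }
  out <- rep(if (side == "n") "n_lobe_other" else "c_lobe_other",
             length(res_no))
  for (el in rev(names(named))) out[res_no %in% named[[el]]] <- el
  out
}

# Cell-list search for cross pairs (i in a_idx, j in b_idx) with distance
# strictly below cutoff. Returns a matrix [i, j, distance].
grid_cross_pairs <- function(xyz, a_idx, b_idx, cutoff) {
  if (length(a_idx) == 0L || length(b_idx) == 0L) {
    return(matrix(numeric(0), 0, 3))
  }
  cell <- floor(xyz / cutoff)
  key <- function(m) paste(m[, 1L], m[, 2L], m[, 3L], sep = ",")
  b_cells <- cell[b_idx, , drop = FALSE]
  b_map <- split(b_idx, key(b_cells))
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (i in a_idx) {
    ci <- cell[i, ]
    neigh <- sweep(offsets, 2, ci, "+")
    cand <- unlist(b_map[key(neigh)], use.names = FALSE)
    if (length(cand) == 0L) next
    d2 <- (xyz[cand, 1L] - xyz[i, 1L])^2 + (xyz[cand, 2L] - xyz[i, 2L])^2 +
          (xyz[cand, 3L] - xyz[i, 3L])^2
    hit <- which(d2 < cutoff^2)
    if (length(hit) > 0L) {
      out_i <- c(out_i, rep(i, length(hit)))
      out_j <- c(out_j, cand[hit])
      out_d <- c(out_d, sqrt(d2[hit]))
    }
  }
  cbind(out_i, out_j, out_d)
}

# ---- Hydrophobic spine assessment -----------------------------------------

#' Assess assembly of a hydrophobic spine
#'
#' For consecutive residues of the configured regulatory (R) or catalytic
#' (C) spine, computes the minimum distance between side-chain heavy
#' atoms. A link is broken when its gap exceeds `link_threshold` (or when a
#' residue lacks side-chain atoms); the spine is assembled iff no link is
#' broken.
#'
#' @param model A `structure_model`.
#' @param emap An `element_map`.
#' @param spine `"R"` or `"C"`.
#' @param link_threshold Maximum stacking gap in Angstrom (default 4.5).
#' @return `spine_assessment` with `spine`, `residue_gaps`, `assembled`,
#'   `broken_links`.
#' @export
assess_spine <- function(model, emap, spine = c("R", "C"),
                         link_threshold = 4.5) {
  spine <- match.arg(spine)
  residues <- if (spine == "R") emap$r_spine_residues else emap$c_spine_residues
  if (length(residues) < 2L) {
    stop("spine definition needs at least 2 residues", call. = FALSE)
  }
  at <- kinase_heavy_atoms(model)
  side <- function(res) {
    r <- at[at$res_no == res & !(at$atom_name %in% BACKBONE_ATOMS), ,
            drop = FALSE]
    as.matrix(r[, c("x", "y", "z")])
  }
  gaps <- numeric(length(residues) - 1L)
  for (k in seq_len(length(residues) - 1L)) {
    A <- side(residues[k]); B <- side(residues[k + 1L])
    gaps[k] <- if (nrow(A) == 0L || nrow(B) == 0L) Inf else min_cross_dist(A, B)
  }
  broken <- which(gaps > link_threshold)
  structure(
    list(spine = spine, residue_gaps = gaps,
         assembled = length(broken) == 0L,
         broken_links = data.frame(res_a = residues[broken],
                                   res_b = residues[broken + 1L],
                                   gap = gaps[broken]),
         link_threshold = link_threshold,
         residues = residues, identifier = model$identifier),
    class = "spine_assessment"
  )
}

min_cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' @export
print.spine_assessment <- function(x, ...) {
  cat(sprintf("<spine_assessment> %s-spine of %s: %s (%d/%d links intact)\n",
              x$spine, x$identifier,
              if (x$assembled) "assembled" else "broken",
              length(x$residue_gaps) - nrow(x$broken_links),
              length(x$residue_gaps)))
  invisible(x)
}

# ---- P-loop conformation --------------------------------------------------

#' Classify the P-loop tyrosine conformation
#'
#' The P-loop tyrosine (Y15) either tucks into the ATP pocket or pops out
#' to coordinate the activation-segment glutamate (E163 in CDK1). The
#' classifier measures the tyrosine hydroxyl distance to the glutamate
#' carboxylate oxygens (`d_glu`) and to a ligand-independent pocket
#' reference (`d_pocket`: centroid of gatekeeper side-chain heavy atoms
#' and hinge C-alphas). Labels: `popped_out` when `d_glu` is below
#' `coordination_threshold` and smaller than `d_pocket`; `tucked_in` when
#' the hydroxyl sits within `pocket_radius` of the pocket reference and
#' closer to it than to the glutamate; otherwise `indeterminate`.
#'
#' @param model A `structure_model`.
#' @param emap An `element_map`.
#' @param coordination_threshold Angstrom; default 3.5.
#' @param pocket_radius Angstrom; default 6.0.
#' @return `ploop_class` with `label`, `d_pocket`, `d_glu` and a `reason`
#'   when indeterminate.
#' @export
classify_ploop <- function(model, emap, coordination_threshold = 3.5,
                           pocket_radius = 6.0) {
  at <- kinase_heavy_atoms(model)
  oh <- at[at$res_no == emap$ploop_tyrosine & at$atom_name == "OH", ,
           drop = FALSE]
  carbox <- at[at$res_no == emap$activation_glutamate &
               at$atom_name %in% c("OE1", "OE2"), , drop = FALSE]
  indeterminate <- function(reason) {
    cdk_message("classify_ploop %s: indeterminate (%s)",
                model$identifier, reason)
    structure(list(label = "indeterminate", d_pocket = NA_real_,
                   d_glu = NA_real_, reason = reason),
              class = "ploop_class")
  }
  if (nrow(oh) == 0L) return(indeterminate("tyrosine OH atom missing"))
  if (nrow(carbox) == 0L) {
    return(indeterminate("glutamate carboxylate atoms missing"))
  }
  gk <- at[at$res_no == emap$gatekeeper &
           !(at$atom_name %in% BACKBONE_ATOMS), , drop = FALSE]
  hinge_ca <- at[at$res_no %in% emap$hinge & at$atom_name == "CA", ,
                 drop = FALSE]
  ref_atoms <- rbind(gk, hinge_ca)
  if (nrow(ref_atoms) == 0L) return(indeterminate("pocket reference empty"))
  ref <- colMeans(as.matrix(ref_atoms[, c("x", "y", "z")]))
  p_oh <- as.numeric(oh[1L, c("x", "y", "z")])
  d_pocket <- sqrt(sum((p_oh - ref)^2))
  d_glu <- min(sqrt(rowSums(sweep(as.matrix(carbox[, c("x", "y", "z")]),
                                  2, p_oh)^2)))
  label <- if (d_glu < coordination_threshold && d_glu < d_pocket) {
    "popped_out"
  } else if (d_pocket < pocket_radius && d_pocket < d_glu) {
    "tucked_in"
  } else {
    "indeterminate"
  }
  structure(list(label = label, d_pocket = d_pocket, d_glu = d_glu,
                 reason = NULL),
            class = "ploop_class")
}

#' @export
print.ploop_class <- function(x, ...) {
  cat(sprintf("<ploop_class> %s (d_pocket = %.2f A, d_glu = %.2f A)\n",
              x$label, x$d_pocket, x$d_glu))
  invisible(x)
}

# ---- State comparison -----------------------------------------------------

#' Rank kinase states by inter-lobe contact count
#'
#' @param censuses Named list of `contact_census_result` objects (names are
#'   state labels); all cutoffs must agree.
#' @return Data frame sorted ascending by `total_contacts` with an
#'   `is_minimum` flag (several rows flagged on a tie).
#' @export
compare_states <- function(censuses) {
  if (length(censuses) < 2L) {
    stop("need at least 2 censuses to compare", call. = FALSE)
  }
  if (is.null(names(censuses)) || any(names(censuses) == "")) {
    stop("censuses must be a named list (state labels)", call. = FALSE)
  }
  cutoffs <- vapply(censuses, function(x) x$cutoff, numeric(1))
  if (length(unique(cutoffs)) != 1L) {
    stop(errorCondition(
      sprintf("censuses computed at different cutoffs: %s",
              paste(unique(cutoffs), collapse = ", ")),
      class = c("cdkstates_incompatible_census", "error", "condition")))
  }
  tab <- data.frame(
    state = names(censuses),
    total_contacts = vapply(censuses, function(x) x$total_contacts,
                            numeric(1)),
    cutoff = cutoffs
  )
  tab <- tab[order(tab$total_contacts, tab$state), , drop = FALSE]
  tab$is_minimum <- tab$total_contacts == min(tab$total_contacts)
  rownames(tab) <- NULL
  attr(tab, "tie") <- sum(tab$is_minimum) > 1L
  tab
}
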