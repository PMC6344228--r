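# ---- StructureModel -------------------------------------------------------

#' Construct a structure model
#'
#' A `structure_model` is the package's coordinate container: an ordered
#' atom table (author residue numbering) plus an identifier and per-chain
#' role annotations. Structural metrics operate on the chain annotated with
#' role `"kinase"`.
#'
#' @param identifier Character scalar, e.g. a PDB id or a synthetic label.
#' @param atoms Data frame with columns `chain_id`, `res_no` (integer,
#'   author numbering), `ins_code`, `res_name`, `atom_name`, `element`,
#'   `x`, `y`, `z` (Angstrom), `occupancy`, `altloc`, `is_hetero`.
#' @param chain_roles Named character vector mapping chain id to one of
#'   `"kinase"`, `"cyclin"`, `"cks"`, `"ligand"`, `"other"`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(identifier, atoms, chain_roles = NULL) {
  required <- c("chain_id", "res_no", "ins_code", "res_name", "atom_name",
                "element", "x", "y", "z", "occupancy", "altloc", "is_hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  atoms <- as.data.frame(atoms)[, required]
  atoms$res_no <- as.integer(atoms$res_no)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom positions must be finite", call. = FALSE)
  }
  occ <- atoms$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1))) {
    stop("occupancy must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(chain_roles)) {
    chains <- unique(atoms$chain_id)
    chain_roles <- stats::setNames(rep("other", length(chains)), chains)
  }
  structure(
    list(identifier = identifier, atoms = atoms,
         chain_roles = chain_roles),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, %d chain(s) [%s]\n",
              x$identifier, nrow(x$atoms),
              length(unique(x$atoms$chain_id)),
              paste(sprintf("%s=%s", names(x$chain_roles), x$chain_roles),
                    collapse = ", ")))
  invisible(x)
}

#' Number of atoms in a structure model
#' @param model A `structure_model`.
#' @return Integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Kinase chain id of a structure model
#'
#' Returns the chain annotated with role "kinase"; when several chains are
#' kinases (multiple copies in the asymmetric unit) the first by chain-id
#' sort order is used and the others are ignored, never averaged.
#'
#' @param model A `structure_model`.
#' @return Single chain id.
#' @export
kinase_chain <- function(model) {
  kin <- names(model$chain_roles)[model$chain_roles == "kinase"]
  if (length(kin) == 0L) {
    stop("no chain has role 'kinase' in model '", model$identifier, "'",
         call. = FALSE)
  }
  sort(kin)[1L]
}

cdk_message <- function(...) {
  if (isTRUE(getOption("cdkstates.verbose", FALSE))) message(sprintf(...))
}

# ---- Reading --------------------------------------------------------------

#' Read macromolecular coordinates
#'
#' Reads PDB or mmCIF coordinates (via bio3d) into a [structure_model()],
#' preserving author residue numbering and applying no coordinate
#' transformation. With `filter = TRUE` (default) the standard filter is
#' applied afterwards: hydrogens removed and one altloc kept per atom site
#' (highest occupancy, ties broken lexicographically).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param filter Apply [standard_filter()] after reading.
#' @param chain_roles Optional named role vector; defaults to `"other"`.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           filter = TRUE, chain_roles = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file does not exist: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb",
      cif = "mmcif", mmcif = "mmcif",
      stop("cannot infer format from extension '", ext,
           "'; pass format explicitly", call. = FALSE))
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") {
        bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
      } else {
        bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
      }),
    error = function(e) {
      stop(sprintf("failed to parse %s as %s: %s", path, format,
                   conditionMessage(e)), call. = FALSE)
    })
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop(sprintf("failed to parse %s as %s: no ATOM/HETATM records found",
                 path, format), call. = FALSE)
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- trimws(elem)
  blank <- is.na(elem) | elem == ""
  elem[blank] <- element_from_atom_name(at$elety[blank])
  atoms <- data.frame(
    chain_id  = ifelse(is.na(at$chain), "", at$chain),
    res_no    = as.integer(at$resno),
    ins_code  = ifelse(is.na(at$insert), "", at$insert),
    res_name  = trimws(at$resid),
    atom_name = trimws(at$elety),
    element   = toupper(elem),
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o,
    altloc    = ifelse(is.na(at$alt), "", at$alt),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  model <- structure_model(id, atoms, chain_roles)
  cdk_message("read %s: %d atoms", path, nrow(atoms))
  if (filter) model <- standard_filter(model) else model
}

# Derive element symbol from a PDB atom name (first alphabetic character
# ignoring leading digits; two-letter elements in protein context are rare
# enough that the single-letter rule is used).
element_from_atom_name <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", trimws(atom_name))
  toupper(substr(nm, 1L, 1L))
}

#' Standard atom filtering
#'
#' Removes hydrogens (and deuterium) and resolves alternate locations:
#' per atom site (chain, residue number, insertion code, atom name) the
#' altloc with highest occupancy is kept; ties break lexicographically.
#'
#' @param model A `structure_model`.
#' @return Filtered `structure_model`.
#' @export
standard_filter <- function(model) {
  at <- model$atoms
  n0 <- nrow(at)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  site <- paste(at$chain_id, at$res_no, at$ins_code, at$atom_name,
                at$is_hetero, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  dup_sites <- unique(site[duplicated(site)])
  for (s in dup_sites) {
    idx <- which(site == s)
    occ <- at$occupancy[idx]
    occ[is.na(occ)] <- 0
    best <- idx[order(-occ, at$altloc[idx])][1L]
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  rownames(at) <- NULL
  cdk_message("standard_filter %s: %d atoms in, %d atoms out",
              model$identifier, n0, nrow(at))
  model$atoms <- at
  model
}

#' Subset atoms of a structure model
#'
#' Applies the conjunction of the given predicates, preserving atom order.
#'
#' @param model A `structure_model`.
#' @param chain Optional chain id; must exist in the model.
#' @param residues Optional integer vector of author residue numbers.
#' @param heavy_only Drop hydrogens.
#' @param exclude_hetero Drop HETATM records (ligands, waters, ions).
#' @return A `structure_model` containing the selection.
#' @export
select_atoms <- function(model, chain = NULL, residues = NULL,
                         heavy_only = FALSE, exclude_hetero = FALSE) {
  at <- model$atoms
  if (!is.null(chain)) {
    if (!chain %in% at$chain_id) {
      stop("chain '", chain, "' not present in model '", model$identifier,
           "'", call. = FALSE)
    }
    at <- at[at$chain_id == chain, , drop = FALSE]
  }
  if (!is.null(residues)) at <- at[at$res_no %in% residues, , drop = FALSE]
  if (heavy_only) at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  if (exclude_hetero) at <- at[!at$is_hetero, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop(errorCondition(
      sprintf("selection yielded no atoms in model '%s'", model$identifier),
      class = c("cdkstates_empty_selection", "error", "condition")))
  }
  rownames(at) <- NULL
  cdk_message("select_atoms %s: %d atoms in, %d atoms out",
              model$identifier, nrow(model$atoms), nrow(at))
  model$atoms <- at
  model
}

#' Write a structure model as PDB
#'
#' Serializes through `bio3d::write.pdb`, so output re-parses with
#' [read_structure()] field-for-field.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(
    file   = path,
    type   = ifelse(at$is_hetero, "HETATM", "ATOM"),
    xyz    = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno  = at$res_no,
    resid  = at$res_name,
    eleno  = seq_len(nrow(at)),
    elety  = at$atom_name,
    chain  = at$chain_id,
    insert = ifelse(at$ins_code == "", NA, at$ins_code),
    alt    = ifelse(at$altloc == "", NA, at$altloc),
    o      = at$occupancy,
    b      = rep(0, nrow(at)),
    elesy  = at$element
  )
  invisible(path)
}

# ---- ElementMap -----------------------------------------------------------

#' Construct a kinase element map
#'
#' Named residue ranges (author numbering, inclusive) partitioning a kinase
#' chain into the structural elements the metrics consume. Invariants: the
#' N- and C-lobes are disjoint; the P loop and C helix lie in the N-lobe;
#' the activation segment lies in the C-lobe.
#'
#' @param n_lobe,c_lobe,hinge,p_loop,c_helix,activation_segment,beta_sheet_base
#'   Integer vectors of residue numbers.
#' @param r_spine_residues,c_spine_residues Ordered integer vectors (spine
#'   stacking order, N-lobe to C-lobe).
#' @param gatekeeper,ploop_tyrosine,activation_glutamate Single residues.
#' @return An object of class `element_map`.
#' @export
element_map <- function(n_lobe, c_lobe, hinge, p_loop, c_helix,
                        activation_segment, beta_sheet_base,
                        r_spine_residues, c_spine_residues,
                        gatekeeper, ploop_tyrosine, activation_glutamate) {
  em <- list(
    n_lobe = as.integer(n_lobe), c_lobe = as.integer(c_lobe),
    hinge = as.integer(hinge), p_loop = as.integer(p_loop),
    c_helix = as.integer(c_helix),
    activation_segment = as.integer(activation_segment),
    beta_sheet_base = as.integer(beta_sheet_base),
    r_spine_residues = as.integer(r_spine_residues),
    c_spine_residues = as.integer(c_spine_residues),
    gatekeeper = as.integer(gatekeeper),
    ploop_tyrosine = as.integer(ploop_tyrosine),
    activation_glutamate = as.integer(activation_glutamate)
  )
  if (length(intersect(em$n_lobe, em$c_lobe)) > 0L) {
    stop("n_lobe and c_lobe overlap", call. = FALSE)
  }
  if (!all(em$p_loop %in% em$n_lobe)) {
    stop("p_loop must lie within n_lobe", call. = FALSE)
  }
  if (!all(em$c_helix %in% em$n_lobe)) {
    stop("c_helix must lie within n_lobe", call. = FALSE)
  }
  if (!all(em$activation_segment %in% em$c_lobe)) {
    stop("activation_segment must lie within c_lobe", call. = FALSE)
  }
  structure(em, class = "element_map")
}

#' Default element maps for CDK1 and CDK2
#'
#' Residue ranges follow the standard CDK architecture: glycine-rich P loop
#' 11-17; hinge anchored on the E81/L83 inhibitor hydrogen-bonding
#' residues; the lobe boundary places the N-lobe from the chain start to
#' the residue preceding the hinge; activation segment 146-173 (CDK1,
#' DFG to APE) or 145-172 (CDK2); gatekeeper F80; P-loop tyrosine Y15; the
#' activation-segment glutamate that a popped-out Y15 coordinates is E163
#' (CDK1) / E162 (CDK2). The C-helix span, the beta-sheet base and the
#' R-/C-spine residue lists are configuration defaults following the
#' conserved protein-kinase spine assignment (C-helix leucine L55 and the
#' DFG phenylalanine on the R-spine); all are overridable via
#' [element_map_from_config()].
#'
#' @param kinase `"CDK1"` or `"CDK2"`.
#' @return An `element_map`.
#' @export
default_element_map <- function(kinase = c("CDK1", "CDK2")) {
  if (!is.character(kinase) || !(toupper(kinase[1L]) %in% c("CDK1", "CDK2"))) {
    stop("unknown kinase '", kinase[1L], "'; expected CDK1 or CDK2",
         call. = FALSE)
  }
  kinase <- toupper(kinase[1L])
  tab <- read_element_table()
  tab <- tab[tab$kinase == kinase, , drop = FALSE]
  rng <- function(el) {
    rows <- tab[tab$element == el, , drop = FALSE]
    unlist(lapply(seq_len(nrow(rows)),
                  function(i) seq.int(rows$start[i], rows$end[i])))
  }
  element_map(
    n_lobe = rng("n_lobe"), c_lobe = rng("c_lobe"), hinge = rng("hinge"),
    p_loop = rng("p_loop"), c_helix = rng("c_helix"),
    activation_segment = rng("activation_segment"),
    beta_sheet_base = rng("beta_sheet_base"),
    r_spine_residues = rng("r_spine"),
    c_spine_residues = rng("c_spine"),
    gatekeeper = rng("gatekeeper"),
    ploop_tyrosine = rng("ploop_tyrosine"),
    activation_glutamate = rng("activation_glutamate")
  )
}

read_element_table <- function() {
  path <- system.file("extdata", "cdk_elements.tsv", package = "cdkstates")
  if (path == "") path <- file.path("inst", "extdata", "cdk_elements.tsv")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build an element map from a YAML/JSON config
#'
#' The config is keyed by kinase name, then element name; each value is an
#' inclusive `[start, end]` pair or an explicit residue list. Elements not
#' given fall back to [default_element_map()].
#'
#' @param path YAML or JSON file path.
#' @param kinase Kinase name key.
#' @return An `element_map`.
#' @export
element_map_from_config <- function(path, kinase) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg[[kinase]])) {
    stop("config has no entry for kinase '", kinase, "'", call. = FALSE)
  }
  base <- unclass(default_element_map(kinase))
  name_alias <- c(r_spine = "r_spine_residues", c_spine = "c_spine_residues")
  for (el in names(cfg[[kinase]])) {
    target <- if (el %in% names(name_alias)) name_alias[[el]] else el
    if (!target %in% names(base)) {
      stop("unknown element '", el, "' in config", call. = FALSE)
    }
    v <- unlist(cfg[[kinase]][[el]])
    base[[target]] <- if (length(v) == 2L && v[2L] >= v[1L] &&
                          !target %in% c("r_spine_residues",
                                         "c_spine_residues")) {
      seq.int(v[1L], v[2L])
    } else {
      as.integer(v)
    }
  }
  do.call(element_map, base)
}
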