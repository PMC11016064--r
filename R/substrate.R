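## Substrate preparation: building the covalent PLP external aldimine,
## annotating the atom roles the geometry core needs, and sizing the grid.
##
## Chemistry (SMILES parsing, 3D generation, pH-dependent protonation,
## MMFF94s minimization, Gasteiger charges) is delegated to Open Babel;
## molecular graphs are held in a plain atoms+bonds representation so role
## annotation and torsion-tree writing are transparent R code.

## The PLP cofactor written with the 4-position carbon ready for imine
## condensation (no aldehyde oxygen), the form used as docking input.
PLP_SMILES <- "CC1=NC=C(C(=C1O)C)COP(=O)([O-])[O-]"

#' Is Open Babel available?
#' @return TRUE when the `obabel` executable is on the PATH.
#' @export
have_openbabel <- function() nzchar(Sys.which("obabel"))

obabel <- function(args, stdin_smiles = NULL) {
  if (!have_openbabel())
    stop_plp("plpscreen_capability_error",
             "Open Babel (obabel) not found on PATH; substrate preparation needs it")
  if (!is.null(stdin_smiles)) args <- c(shQuote(paste0("-:", stdin_smiles)), args)
  out <- suppressWarnings(system2("obabel", args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0)
    stop_plp("plpscreen_build_error", "obabel failed: %s",
             paste(utils::tail(out, 3), collapse = " | "))
  out
}

## ---- molecular graphs ----------------------------------------------------

new_molgraph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

## V2000 charge codes used by the SDF atom block.
SDF_CHG <- c(`3` = 1L, `2` = 2L, `1` = 3L, `5` = -1L, `6` = -2L, `7` = -3L)

sdf_to_molgraph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  chg_col <- if ("C6" %in% colnames(ab)) ab[, "C6"] else ab[, 5]
  chg <- SDF_CHG[as.character(chg_col)]
  chg[is.na(chg)] <- 0L
  atoms <- data.frame(element = elem,
                      x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      formal_charge = as.integer(chg),
                      partial_charge = NA_real_,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  new_molgraph(atoms, bonds)
}

read_sdf_molgraph <- function(path) {
  set <- ChemmineR::read.SDFset(path)
  if (length(set) == 0)
    stop_plp("plpscreen_build_error", "no molecule in %s", path)
  sdf_to_molgraph(set[[1]])
}

molgraph_to_sdf_lines <- function(mol, title = "mol") {
  a <- mol$atoms; b <- mol$bonds
  lines <- c(title, "  plpscreen", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(b)),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     a$x, a$y, a$z, a$element),
             sprintf("%3d%3d%3d  0  0  0  0", b$from, b$to, b$order))
  chg <- which(a$formal_charge != 0)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg,
                                            a$formal_charge[chg]),
                                    collapse = "")))
  c(lines, "M  END", "$$$$")
}

smiles_to_molgraph <- function(smiles) {
  path <- tempfile(fileext = ".sdf")
  on.exit(unlink(path), add = TRUE)
  obabel(c("-osdf", "-O", path), stdin_smiles = smiles)
  if (!file.exists(path) || file.size(path) == 0)
    stop_plp("plpscreen_build_error", "unparsable SMILES: %s", smiles)
  read_sdf_molgraph(path)
}

mol_igraph <- function(mol, heavy_only = FALSE) {
  keep <- rep(TRUE, nrow(mol$atoms))
  if (heavy_only) keep <- mol$atoms$element != "H"
  b <- mol$bonds[keep[mol$bonds$from] & keep[mol$bonds$to], , drop = FALSE]
  igraph::graph_from_data_frame(b[, c("from", "to")], directed = FALSE,
                                vertices = data.frame(name = which(keep)))
}

heavy_neighbors <- function(mol, i) {
  b <- mol$bonds
  nb <- c(b$to[b$from == i], b$from[b$to == i])
  nb[mol$atoms$element[nb] != "H"]
}

all_neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$to[b$from == i], b$from[b$to == i])
}

bond_order <- function(mol, i, j) {
  b <- mol$bonds
  hit <- (b$from == i & b$to == j) | (b$from == j & b$to == i)
  if (!any(hit)) 0L else b$order[which(hit)[1]]
}

## 6-membered ring containing a given atom: cut each incident edge in turn
## and look for a length-5 alternative path between its endpoints.
ring6_through <- function(mol, atom) {
  g <- mol_igraph(mol, heavy_only = TRUE)
  vid <- match(atom, as.integer(igraph::V(g)$name))
  if (is.na(vid)) return(NULL)
  for (nb in as.integer(igraph::neighbors(g, vid))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(vid, nb)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, vid, nb)$vpath[[1]])
    if (length(sp) == 6)
      return(as.integer(igraph::V(g)$name[as.integer(sp)]))
  }
  NULL
}

## Identify the pyridoxal C4' (the exocyclic carbon of the ring position
## bearing the imine/aldehyde) from the PLP moiety's graph: the ring
## hydroxyl carbon C3 is the ring atom with a terminal oxygen; C4 is its
## ring neighbor not adjacent to the ring nitrogen; C4' hangs off C4.
plp_c4prime <- function(mol) {
  for (rn in which(mol$atoms$element == "N")) {
    ring <- ring6_through(mol, rn)
    if (is.null(ring) || !(rn %in% ring)) next
    term_o <- function(i) {
      any(vapply(heavy_neighbors(mol, i), function(j)
        mol$atoms$element[j] == "O" && length(heavy_neighbors(mol, j)) == 1,
        logical(1)))
    }
    c3 <- setdiff(ring[vapply(ring, term_o, logical(1))], rn)
    if (length(c3) != 1) next
    ring_nb_of_c3 <- intersect(heavy_neighbors(mol, c3), ring)
    n_adj <- intersect(heavy_neighbors(mol, rn), ring)
    c4 <- setdiff(ring_nb_of_c3, n_adj)
    if (length(c4) != 1) next
    c4p <- setdiff(heavy_neighbors(mol, c4), ring)
    c4p <- c4p[mol$atoms$element[c4p] == "C"]
    if (length(c4p) == 1)
      return(list(ring = ring, ring_n = rn, c3 = c3, c4 = c4, c4prime = c4p))
  }
  stop_plp("plpscreen_build_error",
           "ring detection: could not identify the pyridoxal C4' carbon")
}

## ---- substrate specification --------------------------------------------

#' Describe a substrate for aldimine construction
#'
#' @param source SMILES string or path to an SDF file.
#' @param link_nitrogen 1-based heavy-atom index (in `source` atom order)
#'   of the primary amine nitrogen to condense with PLP.
#' @param reaction_class one of `"decarboxylation"` (inspect chi1),
#'   `"aldol"` (chi2), `"alpha_h_abstraction"` (chi3), or `"aldh"`
#'   (aldehyde-dehydrogenase near-attack mode).
#' @param pubchem_id optional identifier kept as metadata only (never
#'   resolved over the network).
#' @return a `substrate_spec` list.
#' @export
substrate_spec <- function(source, link_nitrogen,
                           reaction_class = c("aldol", "decarboxylation",
                                              "alpha_h_abstraction", "aldh"),
                           pubchem_id = NULL) {
  reaction_class <- match.arg(reaction_class)
  structure(list(source = source, link_nitrogen = as.integer(link_nitrogen),
                 reaction_class = reaction_class, pubchem_id = pubchem_id),
            class = "substrate_spec")
}

inspected_chi <- function(reaction_class) {
  switch(reaction_class,
         decarboxylation = "chi1", aldol = "chi2",
         alpha_h_abstraction = "chi3",
         aldh = NA_character_)
}

#' Protonate a molecule for a given pH
#'
#' Applies Open Babel's pH transform model: at pH 7.4 carboxylic acids are
#' deprotonated, free primary amines protonated, and the PLP phosphate
#' dianionic; groups without titratable protons (e.g. quaternary ammonium)
#' are untouched.
#'
#' @param smiles molecule as a SMILES string.
#' @param ph target pH (default 7.4).
#' @return protonated molecule as a SMILES string.
#' @export
protonate_for_ph <- function(smiles, ph = 7.4) {
  out <- obabel(c("-osmi", "-p", format(ph)), stdin_smiles = smiles)
  smi <- trimws(sub("\t.*$", "", out[nzchar(out) & !grepl("converted", out)]))
  smi <- smi[nzchar(smi)]
  if (length(smi) == 0)
    stop_plp("plpscreen_build_error", "protonation produced no molecule")
  smi[1]
}

#' Maximum interatomic distance of a molecule
#'
#' @param mol a `molgraph` (or any data frame / matrix with x, y, z).
#' @return largest pairwise Euclidean distance over all atoms, angstroms.
#' @export
max_interatomic_distance <- function(mol) {
  xyz <- if (inherits(mol, "molgraph")) mol$atoms[, c("x", "y", "z")]
         else as.data.frame(mol)[, c("x", "y", "z")]
  if (nrow(xyz) == 0 || any(!is.finite(as.matrix(xyz))))
    stop_plp("plpscreen_geometry_error", "molecule lacks 3D coordinates")
  if (nrow(xyz) == 1) return(0)
  max(stats::dist(xyz))
}

## ---- aldimine construction ----------------------------------------------

#' Build the PLP external aldimine of a substrate
#'
#' Condenses the substrate's chosen primary amine with the 4-position
#' carbon of PLP into a Schiff base (C4'=N imine; a terminal aldehyde
#' oxygen on C4', if present in the PLP input, leaves as water), then
#' generates 3D coordinates, protonates for pH 7.4, minimizes with
#' MMFF94s, and assigns Gasteiger partial charges — all through Open
#' Babel.  Atom roles (pyridine ring, imine carbon, C-alpha, carboxylate
#' carbon, C-beta, H-alpha) are annotated by graph traversal and rotatable
#' bonds are detected on acyclic single bonds.
#'
#' @param spec a [substrate_spec()].
#' @param plp_smiles the PLP cofactor SMILES; the default is the docking
#'   input form with the 4-position carbon ready for condensation.
#' @param residue_code 3-letter tag used for the ligand in pose files.
#' @param ph protonation pH.
#' @param minimize_steps MMFF94s steepest-descent steps.
#' @return an `aldimine_model`: list with `atoms` (element, x, y, z,
#'   formal_charge, partial_charge, name), `bonds`, `rotatable_bonds`
#'   (two-column matrix of atom indices), `roles` (named list of atom
#'   indices; see [annotate_atom_roles()]), `residue_code`, and
#'   `maxDist`.
#' @export
build_external_aldimine <- function(spec, plp_smiles = PLP_SMILES,
                                    residue_code = "UNL", ph = 7.4,
                                    minimize_steps = 500) {
  stopifnot(inherits(spec, "substrate_spec"))
  sub <- if (file.exists(spec$source)) read_sdf_molgraph(spec$source)
         else smiles_to_molgraph(spec$source)
  plp <- smiles_to_molgraph(plp_smiles)

  ln <- spec$link_nitrogen
  if (ln < 1 || ln > nrow(sub$atoms) || sub$atoms$element[ln] != "N")
    stop_plp("plpscreen_build_error",
             "link stage: atom %d is not a nitrogen of the substrate", ln)
  if (length(heavy_neighbors(sub, ln)) != 1)
    stop_plp("plpscreen_build_error",
             "link stage: atom %d is not a primary amine nitrogen", ln)

  anchor <- plp_c4prime(plp)
  ## condensation: a terminal aldehyde O on C4' leaves as water
  ald_o <- setdiff(heavy_neighbors(plp, anchor$c4prime), anchor$c4)
  ald_o <- ald_o[plp$atoms$element[ald_o] == "O" &
                   vapply(ald_o, function(j)
                     length(heavy_neighbors(plp, j)) == 1, logical(1))]
  if (length(ald_o)) {
    keep <- setdiff(seq_len(nrow(plp$atoms)), ald_o)
    remap <- match(seq_len(nrow(plp$atoms)), keep)
    plp$atoms <- plp$atoms[keep, , drop = FALSE]
    b <- plp$bonds
    b <- b[!(b$from %in% ald_o) & !(b$to %in% ald_o), , drop = FALSE]
    b$from <- remap[b$from]; b$to <- remap[b$to]
    plp$bonds <- b
    anchor$c4prime <- remap[anchor$c4prime]
  }

  ns <- nrow(sub$atoms)
  atoms <- rbind(sub$atoms, plp$atoms)
  plp_b <- plp$bonds
  plp_b$from <- plp_b$from + ns; plp_b$to <- plp_b$to + ns
  bonds <- rbind(sub$bonds, plp_b,
                 data.frame(from = ln, to = anchor$c4prime + ns, order = 2L))
  comb <- new_molgraph(atoms, bonds)

  sdf_in <- tempfile(fileext = ".sdf"); sdf_3d <- tempfile(fileext = ".sdf")
  sdf_h <- tempfile(fileext = ".sdf"); sdf_min <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(sdf_in, sdf_3d, sdf_h, sdf_min)), add = TRUE)
  writeLines(molgraph_to_sdf_lines(comb, "aldimine"), sdf_in)
  obabel(c(sdf_in, "-O", sdf_3d, "--gen3d"))
  obabel(c(sdf_3d, "-O", sdf_h, "-p", format(ph)))
  obabel(c(sdf_h, "-O", sdf_min, "--minimize", "--ff", "MMFF94s",
           "--steps", format(minimize_steps)))
  mol <- read_sdf_molgraph(sdf_min)
  mol$atoms$partial_charge <- gasteiger_charges(sdf_min)

  roles <- annotate_atom_roles(mol)
  mol$rotatable_bonds <- rotatable_bonds(mol)
  mol$roles <- roles
  mol$residue_code <- residue_code
  mol$reaction_class <- spec$reaction_class
  mol$atoms$name <- aldimine_atom_names(mol)
  mol$maxDist <- max_interatomic_distance(mol)
  class(mol) <- c("aldimine_model", "molgraph")
  mol
}

gasteiger_charges <- function(sdf_path) {
  out <- obabel(c(sdf_path, "-omol2", "--partialcharge", "gasteiger"))
  a0 <- grep("@<TRIPOS>ATOM", out, fixed = TRUE)[1]
  sections <- grep("@<TRIPOS>", out, fixed = TRUE)
  a1 <- min(c(sections[sections > a0], length(out) + 1L))
  rows <- out[(a0 + 1):(a1 - 1)]
  fields <- strsplit(trimws(rows), "\\s+")
  fields <- fields[vapply(fields, length, integer(1)) >= 9]
  as.numeric(vapply(fields, `[`, character(1), 9))
}

#' Annotate the atom roles of an external aldimine
#'
#' Pure graph traversal from the imine linkage: the pyridine ring is the
#' 6-cycle containing the ring nitrogen; the imine carbon (PLP C4') is the
#' ring-adjacent carbon double-bonded to a non-ring nitrogen; C-alpha is
#' that nitrogen's other heavy neighbor; the carboxylate carbon is the
#' C-alpha neighbor bearing two oxygens; C-beta is the remaining carbon
#' neighbor; H-alpha are the hydrogens on C-alpha (two for glycine-like
#' substrates, both recorded).
#'
#' @param mol a `molgraph` of the aldimine (explicit hydrogens expected
#'   for `alpha_hydrogen`; absent hydrogens are reported as `NULL`).
#' @return named list of atom indices: `ring_atoms` (length 6, in ring
#'   order), `ring_nitrogen`, `imine_carbon`, `imine_nitrogen`,
#'   `alpha_carbon`, `carboxyl_carbon`, `beta_carbon` (or NULL),
#'   `alpha_hydrogen` (vector, possibly empty).
#' @export
annotate_atom_roles <- function(mol) {
  anchor <- tryCatch(plp_c4prime(mol), error = function(e)
    stop_plp("plpscreen_annotation_error",
             "role 'ring_atoms': %s", conditionMessage(e)))
  c4p <- anchor$c4prime
  imine_n <- setdiff(heavy_neighbors(mol, c4p), anchor$c4)
  imine_n <- imine_n[mol$atoms$element[imine_n] == "N" &
                       vapply(imine_n, function(j)
                         bond_order(mol, c4p, j) == 2, logical(1))]
  if (length(imine_n) != 1)
    stop_plp("plpscreen_annotation_error",
             "role 'imine_nitrogen': expected one N double-bonded to C4'")
  ca <- setdiff(heavy_neighbors(mol, imine_n), c4p)
  ca <- ca[mol$atoms$element[ca] == "C"]
  if (length(ca) != 1)
    stop_plp("plpscreen_annotation_error",
             "role 'alpha_carbon': expected one carbon on the imine nitrogen")
  nb <- setdiff(heavy_neighbors(mol, ca), imine_n)
  is_carboxyl <- vapply(nb, function(j) {
    mol$atoms$element[j] == "C" &&
      sum(mol$atoms$element[heavy_neighbors(mol, j)] == "O") >= 2
  }, logical(1))
  cooh <- nb[is_carboxyl]
  if (length(cooh) != 1)
    stop_plp("plpscreen_annotation_error",
             "role 'carboxyl_carbon': expected exactly one carboxylate on C-alpha")
  cb <- nb[!is_carboxyl & mol$atoms$element[nb] == "C"]
  cb <- if (length(cb) >= 1) cb[1] else NULL
  ha <- all_neighbors(mol, ca)
  ha <- ha[mol$atoms$element[ha] == "H"]
  list(ring_atoms = anchor$ring, ring_nitrogen = anchor$ring_n,
       imine_carbon = c4p, imine_nitrogen = imine_n,
       alpha_carbon = ca, carboxyl_carbon = cooh,
       beta_carbon = cb, alpha_hydrogen = ha)
}

## Acyclic single bonds between non-terminal heavy atoms.
rotatable_bonds <- function(mol) {
  g <- mol_igraph(mol, heavy_only = TRUE)
  bridges <- igraph::bridges(g)
  el <- igraph::as_edgelist(g)[as.integer(bridges), , drop = FALSE]
  out <- matrix(as.integer(el), ncol = 2)
  keep <- apply(out, 1, function(e) {
    bond_order(mol, e[1], e[2]) == 1 &&
      length(heavy_neighbors(mol, e[1])) >= 2 &&
      length(heavy_neighbors(mol, e[2])) >= 2
  })
  out[keep, , drop = FALSE]
}

## Stable atom names for pose files: role atoms get canonical names, the
## rest element + counter.
aldimine_atom_names <- function(mol) {
  r <- mol$roles
  nm <- rep(NA_character_, nrow(mol$atoms))
  ring <- r$ring_atoms
  ring_names <- character(6)
  ring_names[match(r$ring_nitrogen, ring)] <- "N1"
  left <- setdiff(seq_len(6), match(r$ring_nitrogen, ring))
  ring_names[left] <- paste0("C", 1 + seq_along(left))
  nm[ring] <- ring_names
  nm[r$imine_carbon] <- "C4A"
  nm[r$imine_nitrogen] <- "N"
  nm[r$alpha_carbon] <- "CA"
  nm[r$carboxyl_carbon] <- "C"
  if (!is.null(r$beta_carbon)) nm[r$beta_carbon] <- "CB"
  if (length(r$alpha_hydrogen))
    nm[r$alpha_hydrogen] <- paste0("HA", seq_along(r$alpha_hydrogen))
  todo <- which(is.na(nm))
  cnt <- list()
  for (i in todo) {
    e <- mol$atoms$element[i]
    cnt[[e]] <- (cnt[[e]] %||% 0L) + 1L
    nm[i] <- paste0(e, 10L + cnt[[e]])
  }
  nm
}

#' Role map keyed by atom name
#'
#' Translates the index-based role annotation of an `aldimine_model` into
#' the atom-name form used when matching poses read back from docking
#' output.
#'
#' @param aldimine an `aldimine_model`.
#' @return named list mirroring [annotate_atom_roles()] with atom names.
#' @export
roles_as_names <- function(aldimine) {
  nm <- aldimine$atoms$name
  r <- aldimine$roles
  list(ring_atoms = nm[r$ring_atoms],
       imine_carbon = nm[r$imine_carbon],
       imine_nitrogen = nm[r$imine_nitrogen],
       alpha_carbon = nm[r$alpha_carbon],
       carboxyl_carbon = nm[r$carboxyl_carbon],
       beta_carbon = if (is.null(r$beta_carbon)) NULL else nm[r$beta_carbon],
       alpha_hydrogen = if (length(r$alpha_hydrogen))
         nm[r$alpha_hydrogen] else character(0))
}
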