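#' Parse a PDB-format structure into a structure model
#'
#' Reads ATOM/HETATM records into a flat atom table grouped by chain.  Only
#' the first MODEL of a multi-MODEL file is kept (single-structure mode);
#' pose ensembles are read with [parse_pose_ensemble()] instead.  Parsing of
#' regular PDB files is delegated to \pkg{bio3d}.
#'
#' @param input path to a PDB file, or a character vector of PDB-format
#'   lines (anything containing a newline or more than one element is
#'   treated as text).
#' @param source_id free-text provenance tag stored on the model; defaults
#'   to the file name.
#' @return an object of class `structure_model`: a list with elements
#'   `atoms` (data frame with columns name, element, x, y, z, resname,
#'   resno, chain, occupancy, bfactor, charge, het), `source_id`, and
#'   `oligomeric_state` (number of chains).
#' @examples
#' pdb <- c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
#'          "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C")
#' m <- parse_structure(pdb)
#' m$oligomeric_state
#' @export
parse_structure <- function(input, source_id = NULL) {
  is_text <- length(input) > 1 || grepl("\n", input) ||
    grepl("^(ATOM|HETATM|HEADER|MODEL|REMARK|TER|END)", input[1])
  if (is_text) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(input, "\n")), path)
    source_id <- source_id %||% "text"
  } else {
    path <- input
    if (!file.exists(path))
      stop_plp("plpscreen_format_error", "no such file: %s", path)
    source_id <- source_id %||% basename(path)
  }
  raw <- readLines(path, warn = FALSE)
  natom <- grep("^(ATOM  |HETATM)", raw)
  if (length(natom) == 0)
    stop_plp("plpscreen_format_error",
             "no ATOM/HETATM records; first line: '%s'",
             if (length(raw)) raw[1] else "<empty>")
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop_plp("plpscreen_format_error",
                             "unparseable PDB (%s); first atom line: '%s'",
                             conditionMessage(e), raw[natom[1]]))
  a <- pdb$atom
  elem <- trimws(a$elesy)
  miss <- is.na(elem) | elem == ""
  elem[miss] <- guess_element(a$elety[miss])
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- atom_table(name = trimws(a$elety), element = elem,
                      x = a$x, y = a$y, z = a$z,
                      resname = trimws(a$resid), resno = a$resno,
                      chain = chain, occupancy = a$o, bfactor = a$b,
                      het = a$type == "HETATM")
  new_structure_model(atoms, source_id)
}

new_structure_model <- function(atoms, source_id = "model") {
  stopifnot(nrow(atoms) > 0)
  ## chain order of first appearance is preserved
  chains <- unique(atoms$chain)
  structure(list(atoms = atoms, source_id = source_id,
                 oligomeric_state = length(chains), chains = chains),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atom(s), %d chain(s) [%s]\n",
              x$source_id, nrow(x$atoms), x$oligomeric_state,
              paste(x$chains, collapse = ",")))
  invisible(x)
}

#' Write a structure model to a PDB file
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  write_atoms_pdb(model$atoms, path)
}

chain_atoms <- function(model, chain_id) {
  if (!chain_id %in% model$chains)
    stop_plp("plpscreen_lookup_error", "no chain '%s' in %s",
             chain_id, model$source_id)
  model$atoms[model$atoms$chain == chain_id, , drop = FALSE]
}

## Ordered polymer residues of a chain, in residue-number order.  A
## residue counts as polymer when it carries the N/CA/C backbone: this
## keeps modified residues recorded as HETATM (e.g. MSE, sequenced as X)
## while excluding bound ligands and waters.
chain_residues <- function(model, chain_id) {
  at <- chain_atoms(model, chain_id)
  has_bb <- vapply(split(at$name, at$resno), function(nm)
    all(c("N", "CA", "C") %in% nm), logical(1))
  resnos <- as.integer(names(has_bb))[has_bb]
  ca <- at[at$name == "CA" & at$resno %in% resnos, , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca[order(ca$resno), c("resno", "resname"), drop = FALSE]
}

#' Amino-acid sequence of a chain
#'
#' One letter per residue carrying a CA atom, in residue-number order.
#' HETATM ligand residues are excluded; residues outside the standard 20
#' (including MSE) become `X`.
#'
#' @param model a `structure_model`.
#' @param chain_id chain identifier.
#' @return single character string.
#' @export
chain_sequence <- function(model, chain_id) {
  res <- chain_residues(model, chain_id)
  paste(aa3to1(res$resname), collapse = "")
}

#' Select the best oligomer template
#'
#' Candidates are ranked by the fixed priority used when assembling
#' oligomers from repository templates: heteromers are excluded, then
#' experimental PDB entries beat repository models, more chains beat fewer,
#' and better quality (lower resolution in angstroms for PDB, higher model
#' quality score otherwise) breaks remaining ties.
#'
#' @param candidates data frame with columns `source_db` ("PDB" or
#'   "SWISS-MODEL"), `n_chains`, `is_heteromer`, `quality` (resolution in
#'   angstroms for PDB; model-quality score, higher better, for
#'   SWISS-MODEL).  Extra columns (e.g. an id) are carried through.
#' @return the selected single-row data frame.
#' @export
select_template <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0)
    stop_plp("plpscreen_selection_error", "no template candidates")
  stopifnot(all(c("source_db", "n_chains", "is_heteromer", "quality") %in%
                  names(candidates)))
  ok <- candidates[!candidates$is_heteromer, , drop = FALSE]
  if (nrow(ok) == 0)
    stop_plp("plpscreen_selection_error",
             "only heteromeric templates available; assemble manually with assemble_heteromer()")
  is_pdb <- ok$source_db == "PDB"
  ## PDB quality = resolution (lower better); model quality = score (higher
  ## better).  Negate the score so "ascending" means "better" for both.
  qual <- ifelse(is_pdb, ok$quality, -ok$quality)
  ord <- order(!is_pdb, -ok$n_chains, qual)
  ok[ord[1], , drop = FALSE]
}
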