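#' Locate the catalytic residue in every chain of a structure
#'
#' Maps an annotated catalytic position (e.g. the PLP-binding lysine from
#' the reference sequence record) onto each chain of a structure through
#' pairwise alignment, and anchors the docking grid at a named atom of the
#' matched residue (NZ for lysine, SG for cysteine).  Chains whose mapped
#' residue is not of the expected type yield no site; an enzyme with zero
#' sites is flagged for discard, mirroring the removal of set members
#' without a conserved catalytic residue.
#'
#' @param model a `structure_model`.
#' @param reference_seq the annotated reference sequence (string).
#' @param ptm_pos 1-based catalytic position in `reference_seq`.
#' @param expected_residue 3-letter code the mapped residue must match
#'   (default `"LYS"`).
#' @param anchor_atom atom label holding the grid center (default `"NZ"`;
#'   use `"SG"` with `expected_residue = "CYS"` for aldehyde
#'   dehydrogenases).
#' @return list with `sites` (data frame: chain_id, residue_number,
#'   residue_name, anchor_atom, x, y, z; one row per chain with a
#'   conserved catalytic residue) and `discard` (TRUE when no chain
#'   qualifies).
#' @export
locate_catalytic_site <- function(model, reference_seq, ptm_pos,
                                  expected_residue = "LYS",
                                  anchor_atom = "NZ") {
  if (ptm_pos < 1 || ptm_pos > nchar(reference_seq))
    stop_plp("plpscreen_value_error", "ptm_pos outside reference sequence")
  rows <- list()
  for (ch in model$chains) {
    res <- chain_residues(model, ch)
    if (nrow(res) == 0) next
    tseq <- paste(aa3to1(res$resname), collapse = "")
    pos <- map_sequence_position(reference_seq, tseq, ptm_pos)
    if (is.na(pos)) next
    hit <- res[pos, ]               # ordinal position along the chain
    if (toupper(hit$resname) != toupper(expected_residue)) next
    at <- chain_atoms(model, ch)
    anchor <- at[at$resno == hit$resno & at$name == anchor_atom &
                   !at$het, , drop = FALSE]
    if (nrow(anchor) == 0)
      stop_plp("plpscreen_incomplete_structure_error",
               "chain %s: residue %s%d lacks atom %s",
               ch, hit$resname, hit$resno, anchor_atom)
    rows[[ch]] <- data.frame(chain_id = ch, residue_number = hit$resno,
                             residue_name = hit$resname,
                             anchor_atom = anchor_atom,
                             x = anchor$x[1], y = anchor$y[1],
                             z = anchor$z[1], stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_id = character(0), residue_number = integer(0),
               residue_name = character(0), anchor_atom = character(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  rownames(sites) <- NULL
  list(sites = sites, discard = nrow(sites) == 0)
}

#' Cubic grid edge from the substrate diameter
#'
#' The docking box for a substrate-sized cubic grid is the substrate's
#' maximum interatomic distance, with a hard floor of 14 angstroms.
#'
#' @param maxDist substrate maximum interatomic distance, angstroms.
#' @param floor lower limit on the edge, angstroms.
#' @return cube edge `S = max(maxDist, floor)` in angstroms.
#' @export
grid_edge_from_maxdist <- function(maxDist, floor = 14) {
  if (!is.finite(maxDist) || maxDist < 0)
    stop_plp("plpscreen_value_error", "maxDist must be >= 0")
  max(maxDist, floor)
}

#' Build a grid specification for a catalytic site
#'
#' The grid center is the site's anchor atom (catalytic lysine NZ, or
#' cysteine SG in aldehyde-dehydrogenase mode).  Either a substrate
#' `maxDist` (giving a cube via [grid_edge_from_maxdist()]) or three
#' explicit edge lengths must be supplied.
#'
#' @param site one row of the `sites` table from
#'   [locate_catalytic_site()] (or any list with `x`, `y`, `z`).
#' @param maxDist substrate maximum interatomic distance, angstroms.
#' @param edges explicit edge lengths, length-3 numeric, angstroms
#'   (e.g. `c(11, 18, 11)` for the Aldedh-family fixed box).
#' @return list with `center` (length-3) and `edges` (length-3), class
#'   `grid_spec`.
#' @export
grid_for_site <- function(site, maxDist = NULL, edges = NULL) {
  center <- c(site$x[1], site$y[1], site$z[1])
  if (any(!is.finite(center)))
    stop_plp("plpscreen_value_error", "site has no anchor coordinates")
  if (is.null(edges)) {
    if (is.null(maxDist))
      stop_plp("plpscreen_value_error", "supply maxDist or explicit edges")
    edges <- rep(grid_edge_from_maxdist(maxDist), 3)
  } else {
    edges <- as.numeric(edges)
    if (length(edges) != 3 || any(!is.finite(edges)) || any(edges <= 0))
      stop_plp("plpscreen_value_error", "edges must be 3 positive lengths")
  }
  structure(list(center = center, edges = edges), class = "grid_spec")
}

#' Write the grid-coordinate table for an enzyme set
#'
#' One row per catalytic site: tab-separated with header
#' `structure_path, enzyme_id, chain_id, residue_number, x, y, z,
#' discard_flag` and '.' decimals, the driver table for per-chain docking
#' runs.
#'
#' @param entries list; each element has `structure_path`, `enzyme_id`,
#'   and the result of [locate_catalytic_site()] under `site`.
#' @param path output TSV path.
#' @return the written data frame, invisibly.
#' @export
write_grid_tsv <- function(entries, path) {
  rows <- lapply(entries, function(e) {
    s <- e$site
    if (s$discard)
      return(data.frame(structure_path = e$structure_path,
                        enzyme_id = e$enzyme_id, chain_id = NA_character_,
                        residue_number = NA_integer_, x = NA_real_,
                        y = NA_real_, z = NA_real_, discard_flag = TRUE))
    cbind(structure_path = e$structure_path, enzyme_id = e$enzyme_id,
          s$sites[, c("chain_id", "residue_number", "x", "y", "z")],
          discard_flag = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, dec = ".")
  invisible(out)
}

#' Read a grid-coordinate table written by [write_grid_tsv()]
#' @param path TSV path.
#' @return data frame.
#' @export
read_grid_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
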