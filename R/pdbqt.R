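## Docking-input writers: PDBQT ligand with torsion tree, and the
## substrate-metadata text file consumed by the geometry stage.

autodock_type <- function(element, bonded_to) {
  switch(element,
         H = if (any(bonded_to %in% c("N", "O"))) "HD" else "H",
         C = "C", N = "N", O = "OA", S = "SA", P = "P", element)
}

## Rigid fragments after cutting rotatable bonds; hydrogens ride along.
rigid_fragments <- function(mol) {
  rb <- mol$rotatable_bonds
  b <- mol$bonds
  cut <- rep(FALSE, nrow(b))
  if (!is.null(rb) && nrow(rb))
    for (k in seq_len(nrow(rb)))
      cut <- cut | (b$from == rb[k, 1] & b$to == rb[k, 2]) |
                   (b$from == rb[k, 2] & b$to == rb[k, 1])
  g <- igraph::graph_from_data_frame(b[!cut, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(
                                       name = seq_len(nrow(mol$atoms))))
  comp <- igraph::components(g)$membership
  split(seq_len(nrow(mol$atoms)), comp)
}

#' Write a docking-ready ligand in PDBQT format
#'
#' Emits a torsion-tree PDBQT (ROOT/BRANCH blocks at every detected
#' rotatable bond, Gasteiger charges, AutoDock atom types).  The root is
#' the rigid fragment containing the pyridine ring.
#'
#' @param aldimine an `aldimine_model` from [build_external_aldimine()].
#' @param path output path.
#' @return invisibly, a named integer vector mapping atom index in
#'   `aldimine$atoms` to the PDBQT atom serial.
#' @export
write_pdbqt_ligand <- function(aldimine, path) {
  mol <- aldimine
  frags <- rigid_fragments(mol)
  root_id <- which(vapply(frags, function(f)
    mol$roles$ring_atoms[1] %in% f, logical(1)))[1]
  rb <- mol$rotatable_bonds
  frag_of <- integer(nrow(mol$atoms))
  for (i in seq_along(frags)) frag_of[frags[[i]]] <- i

  serial_map <- integer(nrow(mol$atoms))
  lines <- character(0)
  serial <- 0L
  emit_atoms <- function(idx) {
    for (i in idx) {
      serial <<- serial + 1L
      serial_map[i] <<- serial
      a <- mol$atoms[i, ]
      nbel <- mol$atoms$element[all_neighbors(mol, i)]
      q <- if (is.null(a$partial_charge) || is.na(a$partial_charge)) 0
           else a$partial_charge
      tail <- sprintf("%10.3f %-2s", q, autodock_type(a$element, nbel))
      lines <<- c(lines, format_pdb_atom(serial, a$name, mol$residue_code,
                                         " ", 1L, a$x, a$y, a$z, 1, 0,
                                         het = TRUE, pdbqt_tail = tail))
    }
  }
  visited <- logical(length(frags))
  walk <- function(fid) {
    visited[fid] <<- TRUE
    emit_atoms(frags[[fid]])
    if (!is.null(rb) && nrow(rb)) for (k in seq_len(nrow(rb))) {
      a <- rb[k, 1]; b <- rb[k, 2]
      fa <- frag_of[a]; fb <- frag_of[b]
      child <- NULL
      if (fa == fid && !visited[fb]) child <- c(a, b, fb)
      if (fb == fid && !visited[fa]) child <- c(b, a, fa)
      if (!is.null(child)) {
        lines <<- c(lines, sprintf("BRANCH %3d %3d", serial_map[child[1]],
                                   serial + 1L))
        anchor_serial <- serial_map[child[1]]
        walk(child[3])
        lines <<- c(lines, sprintf("ENDBRANCH %3d %3d", anchor_serial,
                                   serial_map[child[2]]))
      }
    }
  }
  lines <- c(lines, "ROOT")
  walk(root_id)
  lines <- append(lines, "ENDROOT",
                  after = 1L + length(frags[[root_id]]))
  ntors <- if (is.null(rb)) 0L else nrow(rb)
  lines <- c(lines, sprintf("TORSDOF %d", ntors))
  writeLines(lines, path)
  invisible(stats::setNames(serial_map, mol$atoms$name))
}

#' Write the substrate-metadata text file
#'
#' Plain-text companion of the ligand PDBQT carrying everything the
#' geometry stage needs: the six ring atoms, the three inspected bonds,
#' the imine carbon, and the cubic grid edge.  Atom ids are PDBQT serials.
#'
#' @param aldimine an `aldimine_model`.
#' @param path output path.
#' @param serial_map mapping from atom index to PDBQT serial as returned
#'   by [write_pdbqt_ligand()]; identity when NULL.
#' @return `path`, invisibly.
#' @export
write_substrate_meta <- function(aldimine, path, serial_map = NULL) {
  r <- aldimine$roles
  sm <- if (is.null(serial_map)) seq_len(nrow(aldimine$atoms))
        else as.integer(serial_map)
  lines <- c(paste(c("RING", sm[r$ring_atoms]), collapse = " "),
             paste("BOND chi1", sm[r$alpha_carbon], sm[r$carboxyl_carbon]))
  if (!is.null(r$beta_carbon))
    lines <- c(lines, paste("BOND chi2", sm[r$alpha_carbon], sm[r$beta_carbon]))
  for (h in r$alpha_hydrogen)
    lines <- c(lines, paste("BOND chi3", sm[r$alpha_carbon], sm[h]))
  lines <- c(lines,
             paste("IMINE", sm[r$imine_carbon]),
             paste("GRID", format(grid_edge_from_maxdist(aldimine$maxDist))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a substrate-metadata text file
#' @param path metadata path.
#' @return list with `ring` (6 serials), `chi1`, `chi2`, `chi3` (2-column
#'   serial matrices; chi3 may have one row per alpha hydrogen), `imine`
#'   serial, and `grid_edge`.
#' @export
read_substrate_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  out <- list(chi1 = NULL, chi2 = NULL, chi3 = NULL)
  for (f in fields) {
    switch(f[1],
           RING = { out$ring <- as.integer(f[-1]) },
           BOND = {
             key <- f[2]
             out[[key]] <- rbind(out[[key]], as.integer(f[3:4]))
           },
           IMINE = { out$imine <- as.integer(f[2]) },
           GRID = { out$grid_edge <- as.numeric(f[2]) })
  }
  out
}
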