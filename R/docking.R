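#' Docking engine configuration
#'
#' Parameter bundle passed verbatim to the external docking engine.
#' Defaults are the screen's standard settings: 200 independent runs,
#' 5e7 evaluations, 3-angstrom pose-clustering cutoff, population 300,
#' 0.2-angstrom grid spacing.
#'
#' @param nbRuns number of independent docking runs (= poses kept).
#' @param maxEvals evaluation budget per run.
#' @param clusteringRMSDCutoff pose-clustering cutoff, angstroms.
#' @param popSize genetic-algorithm population size.
#' @param spacing grid spacing, angstroms.
#' @return a `docking_config` list.
#' @export
docking_config <- function(nbRuns = 200L, maxEvals = 5e7,
                           clusteringRMSDCutoff = 3.0, popSize = 300L,
                           spacing = 0.2) {
  vals <- list(nbRuns = as.integer(nbRuns), maxEvals = maxEvals,
               clusteringRMSDCutoff = clusteringRMSDCutoff,
               popSize = as.integer(popSize), spacing = spacing)
  if (any(vapply(vals, function(v) !is.finite(v) || v <= 0, logical(1))))
    stop_plp("plpscreen_value_error", "all docking parameters must be positive")
  structure(vals, class = "docking_config")
}

parse_pose_atoms <- function(lines) {
  ## fixed PDB columns; PDBQT appends charge + type after column 66
  nm <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resno <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  elem <- trimws(substr(lines, 77, 78))
  tailf <- trimws(substr(lines, 67, 78))
  q <- rep(0, length(lines))
  is_pdbqt <- grepl("^\\s*-?[0-9.]+\\s+\\S+$", tailf)
  if (any(is_pdbqt)) {
    parts <- strsplit(tailf[is_pdbqt], "\\s+")
    q[is_pdbqt] <- as.numeric(vapply(parts, `[`, character(1), 1))
    elem[is_pdbqt] <- sub("[0-9A-Z]$", "",
                          vapply(parts, `[`, character(1), 2))
    elem[is_pdbqt][elem[is_pdbqt] == ""] <-
      substr(vapply(parts, `[`, character(1), 2)[elem[is_pdbqt] == ""], 1, 1)
  }
  blank <- elem == "" | is.na(elem)
  elem[blank] <- guess_element(nm[blank])
  atom_table(name = nm, element = elem, x = x, y = y, z = z,
             resname = resname, resno = ifelse(is.na(resno), 1L, resno),
             chain = ifelse(chain == " ", "A", chain),
             charge = q, het = startsWith(lines, "HETATM"))
}

#' Parse a docked pose ensemble
#'
#' Reads a multi-MODEL PDB or multi-pose PDBQT file into a `pose_ensemble`.
#' Each MODEL block must carry an energy remark (`REMARK ... affinity: <e>`
#' or an engine summary line `REMARK ... FEB: <e>`); ligand atoms are
#' separated from flexible-receptor atoms by residue code.
#'
#' @param path ensemble file.
#' @param ligand_code 3-letter residue code of the ligand (default: the
#'   most frequent HETATM residue code in the file).
#' @return a `pose_ensemble`: list of `poses` (each with `ligand`, `flex`
#'   atom tables, `energy`, `run_index`) plus `ligand_code`.
#' @export
parse_pose_ensemble <- function(path, ligand_code = NULL) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    ## single-pose file: treat the whole file as one block
    starts <- 1L; ends <- length(lines)
  } else {
    ends_all <- grep("^ENDMDL", lines)
    if (length(ends_all) < length(starts))
      stop_plp("plpscreen_parse_error",
               "truncated ensemble: pose %d has no ENDMDL", length(starts))
    ends <- ends_all[seq_along(starts)]
  }
  poses <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    erem <- grep("^REMARK.*(affinity|FEB|Binding energy)", block,
                 ignore.case = TRUE, value = TRUE)
    if (length(erem) == 0)
      stop_plp("plpscreen_parse_error", "pose %d: missing energy remark", k)
    energy <- as.numeric(sub(".*?(-?[0-9]+\\.?[0-9]*)\\s*$", "\\1", erem[1]))
    if (is.na(energy))
      stop_plp("plpscreen_parse_error", "pose %d: unreadable energy remark", k)
    at_lines <- block[grepl("^(ATOM  |HETATM)", block)]
    if (length(at_lines) == 0)
      stop_plp("plpscreen_parse_error", "pose %d: no atoms", k)
    atoms <- parse_pose_atoms(at_lines)
    if (is.null(ligand_code)) {
      het <- atoms$resname[atoms$het]
      ligand_code <- if (length(het)) names(sort(table(het),
                                                 decreasing = TRUE))[1]
                     else atoms$resname[1]
    }
    is_lig <- atoms$resname == ligand_code
    poses[[k]] <- list(ligand = atoms[is_lig, , drop = FALSE],
                       flex = atoms[!is_lig, , drop = FALSE],
                       energy = energy, run_index = k)
  }
  if (length(poses) == 0)
    stop_plp("plpscreen_format_error", "zero poses in %s", path)
  structure(list(poses = poses, ligand_code = ligand_code,
                 source = path), class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  e <- vapply(x$poses, `[[`, numeric(1), "energy")
  cat(sprintf("pose_ensemble: %d pose(s), ligand '%s', energy %.2f .. %.2f\n",
              length(x$poses), x$ligand_code, min(e), max(e)))
  invisible(x)
}

#' Write a pose ensemble in the pinned multi-MODEL PDB dialect
#'
#' One MODEL block per pose with `REMARK affinity: <energy>`, ligand
#' atoms as HETATM under the ligand residue code, flexible-residue atoms
#' as ATOM records.  [parse_pose_ensemble()] reads this dialect back
#' bit-exactly to the format's 3-decimal coordinate precision.
#'
#' @param ensemble a `pose_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pose_ensemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in ensemble$poses) {
    writeLines(c(sprintf("MODEL %8d", p$run_index),
                 sprintf("REMARK affinity: %.3f", p$energy)), con)
    lig <- p$ligand
    writeLines(mapply(format_pdb_atom, seq_len(nrow(lig)), lig$name,
                      lig$resname, lig$chain, lig$resno, lig$x, lig$y,
                      lig$z, lig$occupancy, lig$bfactor, lig$element,
                      TRUE, USE.NAMES = FALSE), con)
    if (nrow(p$flex)) {
      fl <- p$flex
      writeLines(mapply(format_pdb_atom,
                        nrow(lig) + seq_len(nrow(fl)), fl$name,
                        fl$resname, fl$chain, fl$resno, fl$x, fl$y, fl$z,
                        fl$occupancy, fl$bfactor, fl$element, FALSE,
                        USE.NAMES = FALSE), con)
    }
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Run the external docking engine (adapter)
#'
#' Thin adapter around an ADFR-style command-line docking engine.  The
#' engine is treated as a black box: inputs are written, the command is
#' invoked with the configuration verbatim, and the pose output is read
#' back with [parse_pose_ensemble()].  Every downstream stage also accepts
#' ensembles from files or from [make_pose_ensemble()], so the engine is
#' fully optional.
#'
#' @param receptor_path receptor file (PDB/PDBQT).
#' @param ligand_path ligand PDBQT from [write_pdbqt_ligand()].
#' @param grid a `grid_spec`.
#' @param config a [docking_config()].
#' @param engine path to the engine executable (default `adfr` on PATH).
#' @param out_dir working directory for engine output.
#' @return a `pose_ensemble`.
#' @export
run_engine <- function(receptor_path, ligand_path, grid,
                       config = docking_config(),
                       engine = Sys.which("adfr"), out_dir = tempdir()) {
  if (is.null(engine) || !nzchar(engine) || !file.exists(engine))
    stop_plp("plpscreen_capability_error",
             "docking engine not found; use fixture mode (make_pose_ensemble) or pass engine=")
  for (f in c(receptor_path, ligand_path))
    if (!file.exists(f))
      stop_plp("plpscreen_value_error", "missing input: %s", f)
  out_file <- file.path(out_dir, "poses.pdbqt")
  args <- engine_args(receptor_path, ligand_path, grid, config, out_file)
  status <- system2(engine, args, stdout = file.path(out_dir, "engine.log"),
                    stderr = file.path(out_dir, "engine.log"))
  if (status != 0)
    stop_plp("plpscreen_engine_error", "engine exited %d; log: %s", status,
             file.path(out_dir, "engine.log"))
  parse_pose_ensemble(out_file)
}

engine_args <- function(receptor_path, ligand_path, grid, config, out_file) {
  c("--receptor", receptor_path, "--ligand", ligand_path,
    "--center", sprintf("%.3f", grid$center),
    "--size", sprintf("%.3f", grid$edges),
    "--nbRuns", format(config$nbRuns),
    "--maxEvals", format(config$maxEvals, scientific = FALSE),
    "--clusteringRMSDCutoff", format(config$clusteringRMSDCutoff),
    "--popSize", format(config$popSize),
    "--spacing", format(config$spacing),
    "--out", out_file)
}

#' Read a key=value screen configuration file
#'
#' The configuration file carries the substrate PDBQT path, the metadata
#' path, the grid-coordinate TSV, and the [docking_config()] fields in
#' plain `key = value` form.
#'
#' @param path configuration file.
#' @return list with character paths and a `config` element.
#' @export
read_screen_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(f) trimws(f[2])),
                          vapply(kv, function(f) trimws(f[1]), character(1)))
  num <- function(k, d) if (!is.null(vals[[k]])) as.numeric(vals[[k]]) else d
  cfg <- docking_config(nbRuns = num("nbRuns", 200),
                        maxEvals = num("maxEvals", 5e7),
                        clusteringRMSDCutoff = num("clusteringRMSDCutoff", 3),
                        popSize = num("popSize", 300),
                        spacing = num("spacing", 0.2))
  list(substrate = vals[["substrate"]], metadata = vals[["metadata"]],
       coords = vals[["coords"]], config = cfg)
}
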