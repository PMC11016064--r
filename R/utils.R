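## Internal helpers shared across modules.

stop_plp <- function(class, msg, ...) {
  stop(structure(class = c(class, "plpscreen_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

## Standard 3-letter -> 1-letter amino acid table.  Non-standard residues
## (including MSE) deliberately map to "X".
AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

aa3to1 <- function(res3) {
  out <- AA321[toupper(res3)]
  out[is.na(out)] <- "X"
  unname(out)
}

## Minimal atom table constructor used throughout: one row per atom.
atom_table <- function(name, element, x, y, z,
                       resname = "UNK", resno = 1L, chain = "A",
                       occupancy = 1, bfactor = 0, charge = 0,
                       het = FALSE) {
  data.frame(name = as.character(name), element = as.character(element),
             x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
             resname = as.character(resname), resno = as.integer(resno),
             chain = as.character(chain),
             occupancy = as.numeric(occupancy), bfactor = as.numeric(bfactor),
             charge = as.numeric(charge), het = as.logical(het),
             stringsAsFactors = FALSE)
}

coords_of <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

## Guess the element from a PDB atom name when the element column is blank.
guess_element <- function(name) {
  nm <- gsub("[0-9' ]", "", toupper(name))
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")
  ifelse(substr(nm, 1, 2) %in% two, substr(nm, 1, 2), substr(nm, 1, 1))
}

## PDB-format ATOM/HETATM line (also the coordinate core of PDBQT lines).
format_pdb_atom <- function(serial, name, resname, chain, resno, x, y, z,
                            occupancy = 1, bfactor = 0, element = "",
                            het = FALSE, pdbqt_tail = NULL) {
  rec <- ifelse(het, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
  line <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  rec, serial, nm, resname, chain, resno, x, y, z,
                  occupancy, bfactor, element)
  if (!is.null(pdbqt_tail)) line <- paste0(substr(line, 1, 66), pdbqt_tail)
  line
}

write_atoms_pdb <- function(atoms, path = NULL, serial0 = 0L) {
  lines <- character(0)
  serial <- serial0
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    serial <- serial + seq_len(nrow(sub))
    lines <- c(lines, mapply(format_pdb_atom, serial, sub$name, sub$resname,
                             sub$chain, sub$resno, sub$x, sub$y, sub$z,
                             sub$occupancy, sub$bfactor, sub$element,
                             sub$het, USE.NAMES = FALSE),
               "TER")
    serial <- max(serial)
  }
  if (is.null(path)) return(lines)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
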