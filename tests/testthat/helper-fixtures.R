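## Small structure/pose builders shared across test files.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     het = FALSE, element = substr(name, 1, 1)) {
  rec <- if (het) "HETATM" else "ATOM  "
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, resname, chain, resno, x, y, z, 1, 0, element)
}

## Text of a toy chain: backbone N/CA/C (+O) per residue along x.
toy_chain_lines <- function(res3, chain = "A", serial0 = 0, z = 0,
                            resno = seq_along(res3)) {
  lines <- character(0); s <- serial0
  for (i in seq_along(res3)) {
    x0 <- 1.5 * (i - 1)
    y0 <- 2.3 * sin(i * 100 * pi / 180)    # helix-like, non-collinear CAs
    z0 <- z + 2.3 * cos(i * 100 * pi / 180)
    for (at in list(c("N", -0.8, 0.5), c("CA", 0, 0), c("C", 0.9, 0.6),
                    c("O", 1.1, 1.7))) {
      s <- s + 1
      lines <- c(lines, pdb_line(s, at[1], res3[i], chain, resno[i],
                                 x0 + as.numeric(at[2]),
                                 y0 + as.numeric(at[3]), z0))
    }
  }
  lines
}

## A pose built directly from an atom placement list, for hand-constructed
## clustering/geometry cases.  `shift` translates the whole fixture ligand.
shifted_pose <- function(shift, energy, run_index, chi = c(0.3, 0.95, 0.4),
                         d = 4) {
  base <- plpscreen:::fixture_pose_atoms(chi, d)
  lig <- base$ligand; flex <- base$flex
  lig$x <- lig$x + shift[1]; lig$y <- lig$y + shift[2]; lig$z <- lig$z + shift[3]
  flex$x <- flex$x + shift[1]; flex$y <- flex$y + shift[2]
  flex$z <- flex$z + shift[3]
  list(ligand = lig, flex = flex, energy = energy, run_index = run_index)
}

as_ensemble <- function(poses) {
  structure(list(poses = poses, ligand_code = "LIG", source = "test"),
            class = "pose_ensemble")
}

## Random synthetic pose (uniform geometry, not necessarily chemical) for
## property tests: a jittered hexagon plus chain atoms in random directions.
random_pose <- function(run_index = 1L) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), rnorm(6, 0, 0.05))
  ca <- c(4.2, 0, 0) + rnorm(3, 0, 0.3)
  rnd_dir <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
  cooh <- ca + 1.52 * rnd_dir(); cb <- ca + 1.52 * rnd_dir()
  ha <- ca + 1.09 * rnd_dir()
  c4a <- c(2.9, 0, 0); n <- c(3.6, 0.4, 0)
  lig <- plpscreen:::atom_table(
    name = c("N1", "C2", "C3", "C4", "C5", "C6", "C4A", "N", "CA", "C",
             "CB", "HA1"),
    element = c("N", "C", "C", "C", "C", "C", "C", "N", "C", "C", "C", "H"),
    x = c(ring[, 1], c4a[1], n[1], ca[1], cooh[1], cb[1], ha[1]),
    y = c(ring[, 2], c4a[2], n[2], ca[2], cooh[2], cb[2], ha[2]),
    z = c(ring[, 3], c4a[3], n[3], ca[3], cooh[3], cb[3], ha[3]),
    resname = "LIG", resno = 1L, chain = "B", het = TRUE)
  nz <- c4a + runif(1, 2, 8) * rnd_dir()
  flex <- plpscreen:::atom_table(name = "NZ", element = "N",
                                 x = nz[1], y = nz[2], z = nz[3],
                                 resname = "LYS", resno = 5L, chain = "A")
  list(ligand = lig, flex = flex, energy = round(rnorm(1, -7), 3),
       run_index = run_index)
}
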