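test_that("parse_structure reads toy PDBs and counts chains", {
  lines <- toy_chain_lines(c("GLY", "ALA", "LYS"))
  m <- parse_structure(lines)
  expect_s3_class(m, "structure_model")
  expect_equal(m$oligomeric_state, 1)
  expect_equal(nrow(m$atoms), 12)

  dimer <- c(toy_chain_lines(c("GLY", "ALA"), chain = "A"), "TER",
             toy_chain_lines(c("GLY", "ALA"), chain = "B", serial0 = 8,
                             z = 6))
  expect_equal(parse_structure(dimer)$oligomeric_state, 2)
})

test_that("parse_structure rejects atomless input naming the first line", {
  err <- expect_error(parse_structure("HEADER    ONLY A HEADER"),
                      class = "plpscreen_format_error")
  expect_match(conditionMessage(err), "HEADER")
})

test_that("chain_sequence reads CA-bearing residues, excludes ligands, maps MSE to X", {
  lines <- toy_chain_lines(c("GLY", "ALA", "LYS"))
  m <- parse_structure(lines)
  expect_equal(chain_sequence(m, "A"), "GAK")

  with_lig <- c(lines,
                pdb_line(90, "P", "PLP", "A", 99, 1, 2, 3, het = TRUE),
                pdb_line(91, "O1", "PLP", "A", 99, 2, 2, 3, het = TRUE))
  expect_equal(chain_sequence(parse_structure(with_lig), "A"), "GAK")

  mse <- toy_chain_lines(c("GLY", "MSE", "LYS"))
  expect_equal(chain_sequence(parse_structure(mse), "A"), "GXK")

  expect_error(chain_sequence(m, "Z"), class = "plpscreen_lookup_error")
})

test_that("map_sequence_position carries positions through the alignment", {
  expect_equal(map_sequence_position("MAKKLG", "AKKLG", 4), 3)
  for (p in c(1, 3, 6))
    expect_equal(map_sequence_position("MAKKLG", "MAKKLG", p), p)
  ## deletion swallowing the mapped residue: oracle = independent affine
  ## DP on the same instance
  expect_identical(nw_map_position("MAKKLG", "MAG", 4), NA_integer_)
  expect_true(is.na(map_sequence_position("MAKKLG", "MAG", 4)))
  expect_error(map_sequence_position("MAKKLG", "MAG", 9),
               class = "plpscreen_value_error")
})

test_that("position mapping agrees with an independent DP oracle and round-trips", {
  set.seed(11)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:20) {
    q <- paste(sample(alphabet, 30, replace = TRUE), collapse = "")
    ## target: q with a random deletion and a random substitution
    tchars <- strsplit(q, "")[[1]]
    tchars <- tchars[-sample(30, 3)]
    t <- paste(tchars, collapse = "")
    p <- sample(30, 1)
    got <- map_sequence_position(q, t, p)
    if (!is.na(got)) {
      back <- map_sequence_position(t, q, got)
      expect_equal(back, p)
    }
  }
})

test_that("kabsch_superpose recovers exact rigid motions", {
  set.seed(1)
  pts <- matrix(rnorm(15), 5, 3)
  same <- kabsch_superpose(pts, pts)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)

  R <- rot_z(pi / 2); shift <- c(1, 0, 0)
  ref <- sweep(pts %*% t(R), 2, shift, "+")
  fit <- kabsch_superpose(pts, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, shift, tolerance = 1e-9)
})

test_that("kabsch matches the quaternion oracle and is rigid-motion invariant", {
  set.seed(7)
  for (rep in 1:10) {
    a <- matrix(rnorm(12), 4, 3)
    b <- a; b[1, ] <- b[1, ] + rnorm(3, 0, 0.3)   # one perturbed point
    fit <- kabsch_superpose(a, b)
    oracle <- quaternion_superpose(a, b)
    expect_equal(fit$rmsd, oracle$rmsd, tolerance = 1e-9)
    expect_true(abs(det(fit$rotation) - 1) < 1e-9)

    R <- random_rotation(); t <- rnorm(3, 0, 5)
    a2 <- sweep(a %*% t(R), 2, t, "+")
    b2 <- sweep(b %*% t(R), 2, t, "+")
    expect_equal(kabsch_superpose(a2, b2)$rmsd, fit$rmsd, tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "plpscreen_geometry_error")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line),
               class = "plpscreen_geometry_error")
})

test_that("select_template honors source, chain count, and quality priority", {
  cand <- data.frame(id = c("pdb_dimer", "sm_dimer"),
                     source_db = c("PDB", "SWISS-MODEL"),
                     n_chains = c(2, 2), is_heteromer = FALSE,
                     quality = c(2.5, 0.9))
  expect_equal(select_template(cand)$id, "pdb_dimer")

  cand2 <- data.frame(id = c("mono", "tetra"), source_db = "PDB",
                      n_chains = c(1, 4), is_heteromer = FALSE,
                      quality = c(1.8, 2.9))
  expect_equal(select_template(cand2)$id, "tetra")

  cand3 <- data.frame(id = c("d20", "d25"), source_db = "PDB",
                      n_chains = 2, is_heteromer = FALSE,
                      quality = c(2.0, 2.5))
  expect_equal(select_template(cand3)$id, "d20")

  het <- data.frame(id = "h", source_db = "PDB", n_chains = 2,
                    is_heteromer = TRUE, quality = 2)
  expect_error(select_template(het), class = "plpscreen_selection_error")
  expect_error(select_template(het[0, ]),
               class = "plpscreen_selection_error")
  ## heteromers excluded before any other criterion
  mix <- rbind(het, data.frame(id = "sm_mono", source_db = "SWISS-MODEL",
                               n_chains = 1, is_heteromer = FALSE,
                               quality = 0.8))
  expect_equal(select_template(mix)$id, "sm_mono")
})

test_that("assemble_oligomer reproduces a self-template arrangement", {
  seq15 <- c("GLY", "ALA", "SER", "LYS", "LEU", "VAL", "THR", "ALA",
             "GLY", "GLU", "ASP", "PHE", "TYR", "ILE", "ASN")
  seq60 <- rep(seq15, 4)
  mono <- parse_structure(toy_chain_lines(seq60))
  ## template: the monomer and a copy rotated 180 degrees about z, shifted
  at <- mono$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rot_z(pi))
  at2 <- at
  at2$x <- xyz[, 1] + 30; at2$y <- xyz[, 2]; at2$z <- xyz[, 3]
  at2$chain <- "B"
  template <- plpscreen:::new_structure_model(rbind(at, at2), "tmpl")

  asm <- assemble_oligomer(mono, template, min_length = 30)
  expect_equal(asm$oligomeric_state, 2)
  expect_true(all(attr(asm, "rmsd") < 1e-6))
  expect_equal(as.matrix(asm$atoms[, c("x", "y", "z")]),
               as.matrix(template$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)

  ## monomeric template: output is the superposed monomer
  asm1 <- assemble_oligomer(mono, mono, min_length = 30)
  expect_equal(asm1$oligomeric_state, 1)
  expect_true(attr(asm1, "rmsd")[["A"]] < 1e-9)

  ## unalignable template chain errors, naming the chain
  other <- parse_structure(toy_chain_lines(rep(c("TRP", "PRO", "HIS"), 20),
                                           chain = "B"))
  err <- expect_error(assemble_oligomer(mono, other, min_length = 30),
                      class = "plpscreen_assembly_error")
  expect_match(conditionMessage(err), "chain B")
})

test_that("locate_catalytic_site maps the annotated lysine per chain", {
  toy <- make_toy_complex("lysine")
  ## dimer: duplicate the toy chain as B
  at <- toy$receptor$atoms
  atB <- at; atB$chain <- "B"; atB$z <- atB$z + 20
  dimer <- plpscreen:::new_structure_model(rbind(at, atB), "dimer")
  got <- locate_catalytic_site(dimer, toy$reference_seq, toy$ptm_pos)
  expect_false(got$discard)
  expect_equal(nrow(got$sites), 2)
  expect_setequal(got$sites$chain_id, c("A", "B"))
  expect_equal(got$sites$residue_name, c("LYS", "LYS"))

  ## non-conserved catalytic residue: mapped position is ARG -> discard
  atR <- at
  atR$resname[atR$resno == 5] <- "ARG"
  atR <- atR[!(atR$resno == 5 & atR$name %in% c("CB", "CG", "CD", "CE", "NZ")), ]
  noK <- plpscreen:::new_structure_model(atR, "noK")
  got2 <- locate_catalytic_site(noK, toy$reference_seq, toy$ptm_pos)
  expect_true(got2$discard)
  expect_equal(nrow(got2$sites), 0)

  ## aldehyde-dehydrogenase mode anchors at the cysteine SG
  cys <- make_toy_complex("cysteine")
  got3 <- locate_catalytic_site(cys$receptor, cys$reference_seq, 5,
                                expected_residue = "CYS", anchor_atom = "SG")
  expect_equal(got3$sites$anchor_atom, "SG")

  ## conserved lysine with the anchor atom stripped -> structural error
  atN <- at[!(at$resno == 5 & at$name == "NZ"), ]
  noNZ <- plpscreen:::new_structure_model(atN, "noNZ")
  expect_error(locate_catalytic_site(noNZ, toy$reference_seq, toy$ptm_pos),
               class = "plpscreen_incomplete_structure_error")
})

test_that("grid placement centers on the anchor and honors the 14 A floor", {
  site <- data.frame(x = 1, y = 2, z = 3)
  g <- grid_for_site(site, maxDist = 10)
  expect_equal(g$center, c(1, 2, 3))
  expect_equal(g$edges, c(14, 14, 14))
  g2 <- grid_for_site(site, edges = c(11, 18, 11))
  expect_equal(g2$edges, c(11, 18, 11))
  expect_error(grid_for_site(site, edges = c(0, 18, 11)),
               class = "plpscreen_value_error")
  expect_error(grid_edge_from_maxdist(-1), class = "plpscreen_value_error")
})

test_that("grid TSV round-trips with discard flags", {
  toy <- make_toy_complex("lysine")
  entries <- list(
    list(structure_path = "a.pdb", enzyme_id = "E1", site = toy$site),
    list(structure_path = "b.pdb", enzyme_id = "E2",
         site = list(discard = TRUE)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grid_tsv(entries, path)
  back <- read_grid_tsv(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$enzyme_id, c("E1", "E2"))
  expect_equal(back$discard_flag, c(FALSE, TRUE))
  expect_equal(back$x[1], toy$site$sites$x[1])
})
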