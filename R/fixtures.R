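## Seeded synthetic fixtures: toy receptor sites, pose ensembles with
## controlled chi angles / catalytic distances / energies / cluster
## structure, labeled screen fixtures, and noisy kinetics data.  All
## generators are pure functions of (spec, seed): the global RNG state is
## saved and restored, so identical inputs give byte-identical output.

with_seed <- function(seed, expr) {
  if (is.null(seed))
    stop_plp("plpscreen_value_error", "a seed is mandatory for fixtures")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Role map of the fixture aldimine ligand
#'
#' The synthetic ligand uses fixed atom names: pyridine ring N1/C2..C6,
#' imine carbon C4A, imine nitrogen N, C-alpha CA, carboxylate C,
#' C-beta CB, alpha hydrogen HA1.
#'
#' @return named list in the [roles_as_names()] layout.
#' @export
fixture_roles <- function() {
  list(ring_atoms = c("N1", "C2", "C3", "C4", "C5", "C6"),
       imine_carbon = "C4A", imine_nitrogen = "N",
       alpha_carbon = "CA", carboxyl_carbon = "C",
       beta_carbon = "CB", alpha_hydrogen = "HA1",
       aldehyde_carbon = "C4A")
}

#' Minimal receptor with a known catalytic site
#'
#' A short, deterministic single-chain peptide with a catalytic lysine
#' (NZ anchor) or cysteine (SG anchor) at position 5 of nine residues.
#' Both kinds share the same backbone and differ only at the catalytic
#' residue.
#'
#' @param site_kind `"lysine"` or `"cysteine"`.
#' @return list with `receptor` (`structure_model`), `reference_seq`,
#'   `ptm_pos`, and `site` (result of [locate_catalytic_site()]).
#' @export
make_toy_complex <- function(site_kind = c("lysine", "cysteine")) {
  site_kind <- match.arg(site_kind)
  res3 <- c("GLY", "ALA", "SER", "GLY",
            if (site_kind == "lysine") "LYS" else "CYS",
            "ALA", "GLY", "SER", "ALA")
  rows <- list()
  for (i in seq_along(res3)) {
    x0 <- 3.8 * (i - 1)
    y0 <- 0.3 * (i %% 2)      # mild zig-zag
    rows[[length(rows) + 1]] <-
      atom_table(name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
                 x = x0 + c(-0.8, 0, 0.9, 1.1),
                 y = y0 + c(0.5, 0, 0.6, 1.7), z = c(0.2, 0, -0.2, -0.3),
                 resname = res3[i], resno = i, chain = "A")
    if (res3[i] == "LYS")
      rows[[length(rows) + 1]] <-
        atom_table(name = c("CB", "CG", "CD", "CE", "NZ"),
                   element = c("C", "C", "C", "C", "N"),
                   x = x0, y = y0 + c(1.5, 2.8, 4.1, 5.4, 6.7),
                   z = c(0.3, 0.1, 0.4, 0.2, 0.5),
                   resname = "LYS", resno = i, chain = "A")
    if (res3[i] == "CYS")
      rows[[length(rows) + 1]] <-
        atom_table(name = c("CB", "SG"), element = c("C", "S"),
                   x = x0, y = y0 + c(1.5, 3.0), z = c(0.3, 0.4),
                   resname = "CYS", resno = i, chain = "A")
  }
  receptor <- new_structure_model(do.call(rbind, rows),
                                  paste0("toy_", site_kind))
  reference_seq <- paste(aa3to1(res3), collapse = "")
  site <- locate_catalytic_site(receptor, reference_seq, 5,
                                expected_residue = if (site_kind == "lysine")
                                  "LYS" else "CYS",
                                anchor_atom = if (site_kind == "lysine")
                                  "NZ" else "SG")
  list(receptor = receptor, reference_seq = reference_seq, ptm_pos = 5L,
       site = site)
}

#' Specify a synthetic pose ensemble
#'
#' @param clusters list; each element a list with `n` (members),
#'   `shift` (cluster displacement: scalar along x or length-3 vector,
#'   angstroms), `energy_mean`, `energy_sd` (kcal/mol), `chi` (length-3
#'   |sin(chi)| targets in \[0, 1\]), `d` (imine-C to NZ distance,
#'   angstroms), and optionally `cfc_prob` (per-member probability of
#'   the favorable `chi`/`d` geometry; otherwise `chi_alt`/`d_alt` are
#'   used, defaults `c(0.9, 0.2, 0.4)` and `d`).
#' @param seed mandatory integer seed.
#' @param n_poses total poses; must equal the sum of cluster sizes.
#' @return an `ensemble_spec` list.
#' @export
ensemble_spec <- function(clusters, seed,
                          n_poses = sum(vapply(clusters, `[[`, numeric(1),
                                               "n"))) {
  if (missing(seed) || is.null(seed))
    stop_plp("plpscreen_value_error", "seed is mandatory")
  tot <- sum(vapply(clusters, `[[`, numeric(1), "n"))
  if (tot != n_poses)
    stop_plp("plpscreen_value_error",
             "cluster sizes sum to %d, not n_poses = %d", tot, n_poses)
  clusters <- lapply(clusters, function(cl) {
    cl$chi <- as.numeric(cl$chi)
    if (length(cl$chi) != 3 || any(!is.finite(cl$chi)) ||
        any(cl$chi < 0) || any(cl$chi > 1))
      stop_plp("plpscreen_feasibility_error",
               "chi targets must be three values in [0, 1]")
    if (length(cl$shift %||% 0) == 1) cl$shift <- c(cl$shift %||% 0, 0, 0)
    cl$d <- cl$d %||% 4
    cl$energy_mean <- cl$energy_mean %||% -7
    cl$energy_sd <- cl$energy_sd %||% 0.5
    cl$chi_alt <- cl$chi_alt %||% c(0.9, 0.2, 0.4)
    cl$d_alt <- cl$d_alt %||% cl$d
    cl
  })
  structure(list(clusters = clusters, n_poses = n_poses, seed = seed),
            class = "ensemble_spec")
}

## Constructive pose geometry: ring in the z = 0 plane, all chain atoms
## placed so each C-alpha bond makes exactly the requested |sin(chi)|
## with the ring plane.
fixture_pose_atoms <- function(chi, d, ligand_code = "LIG") {
  ang <- seq(0, by = pi / 3, length.out = 6)
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  c4 <- ring[1, ]
  c4a <- c4 + c(1.50, 0, 0)
  n <- c4a + c(1.28, 0, 0)
  ca <- n + c(1.47, 0, 0)
  place <- function(s, azimuth, len) {
    u <- c(cos(azimuth), sin(azimuth), 0)
    dir <- sqrt(1 - s^2) * u + s * c(0, 0, 1)
    ca + len * dir
  }
  cooh <- place(chi[1], pi / 2, 1.52)
  cb <- place(chi[2], 7 * pi / 6, 1.52)
  ha <- place(chi[3], 11 * pi / 6, 1.09)
  lig <- atom_table(
    name = c("N1", "C2", "C3", "C4", "C5", "C6", "C4A", "N", "CA",
             "C", "CB", "HA1"),
    element = c("N", "C", "C", "C", "C", "C", "C", "N", "C", "C", "C", "H"),
    x = c(ring[c(4, 5, 6, 1, 2, 3), 1], c4a[1], n[1], ca[1],
          cooh[1], cb[1], ha[1]),
    y = c(ring[c(4, 5, 6, 1, 2, 3), 2], c4a[2], n[2], ca[2],
          cooh[2], cb[2], ha[2]),
    z = c(ring[c(4, 5, 6, 1, 2, 3), 3], c4a[3], n[3], ca[3],
          cooh[3], cb[3], ha[3]),
    resname = ligand_code, resno = 1L, chain = "B",
    charge = c(-0.25, 0.1, 0.1, 0.05, 0.05, 0.05, 0.2, -0.3, 0.1,
               0.35, 0.05, 0.05),
    het = TRUE)
  nz_dir <- c(0, 0.8, 0.6)
  nz <- c4a + d * nz_dir
  flex <- atom_table(name = c("CE", "NZ"), element = c("C", "N"),
                     x = c(nz[1] - 1.0, nz[1]), y = c(nz[2], nz[2]),
                     z = c(nz[3] - 1.0, nz[3]),
                     resname = "LYS", resno = 5L, chain = "A",
                     charge = c(0.1, -0.3))
  list(ligand = lig, flex = flex)
}

#' Generate a synthetic docked pose ensemble
#'
#' For each cluster the base pose is built constructively so the three
#' C-alpha bonds achieve the requested |sin(chi)| values exactly and the
#' imine-carbon-to-NZ distance equals `d`; members are jittered by a
#' rigid translation (< 0.9 angstroms) plus 0.02-angstrom atomic noise,
#' well inside the 3-angstrom clustering cutoff, and energies are drawn
#' from the stated normal distributions.  With `cfc_prob`, members
#' switch between the favorable and alternative geometry independently.
#'
#' @param spec an [ensemble_spec()].
#' @param origin translation applied to every pose (e.g. a site anchor).
#' @param path optional output file; when given, the ensemble is also
#'   written with [write_pose_ensemble()].
#' @param ligand_code ligand residue code in pose files.
#' @return a `pose_ensemble` (with attribute `path` when written).
#' @export
make_pose_ensemble <- function(spec, origin = c(0, 0, 0), path = NULL,
                               ligand_code = "LIG") {
  stopifnot(inherits(spec, "ensemble_spec"))
  with_seed(spec$seed, {
    poses <- list()
    run <- 0L
    for (cl in spec$clusters) {
      energies <- stats::rnorm(cl$n, cl$energy_mean, cl$energy_sd)
      use_fav <- if (is.null(cl$cfc_prob) || is.na(cl$cfc_prob))
        rep(TRUE, cl$n) else stats::runif(cl$n) < cl$cfc_prob
      for (j in seq_len(cl$n)) {
        run <- run + 1L
        base <- if (use_fav[j])
          fixture_pose_atoms(cl$chi, cl$d, ligand_code)
        else fixture_pose_atoms(cl$chi_alt, cl$d_alt, ligand_code)
        dirv <- stats::rnorm(3); dirv <- dirv / vnorm(dirv)
        trans <- origin + cl$shift + stats::runif(1, 0, 0.9) * dirv
        jig <- function(at) {
          at$x <- at$x + trans[1] + stats::rnorm(nrow(at), 0, 0.02)
          at$y <- at$y + trans[2] + stats::rnorm(nrow(at), 0, 0.02)
          at$z <- at$z + trans[3] + stats::rnorm(nrow(at), 0, 0.02)
          at
        }
        poses[[run]] <- list(ligand = jig(base$ligand),
                             flex = jig(base$flex),
                             energy = round(energies[j], 3),
                             run_index = run)
      }
    }
    ens <- structure(list(poses = poses, ligand_code = ligand_code,
                          source = "synthetic"), class = "pose_ensemble")
    if (!is.null(path)) {
      write_pose_ensemble(ens, path)
      attr(ens, "path") <- path
    }
    ens
  })
}

#' Generate a labeled synthetic screen
#'
#' Emulates a validation screen: every enzyme gets a pose ensemble with
#' three well-separated clusters; the first is the catalytic candidate,
#' whose members adopt the favorable (inspected-bond-perpendicular,
#' d = 4) geometry with a probability that depends on the enzyme label.
#' Positives are enriched according to `effect`:
#' `"extreme"` (0.9 vs 0), `"moderate"` (0.6 vs 0.4), `"none"` (0.3 vs
#' 0.3), or a numeric `c(p_pos, p_neg)`.  The full pipeline (clustering,
#' CFC classification, scoring) is run on each ensemble.
#'
#' @param n_enzymes,n_positives screen size and number of positives.
#' @param effect effect level (see above).
#' @param seed mandatory integer seed.
#' @param n_poses poses per enzyme (default 200).
#' @param rule scoring rule (default aldol, chi2, per-pose gate).
#' @param aa_energies also compute amino-acid-only energies against the
#'   toy receptor (fills LCaaE/BCaaE; slower).
#' @param dir optional directory; when given, `scores.tsv` and
#'   `labels.tsv` are written there.
#' @return list with `scores` (a [score_table()] data frame), `labels`
#'   (enzyme_id, is_positive, category), and `rule`.
#' @export
make_screen_fixture <- function(n_enzymes, n_positives,
                                effect = c("moderate", "extreme", "none"),
                                seed, n_poses = 200, rule = cfc_rule(),
                                aa_energies = FALSE, dir = NULL) {
  if (n_positives <= 0 || n_positives >= n_enzymes)
    stop_plp("plpscreen_value_error",
             "need 0 < n_positives < n_enzymes")
  p <- if (is.numeric(effect)) effect
       else switch(match.arg(effect),
                   extreme = c(0.9, 0), moderate = c(0.6, 0.4),
                   none = c(0.3, 0.3))
  roles <- fixture_roles()
  toy <- if (aa_energies) make_toy_complex("lysine") else NULL
  aa_names <- c("N", "CA", "C", "CB", "HA1")
  with_seed(seed, {
    ids <- sprintf("E%03d", seq_len(n_enzymes))
    pos_ids <- sample(ids, n_positives)
    sub_seeds <- sample.int(1e6, n_enzymes)
    scores <- vector("list", n_enzymes)
    for (i in seq_len(n_enzymes)) {
      is_pos <- ids[i] %in% pos_ids
      n1 <- round(n_poses * 0.5)
      n2 <- round(n_poses * 0.3)
      n3 <- n_poses - n1 - n2
      spec <- ensemble_spec(list(
        list(n = n1, shift = 0, energy_mean = -8, energy_sd = 0.6,
             chi = c(0.3, 0.95, 0.4), d = 4,
             cfc_prob = if (is_pos) p[1] else p[2],
             chi_alt = c(0.9, 0.2, 0.4), d_alt = 7),
        list(n = n2, shift = 12, energy_mean = -7.2, energy_sd = 0.6,
             chi = c(0.9, 0.2, 0.4), d = 7),
        list(n = n3, shift = 24, energy_mean = -6.5, energy_sd = 0.6,
             chi = c(0.2, 0.3, 0.9), d = 7)),
        seed = sub_seeds[i])
      ens <- make_pose_ensemble(spec)
      clusters <- cluster_poses(ens, cutoff = 3)
      cfc <- cfc_table(ens, roles, rule,
                       clusters = if (rule$distance_gate == "cluster_mean")
                         clusters else NULL)
      aaE <- NULL
      if (aa_energies) {
        rec <- toy$receptor$atoms
        rec$charge <- rep_len(c(0.1, -0.1), nrow(rec))
        aaE <- vapply(ens$poses, function(pp) {
          sub <- pp$ligand[pp$ligand$name %in% aa_names, , drop = FALSE]
          aa_interaction_energy(sub, rec)
        }, numeric(1))
        names(aaE) <- vapply(ens$poses, `[[`, integer(1), "run_index")
      }
      scores[[i]] <- score_enzyme(clusters, cfc, rule,
                                  enzyme_id = ids[i], chain_id = "A",
                                  aa_energy = aaE)
    }
    labels <- data.frame(enzyme_id = ids,
                         is_positive = ids %in% pos_ids,
                         category = ifelse(ids %in% pos_ids,
                                           "aldolase", "other"),
                         stringsAsFactors = FALSE)
    tab <- score_table(scores)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(tab, file.path(dir, "scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(scores = tab, labels = labels, rule = rule)
  })
}

#' Noisy Michaelis-Menten dataset
#'
#' `v = kcat * S / (Km + S)` plus seeded Gaussian noise.
#'
#' @param kcat,Km generating parameters (1/s, mM).
#' @param S_levels substrate concentrations, mM.
#' @param noise_sd Gaussian noise SD on v.
#' @param seed mandatory integer seed.
#' @param replicates replicates per level.
#' @return a [kinetic_dataset()].
#' @export
make_mm_data <- function(kcat, Km, S_levels, noise_sd = 0, seed,
                         replicates = 1) {
  if (kcat <= 0 || Km <= 0)
    stop_plp("plpscreen_value_error", "kcat and Km must be positive")
  with_seed(seed, {
    S <- rep(S_levels, each = replicates)
    v <- kcat * S / (Km + S) + stats::rnorm(length(S), 0, noise_sd)
    kinetic_dataset(S, v)
  })
}
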