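## Geometry core: ring-plane fitting, bond-to-plane angles (chi), the
## catalytic distance, and the catalytically-favorable-conformation (CFC)
## classification.

#' Least-squares plane through the six pyridine-ring atoms
#'
#' Fits the best plane by singular value decomposition of the centered
#' coordinates: the normal is the direction of smallest variance.  The
#' normal sign is canonicalized so its first nonzero component is
#' positive; |sin(chi)| is insensitive to this choice.
#'
#' @param ring_coords 6 x 3 matrix of ring-atom coordinates.
#' @return list of class `plane_eq` with unit `normal` (A, B, C) and
#'   `offset` D, for the plane Ax + By + Cz = D.
#' @export
fit_ring_plane <- function(ring_coords) {
  xyz <- as.matrix(ring_coords)
  if (nrow(xyz) != 6 || ncol(xyz) != 3 || any(!is.finite(xyz)))
    stop_plp("plpscreen_geometry_error", "need a finite 6 x 3 coordinate matrix")
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  if (sv$d[2] < 1e-8)
    stop_plp("plpscreen_geometry_error", "ring atoms are collinear")
  n <- sv$v[, 3]
  nz <- which(abs(n) > 1e-12)[1]
  if (n[nz] < 0) n <- -n
  structure(list(normal = n, offset = sum(n * ctr)), class = "plane_eq")
}

#' |sin(chi)|: sine of the angle between a bond and the ring plane
#'
#' For plane normal (A, B, C) and bond direction (a, b, c):
#' `|Aa + Bb + Cc| / (sqrt(a^2+b^2+c^2) * sqrt(A^2+B^2+C^2))`.
#' 1 means the bond is orthogonal to the plane (parallel to the ring's
#' pi system, the Dunathan-labile orientation); 0 means it lies in the
#' plane.
#'
#' @param plane a `plane_eq` (or list with `normal`).
#' @param bond bond direction vector (length 3), or a `bond_vector`.
#' @return value in \[0, 1\].
#' @export
sin_chi <- function(plane, bond) {
  v <- if (is.list(bond)) bond$direction else as.numeric(bond)
  nv <- vnorm(v)
  if (!is.finite(nv) || nv == 0)
    stop_plp("plpscreen_value_error", "zero-length bond vector")
  n <- plane$normal
  abs(sum(n * v)) / (nv * vnorm(n))
}

#' Bond direction from C-alpha to a bonded atom
#' @param from_xyz,to_xyz coordinates (length-3).
#' @param from_atom,to_atom optional atom labels carried along.
#' @return a `bond_vector` with `direction = to - from`.
#' @export
bond_vector <- function(from_xyz, to_xyz, from_atom = NA, to_atom = NA) {
  d <- as.numeric(to_xyz) - as.numeric(from_xyz)
  if (vnorm(d) == 0)
    stop_plp("plpscreen_value_error", "coincident atoms give a zero bond")
  structure(list(direction = d, from_atom = from_atom, to_atom = to_atom),
            class = "bond_vector")
}

pose_atom_xyz <- function(atoms, name, what) {
  i <- which(atoms$name == name)
  if (length(i) == 0)
    stop_plp("plpscreen_geometry_error", "missing %s atom '%s' in pose",
             what, name)
  as.numeric(atoms[i[1], c("x", "y", "z")])
}

## Ideal tetrahedral H-alpha reconstruction: opposite to the sum of the
## unit vectors toward C-alpha's three heavy neighbors.
reconstruct_halpha <- function(ca, heavy_xyz, bond_length = 1.09) {
  u <- sapply(heavy_xyz, function(p) {
    d <- as.numeric(p) - ca; d / vnorm(d)
  })
  s <- -rowSums(u)
  if (vnorm(s) < 1e-8)
    stop_plp("plpscreen_geometry_error",
             "degenerate neighbor geometry; cannot reconstruct H-alpha")
  ca + bond_length * s / vnorm(s)
}

#' Compute the chi angle triplet of a docked pose
#'
#' Fits the PLP ring plane from the pose's ring atoms and evaluates
#' |sin(chi)| for the three C-alpha bonds: chi1 to the carboxylate
#' carbon, chi2 to C-beta, chi3 to H-alpha.  A missing C-beta (glycine)
#' is recorded as `NA`; a missing H-alpha is reconstructed at the ideal
#' tetrahedral position from the three heavy neighbors when
#' `reconstruct_h = TRUE` (the result is flagged).  When two alpha
#' hydrogens are present, chi3 is the larger of the two |sin| values.
#'
#' @param pose a pose (list with `ligand` atom table) or a bare atom
#'   table.
#' @param roles role map keyed by atom name, as from [roles_as_names()].
#' @param reconstruct_h reconstruct a missing H-alpha?
#' @return list of class `chi_triplet`: `sin_chi1`, `sin_chi2`,
#'   `sin_chi3` (each in \[0, 1\] or NA when the bond is absent), and
#'   `h_reconstructed` flag.
#' @export
chi_triplet <- function(pose, roles, reconstruct_h = TRUE) {
  atoms <- if (is.data.frame(pose)) pose else pose$ligand
  ring <- t(vapply(roles$ring_atoms, function(nm)
    pose_atom_xyz(atoms, nm, "ring"), numeric(3)))
  plane <- fit_ring_plane(ring)
  ca <- pose_atom_xyz(atoms, roles$alpha_carbon, "alpha-carbon")
  s1 <- sin_chi(plane, bond_vector(ca,
          pose_atom_xyz(atoms, roles$carboxyl_carbon, "carboxylate")))
  s2 <- NA_real_
  if (!is.null(roles$beta_carbon) && length(roles$beta_carbon))
    s2 <- sin_chi(plane, bond_vector(ca,
            pose_atom_xyz(atoms, roles$beta_carbon, "beta-carbon")))
  h_rec <- FALSE
  ha_names <- roles$alpha_hydrogen
  ha_present <- ha_names[ha_names %in% atoms$name]
  if (length(ha_present)) {
    s3 <- max(vapply(ha_present, function(nm)
      sin_chi(plane, bond_vector(ca, pose_atom_xyz(atoms, nm, "alpha-H"))),
      numeric(1)))
  } else if (reconstruct_h) {
    heavy <- list(pose_atom_xyz(atoms, roles$imine_nitrogen, "imine-N"),
                  pose_atom_xyz(atoms, roles$carboxyl_carbon, "carboxylate"))
    if (!is.null(roles$beta_carbon) && length(roles$beta_carbon))
      heavy <- c(heavy, list(pose_atom_xyz(atoms, roles$beta_carbon,
                                           "beta-carbon")))
    if (length(heavy) < 3)
      stop_plp("plpscreen_geometry_error",
               "cannot reconstruct H-alpha with fewer than 3 heavy neighbors")
    s3 <- sin_chi(plane, bond_vector(ca, reconstruct_halpha(ca, heavy)))
    h_rec <- TRUE
  } else {
    stop_plp("plpscreen_geometry_error", "missing role atom alpha-hydrogen")
  }
  structure(list(sin_chi1 = s1, sin_chi2 = s2, sin_chi3 = s3,
                 h_reconstructed = h_rec), class = "chi_triplet")
}

#' Catalytic distance of a pose
#'
#' PLP mode: distance between the flexible catalytic lysine's NZ and the
#' aldimine imine carbon.  ALDH mode: distance between the receptor
#' cysteine SG and the substrate aldehyde carbon.  Flexible-residue
#' coordinates from the pose are preferred; the rigid receptor's anchor
#' is used as fallback.
#'
#' @param pose pose with `ligand` and `flex` atom tables.
#' @param roles role map keyed by atom name (needs `imine_carbon`, or
#'   `aldehyde_carbon` in ALDH mode).
#' @param mode `"PLP"` or `"ALDH"`.
#' @param anchor_xyz rigid-receptor anchor coordinates (length 3), used
#'   when the pose has no flexible-residue copy of the anchor atom.
#' @param anchor_atom anchor atom name (`"NZ"` or `"SG"`).
#' @return distance in angstroms.
#' @export
catalytic_distance <- function(pose, roles, mode = c("PLP", "ALDH"),
                               anchor_xyz = NULL, anchor_atom = NULL) {
  mode <- match.arg(mode)
  anchor_atom <- anchor_atom %||% if (mode == "PLP") "NZ" else "SG"
  lig_role <- if (mode == "PLP") roles$imine_carbon else roles$aldehyde_carbon
  if (is.null(lig_role))
    stop_plp("plpscreen_geometry_error", "role map lacks the ligand anchor atom")
  lig <- pose_atom_xyz(pose$ligand, lig_role, "ligand-anchor")
  flex <- pose$flex
  a <- NULL
  if (!is.null(flex) && nrow(flex) && anchor_atom %in% flex$name)
    a <- pose_atom_xyz(flex, anchor_atom, "flexible-anchor")
  if (is.null(a)) {
    if (is.null(anchor_xyz))
      stop_plp("plpscreen_geometry_error",
               "no flexible %s in pose and no receptor anchor given",
               anchor_atom)
    a <- as.numeric(anchor_xyz)
  }
  vnorm(lig - a)
}

#' CFC classification rule
#'
#' @param mode `"PLP"` (Dunathan chi criterion + catalytic distance) or
#'   `"ALDH"` (near-attack distance only).
#' @param inspected which chi the reaction cleaves (`"chi1"`
#'   decarboxylation, `"chi2"` aldol, `"chi3"` alpha-H abstraction);
#'   PLP mode only.
#' @param distance_cutoff angstroms; defaults 5 (PLP) or 3.5 (ALDH).
#' @param distance_gate `"per_pose"` (each pose's own distance must be
#'   <= cutoff) or `"cluster_mean"` (the catalytic cluster's mean
#'   distance must be < cutoff).
#' @return a `cfc_rule` list.
#' @export
cfc_rule <- function(mode = c("PLP", "ALDH"),
                     inspected = c("chi2", "chi1", "chi3"),
                     distance_cutoff = NULL,
                     distance_gate = c("per_pose", "cluster_mean")) {
  mode <- match.arg(mode)
  inspected <- match.arg(inspected)
  distance_gate <- match.arg(distance_gate)
  cutoff <- distance_cutoff %||% if (mode == "PLP") 5.0 else 3.5
  if (cutoff <= 0)
    stop_plp("plpscreen_value_error", "distance cutoff must be positive")
  structure(list(mode = mode,
                 inspected = if (mode == "PLP") inspected else NA_character_,
                 distance_cutoff = cutoff, distance_gate = distance_gate),
            class = "cfc_rule")
}

#' Classify a conformation as catalytically favorable or not
#'
#' PLP mode: the inspected bond's |sin(chi)| must be strictly greater
#' than every other available |sin(chi)| (exact ties are conservatively
#' not CFC), and the distance gate must pass — per pose (`d <= cutoff`)
#' or on the catalytic cluster mean (`mean d < cutoff`).  ALDH mode: a
#' near-attack conformation, `d <= cutoff` (default 3.5 angstroms), with
#' no chi condition.
#'
#' @param chi a `chi_triplet` (ignored in ALDH mode).
#' @param d catalytic distance of the pose, angstroms.
#' @param rule a [cfc_rule()].
#' @param cluster_mean_d mean catalytic distance of the pose's cluster;
#'   required when `rule$distance_gate == "cluster_mean"`.
#' @return list of class `cfc_result`: `chi`, `d`, `is_cfc`.
#' @export
classify_cfc <- function(chi, d, rule, cluster_mean_d = NULL) {
  if (rule$mode == "ALDH") {
    return(structure(list(chi = chi, d = d, is_cfc = d <= rule$distance_cutoff),
                     class = "cfc_result"))
  }
  sins <- c(chi1 = chi$sin_chi1, chi2 = chi$sin_chi2, chi3 = chi$sin_chi3)
  ins <- sins[[rule$inspected]]
  if (is.na(ins))
    stop_plp("plpscreen_value_error", "inspected %s absent from triplet",
             rule$inspected)
  others <- sins[setdiff(names(sins), rule$inspected)]
  others <- others[!is.na(others)]
  chi_ok <- all(ins > others)
  gate_ok <- if (rule$distance_gate == "per_pose") {
    d <= rule$distance_cutoff
  } else {
    if (is.null(cluster_mean_d))
      stop_plp("plpscreen_usage_error",
               "cluster_mean gate needs cluster_mean_d")
    cluster_mean_d < rule$distance_cutoff
  }
  structure(list(chi = chi, d = d, is_cfc = chi_ok && gate_ok),
            class = "cfc_result")
}

#' Per-pose CFC table for an ensemble
#'
#' Applies [chi_triplet()], [catalytic_distance()] and [classify_cfc()]
#' to every pose.  With the `cluster_mean` gate, cluster assignments are
#' needed to evaluate the gate; pass `clusters` from [cluster_poses()].
#'
#' @param ensemble a `pose_ensemble`.
#' @param roles role map keyed by atom name.
#' @param rule a [cfc_rule()].
#' @param anchor_xyz rigid-receptor anchor (see [catalytic_distance()]).
#' @param clusters optional cluster list for the `cluster_mean` gate.
#' @return data frame: run_index, sin_chi1..3, d, is_cfc.
#' @export
cfc_table <- function(ensemble, roles, rule = cfc_rule(),
                      anchor_xyz = NULL, clusters = NULL) {
  n <- length(ensemble$poses)
  chis <- vector("list", n); d <- numeric(n)
  for (k in seq_len(n)) {
    p <- ensemble$poses[[k]]
    chis[[k]] <- if (rule$mode == "PLP") chi_triplet(p, roles) else NULL
    d[k] <- catalytic_distance(p, roles, rule$mode, anchor_xyz)
  }
  mean_d_of <- rep(NA_real_, n)
  if (rule$distance_gate == "cluster_mean") {
    if (is.null(clusters))
      stop_plp("plpscreen_usage_error",
               "cluster_mean gate needs clusters=")
    runs <- vapply(ensemble$poses, `[[`, integer(1), "run_index")
    for (cl in clusters) {
      idx <- match(cl$member_runs, runs)
      mean_d_of[idx] <- mean(d[idx])
    }
  }
  is_cfc <- logical(n)
  for (k in seq_len(n))
    is_cfc[k] <- classify_cfc(chis[[k]], d[k], rule, mean_d_of[k])$is_cfc
  data.frame(run_index = vapply(ensemble$poses, `[[`, integer(1),
                                "run_index"),
             sin_chi1 = vapply(chis, function(x)
               if (is.null(x)) NA_real_ else x$sin_chi1, numeric(1)),
             sin_chi2 = vapply(chis, function(x)
               if (is.null(x)) NA_real_ else x$sin_chi2 %||% NA_real_,
               numeric(1)),
             sin_chi3 = vapply(chis, function(x)
               if (is.null(x)) NA_real_ else x$sin_chi3, numeric(1)),
             d = d, is_cfc = is_cfc)
}
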