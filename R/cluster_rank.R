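## Pose clustering by ligand RMSD, cluster metrics (best / largest /
## catalytic cluster), and enzyme ranking.

#' Ligand RMSD between two poses
#'
#' Coordinate RMSD over the shared heavy atoms of the ligand, matched by
#' atom name, without re-superposition (all poses of a run share the
#' receptor frame).
#'
#' @param poseA,poseB poses (lists with `ligand` atom tables) or bare
#'   atom tables.
#' @param heavy_only drop hydrogens before matching (default TRUE).
#' @return RMSD in angstroms.
#' @export
ligand_rmsd <- function(poseA, poseB, heavy_only = TRUE) {
  a <- if (is.data.frame(poseA)) poseA else poseA$ligand
  b <- if (is.data.frame(poseB)) poseB else poseB$ligand
  if (heavy_only) {
    a <- a[a$element != "H", , drop = FALSE]
    b <- b[b$element != "H", , drop = FALSE]
  }
  m <- match(a$name, b$name)
  if (any(is.na(m)) || nrow(a) != nrow(b))
    stop_plp("plpscreen_pairing_error",
             "ligand atom sets differ between poses")
  sqrt(mean(rowSums((coords_of(a) - coords_of(b)[m, , drop = FALSE])^2)))
}

#' Cluster a pose ensemble by ligand RMSD
#'
#' Greedy energy-ordered leader clustering: poses are visited by
#' ascending energy; each pose joins the first existing cluster whose
#' leader (its lowest-energy member) lies within the cutoff, otherwise
#' it founds a new cluster.  Deterministic and standard for docking
#' output.
#'
#' @param ensemble a `pose_ensemble`.
#' @param cutoff clustering RMSD cutoff, angstroms (default 3).
#' @return list of `pose_cluster`s ordered by founding (ascending leader
#'   energy); each has `member_runs`, `size`, `best_energy`,
#'   `mean_energy`, `leader_run`.
#' @export
cluster_poses <- function(ensemble, cutoff = 3.0) {
  poses <- ensemble$poses
  if (length(poses) == 0)
    stop_plp("plpscreen_usage_error", "empty ensemble")
  e <- vapply(poses, `[[`, numeric(1), "energy")
  ord <- order(e)
  leaders <- integer(0)           # pose indices of cluster leaders
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(leaders)) {
      if (ligand_rmsd(poses[[leaders[ci]]], poses[[i]]) <= cutoff) {
        members[[ci]] <- c(members[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      members[[length(leaders)]] <- i
    }
  }
  lapply(seq_along(leaders), function(ci) {
    idx <- members[[ci]]
    structure(list(
      member_runs = vapply(poses[idx], `[[`, integer(1), "run_index"),
      size = length(idx),
      best_energy = min(e[idx]),
      mean_energy = mean(e[idx]),
      leader_run = poses[[leaders[ci]]]$run_index), class = "pose_cluster")
  })
}

## AutoDock4-flavored Lennard-Jones parameters: Rii (sum of radii at the
## minimum, angstroms) and epsii (well depth, kcal/mol), per element.
LJ_TABLE <- data.frame(
  element = c("C", "N", "O", "S", "P", "H"),
  Rii = c(4.00, 3.50, 3.20, 4.00, 4.20, 2.00),
  epsii = c(0.150, 0.160, 0.200, 0.200, 0.200, 0.020))

lj_params <- function(elements, table = LJ_TABLE) {
  m <- match(elements, table$element)
  m[is.na(m)] <- 1L   # unparameterized elements fall back to carbon
  table[m, c("Rii", "epsii")]
}

#' Nonbonded interaction energy of an atom subset against a receptor
#'
#' Self-contained pairwise scorer used for the amino-acid-only cluster
#' energies (aaE metrics): a 12-6 Lennard-Jones term with per-element
#' parameters combined by arithmetic mean (radii) and geometric mean
#' (well depths), plus a Coulomb term with the distance-dependent
#' dielectric eps(r) = 4r, over all pairs within the cutoff.
#'
#' @param subset_atoms ligand-side atom table (with `element` and
#'   `charge` columns) — typically the amino-acid atoms of the aldimine,
#'   PLP excluded.
#' @param receptor_atoms receptor atom table with charges.
#' @param cutoff pair-distance cutoff, angstroms (default 8).
#' @param lj include the Lennard-Jones term (disable for analytic
#'   Coulomb checks).
#' @param lj_table per-element parameter table (columns element, Rii,
#'   epsii), replaceable for engine parity.
#' @return energy in kcal/mol.
#' @export
aa_interaction_energy <- function(subset_atoms, receptor_atoms, cutoff = 8,
                                  lj = TRUE, lj_table = LJ_TABLE) {
  if (nrow(subset_atoms) == 0)
    stop_plp("plpscreen_scoring_error", "empty atom subset")
  if (anyNA(subset_atoms$charge) || anyNA(receptor_atoms$charge))
    stop_plp("plpscreen_scoring_error", "partial charges missing")
  A <- coords_of(subset_atoms); B <- coords_of(receptor_atoms)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  within <- d > 0 & d <= cutoff
  if (!any(within)) return(0)
  qq <- outer(subset_atoms$charge, receptor_atoms$charge)
  ## Coulomb, kcal/mol, distance-dependent dielectric eps(r) = 4r
  e_coul <- sum(332.0637 * qq[within] / (4 * d[within]^2))
  e_lj <- 0
  if (lj) {
    pa <- lj_params(subset_atoms$element, lj_table)
    pb <- lj_params(receptor_atoms$element, lj_table)
    rij <- outer(pa$Rii, pb$Rii, "+") / 2
    eij <- sqrt(outer(pa$epsii, pb$epsii))
    rr <- (rij[within] / d[within])^6
    e_lj <- sum(eij[within] * (rr^2 - 2 * rr))
  }
  e_coul + e_lj
}

#' Score one active site from its clusters and CFC table
#'
#' Identifies the best cluster (BC, lowest best energy), largest cluster
#' (LC, most members) and catalytic cluster (CC, most CFC poses; ties
#' broken toward lower best energy, so with no CFC anywhere CC falls
#' back to BC) and assembles the seven ranking metrics: LCC/BCC (cluster
#' sizes), LCE/BCE (best energies), LCaaE/BCaaE (best amino-acid-only
#' energies, when `aa_energy` is supplied), and CC_CFC (CFC count of the
#' catalytic cluster).  CC means of the inspected |sin(chi)|, the
#' catalytic distance, and the energy are attached as `cc_stats`.
#'
#' @param clusters list from [cluster_poses()].
#' @param cfc data frame from [cfc_table()].
#' @param rule the [cfc_rule()] used (names the inspected chi).
#' @param enzyme_id,chain_id identifiers carried into the score row.
#' @param aa_energy optional named numeric: per-pose amino-acid-only
#'   energy indexed by run_index (names), for the aaE metrics.
#' @return an `enzyme_score` list.
#' @export
score_enzyme <- function(clusters, cfc, rule = cfc_rule(),
                         enzyme_id = "enzyme", chain_id = "A",
                         aa_energy = NULL) {
  if (length(clusters) == 0)
    stop_plp("plpscreen_usage_error", "no clusters")
  cfc_of_run <- stats::setNames(cfc$is_cfc, cfc$run_index)
  d_of_run <- stats::setNames(cfc$d, cfc$run_index)
  ins_col <- if (rule$mode == "ALDH") NULL
             else switch(rule$inspected,
                         chi1 = "sin_chi1", chi2 = "sin_chi2",
                         chi3 = "sin_chi3")
  sin_of_run <- if (!is.null(ins_col) && ins_col %in% names(cfc))
    stats::setNames(cfc[[ins_col]], cfc$run_index) else NULL
  covered <- vapply(clusters, function(cl)
    all(as.character(cl$member_runs) %in% names(cfc_of_run)), logical(1))
  if (!all(covered))
    stop_plp("plpscreen_usage_error",
             "clusters and CFC table cover different runs")
  n_cfc <- vapply(clusters, function(cl)
    sum(cfc_of_run[as.character(cl$member_runs)]), numeric(1))
  best_e <- vapply(clusters, `[[`, numeric(1), "best_energy")
  sizes <- vapply(clusters, `[[`, numeric(1), "size")
  bc <- which.min(best_e)
  lc <- which.max(sizes)
  cc_cand <- which(n_cfc == max(n_cfc))
  cc <- cc_cand[which.min(best_e[cc_cand])]
  best_aa <- function(cl) {
    if (is.null(aa_energy)) return(NA_real_)
    min(aa_energy[as.character(cl$member_runs)])
  }
  cc_runs <- as.character(clusters[[cc]]$member_runs)
  structure(list(
    enzyme_id = enzyme_id, chain_id = chain_id,
    metrics = list(LCC = sizes[lc], BCC = sizes[bc],
                   LCE = best_e[lc], BCE = best_e[bc],
                   LCaaE = best_aa(clusters[[lc]]),
                   BCaaE = best_aa(clusters[[bc]]),
                   CC_CFC = n_cfc[cc]),
    cc_stats = list(
      mean_sin_inspected = if (is.null(sin_of_run)) NA_real_
                           else mean(sin_of_run[cc_runs]),
      mean_d = mean(d_of_run[cc_runs]),
      mean_energy = clusters[[cc]]$mean_energy),
    cluster_index = c(BC = bc, LC = lc, CC = cc),
    n_clusters = length(clusters), n_poses = sum(sizes)),
    class = "enzyme_score")
}

#' Combine enzyme scores into a screen results table
#'
#' One row per score, mirroring the screen results layout: identifiers,
#' the seven metrics, and the catalytic-cluster means.
#'
#' @param scores list of `enzyme_score`s.
#' @return data frame.
#' @export
score_table <- function(scores) {
  do.call(rbind, lapply(scores, function(s) {
    data.frame(enzyme_id = s$enzyme_id, chain_id = s$chain_id,
               LCC = s$metrics$LCC, BCC = s$metrics$BCC,
               LCE = s$metrics$LCE, BCE = s$metrics$BCE,
               LCaaE = s$metrics$LCaaE, BCaaE = s$metrics$BCaaE,
               CC_CFC = s$metrics$CC_CFC,
               mean_abs_sin_chi_inspected = s$cc_stats$mean_sin_inspected,
               mean_d = s$cc_stats$mean_d,
               mean_E = s$cc_stats$mean_energy,
               stringsAsFactors = FALSE)
  }))
}

RANK_METHODS <- c("LCC", "BCC", "LCE", "BCE", "LCaaE", "BCaaE", "CC_CFC")

#' Rank enzymes by one of the seven methods
#'
#' Count metrics (LCC, BCC, CC_CFC) rank descending; energy metrics
#' (LCE, BCE, LCaaE, BCaaE) rank ascending.  With several chains per
#' enzyme, each enzyme is represented by its best chain under the active
#' method.  Ties break by higher catalytic-cluster mean |sin(chi)|, then
#' lower mean energy, then enzyme id.
#'
#' @param scores list of `enzyme_score`s, or a [score_table()] data
#'   frame.
#' @param method one of `r paste(RANK_METHODS, collapse = ", ")`.
#' @return `ranking_table` data frame: rank (1-based), enzyme_id,
#'   chain_id, the method's value, the full metric columns, and a
#'   `tie_break` trace column.
#' @export
rank_enzymes <- function(scores, method = "CC_CFC") {
  if (!method %in% RANK_METHODS)
    stop_plp("plpscreen_usage_error", "unknown ranking method '%s'", method)
  tab <- if (is.data.frame(scores)) scores else score_table(scores)
  if (nrow(tab) == 0)
    stop_plp("plpscreen_usage_error", "no scores to rank")
  ascending <- method %in% c("LCE", "BCE", "LCaaE", "BCaaE")
  key <- tab[[method]]
  if (ascending) key <- -key
  ## best chain per enzyme under the active method
  keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$enzyme_id),
                        function(i) i[which.max(key[i])]), use.names = FALSE)
  tab <- tab[keep, , drop = FALSE]
  key <- key[keep]
  tb_sin <- tab$mean_abs_sin_chi_inspected
  tb_sin[is.na(tb_sin)] <- -Inf
  tb_e <- tab$mean_E
  tb_e[is.na(tb_e)] <- Inf
  ord <- order(-key, -tb_sin, tb_e, tab$enzyme_id)
  out <- tab[ord, , drop = FALSE]
  tied <- duplicated(key[ord]) | duplicated(key[ord], fromLast = TRUE)
  out$tie_break <- ifelse(tied, "sin>E>id", "")
  out <- cbind(rank = seq_len(nrow(out)), out, method = method)
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}
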