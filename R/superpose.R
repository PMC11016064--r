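#' Rigid-body superposition by the Kabsch algorithm
#'
#' Finds the proper rotation and translation minimizing the least-squares
#' deviation between paired point sets, via SVD of the cross-covariance
#' matrix with the usual determinant correction.
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows,
#'   n >= 3 and not collinear.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3;
#'   the transform is `x %*% t(rotation) + translation`), and `rmsd` in
#'   angstroms after superposition.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!is.numeric(mobile) || ncol(mobile) != 3 || ncol(reference) != 3 ||
      nrow(mobile) != nrow(reference))
    stop_plp("plpscreen_geometry_error", "need matched n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3)
    stop_plp("plpscreen_geometry_error", "need at least 3 paired points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  ## collinearity check: centered points must span a plane
  if (sum(svd(A)$d > 1e-8) < 2 || sum(svd(B)$d > 1e-8) < 2)
    stop_plp("plpscreen_geometry_error", "degenerate (collinear) point set")
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cr - R %*% cm)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, -fit$translation)
}

## CA coordinate pairs between a monomer and one template chain, matched
## through sequence alignment.
aligned_ca_pairs <- function(monomer, template, template_chain,
                             min_identity = 0.30, min_length = 50) {
  mono_res <- chain_residues(monomer, monomer$chains[1])
  tmpl_res <- chain_residues(template, template_chain)
  mseq <- paste(aa3to1(mono_res$resname), collapse = "")
  tseq <- paste(aa3to1(tmpl_res$resname), collapse = "")
  if (nchar(mseq) == 0 || nchar(tseq) == 0)
    stop_plp("plpscreen_assembly_error",
             "template chain %s: empty sequence", template_chain)
  aln <- align_pair(mseq, tseq)
  qa <- strsplit(aln$query, "")[[1]]; ta <- strsplit(aln$target, "")[[1]]
  both <- qa != "-" & ta != "-"
  npairs <- sum(both)
  ident <- if (npairs) sum(qa[both] == ta[both]) / npairs else 0
  if (npairs < min_length || ident < min_identity)
    stop_plp("plpscreen_assembly_error",
             "template chain %s not alignable (%d aligned residues, %.0f%% identity)",
             template_chain, npairs, 100 * ident)
  qi <- cumsum(qa != "-")[both]; ti <- cumsum(ta != "-")[both]
  ca_of <- function(model, chain, resnos) {
    at <- chain_atoms(model, chain)
    at <- at[at$name == "CA" & !at$het, , drop = FALSE]
    at <- at[match(resnos, at$resno), , drop = FALSE]
    coords_of(at)
  }
  keep <- !is.na(qi) & !is.na(ti)
  list(mobile = ca_of(monomer, monomer$chains[1], mono_res$resno[qi[keep]]),
       reference = ca_of(template, template_chain, tmpl_res$resno[ti[keep]]))
}

#' Assemble a homo-oligomer by superposing a monomer onto a template
#'
#' Places one copy of the monomer on every chain of the template by
#' superposing CA atoms of sequence-aligned residue pairs, and relabels
#' chains `A, B, ...` in template-chain order.
#'
#' @param monomer single-chain `structure_model`.
#' @param template multi-chain `structure_model` defining the arrangement.
#' @param min_identity,min_length alignment acceptance thresholds per
#'   template chain (fraction identity over aligned pairs; number of
#'   aligned residue pairs).
#' @return a `structure_model` with one chain per template chain and an
#'   attribute `rmsd`: named per-chain superposition RMSD (angstroms).
#' @export
assemble_oligomer <- function(monomer, template,
                              min_identity = 0.30, min_length = 50) {
  if (monomer$oligomeric_state != 1)
    stop_plp("plpscreen_value_error", "monomer must have exactly one chain")
  pieces <- list(); rmsds <- numeric(0)
  for (i in seq_along(template$chains)) {
    tch <- template$chains[i]
    pairs <- aligned_ca_pairs(monomer, template, tch,
                              min_identity, min_length)
    fit <- kabsch_superpose(pairs$mobile, pairs$reference)
    at <- monomer$atoms
    at[, c("x", "y", "z")] <- apply_transform(coords_of(at), fit)
    at$chain <- LETTERS[i]
    pieces[[i]] <- at
    rmsds[LETTERS[i]] <- fit$rmsd
  }
  out <- new_structure_model(do.call(rbind, pieces),
                             paste0(monomer$source_id, "_oligomer"))
  attr(out, "rmsd") <- rmsds
  out
}

#' Assemble a hetero-oligomer from explicit monomer-template chain pairs
#'
#' Manual variant of [assemble_oligomer()] for heteromeric assemblies: each
#' template chain is paired explicitly with one of several monomers.
#'
#' @param monomers named list of single-chain `structure_model`s.
#' @param template multi-chain `structure_model`.
#' @param chain_map named character vector: template chain id -> name in
#'   `monomers`.
#' @inheritParams assemble_oligomer
#' @return as [assemble_oligomer()].
#' @export
assemble_heteromer <- function(monomers, template, chain_map,
                               min_identity = 0.30, min_length = 50) {
  pieces <- list(); rmsds <- numeric(0)
  for (i in seq_along(chain_map)) {
    tch <- names(chain_map)[i]
    mono <- monomers[[chain_map[[i]]]]
    if (is.null(mono))
      stop_plp("plpscreen_assembly_error", "no monomer named '%s'",
               chain_map[[i]])
    pairs <- aligned_ca_pairs(mono, template, tch, min_identity, min_length)
    fit <- kabsch_superpose(pairs$mobile, pairs$reference)
    at <- mono$atoms
    at[, c("x", "y", "z")] <- apply_transform(coords_of(at), fit)
    at$chain <- LETTERS[i]
    pieces[[i]] <- at
    rmsds[LETTERS[i]] <- fit$rmsd
  }
  out <- new_structure_model(do.call(rbind, pieces), "heteromer")
  attr(out, "rmsd") <- rmsds
  out
}
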