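## Independent oracles used to cross-check the package's implementations.
## These deliberately share no code path with the functions they test.

## Horn's closed-form quaternion superposition: rotation from the largest
## eigenvector of the 4x4 key matrix built from the cross-covariance.
quaternion_superpose <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  M <- crossprod(A, B)   # sum over points of a_i b_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fitted <- A %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((fitted - B)^2))))
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y),
    2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
}

## Rigid motion applied to an atom table.
move_atoms <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]; atoms$y <- xyz[, 2] + t[2]
  atoms$z <- xyz[, 3] + t[3]
  atoms
}

## Brute-force CFC re-derivation from raw pose coordinates, written as a
## flat second implementation: principal-axes plane normal via eigen() of
## the covariance matrix, angles via the arcsin of the projection.
brute_force_cfc <- function(ligand, nz_xyz, inspected, cutoff = 5) {
  get <- function(nm) as.numeric(ligand[ligand$name == nm,
                                        c("x", "y", "z")][1, ])
  ring <- t(sapply(c("N1", "C2", "C3", "C4", "C5", "C6"), get))
  cov <- stats::cov(ring)
  ev <- eigen(cov, symmetric = TRUE)
  nrm <- ev$vectors[, which.min(ev$values)]
  nrm <- nrm / sqrt(sum(nrm^2))
  ca <- get("CA")
  sin_of <- function(to) {
    v <- get(to) - ca
    abs(sum(v * nrm)) / sqrt(sum(v^2))
  }
  sins <- c(chi1 = sin_of("C"), chi2 = sin_of("CB"), chi3 = sin_of("HA1"))
  d <- sqrt(sum((get("C4A") - nz_xyz)^2))
  ins <- sins[[inspected]]
  list(sins = sins, d = d,
       is_cfc = all(ins > sins[names(sins) != inspected]) && d <= cutoff)
}

## Exhaustive global alignment by dynamic programming with affine gaps
## (match 1, mismatch -1, open 5, extend 1), tracking whether a given
## 1-based query position ends up aligned to a gap.  Independent of the
## Biostrings-based implementation.
nw_map_position <- function(query, target, qpos) {
  q <- strsplit(query, "")[[1]]; t <- strsplit(target, "")[[1]]
  n <- length(q); m <- length(t)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)    # X: gap in target, Y: in query
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -5 - (i - 1) * 1
  for (j in seq_len(m)) Y[1, j + 1] <- -5 - (j - 1) * 1
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (q[i] == t[j]) 1 else -1
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - 5, X[i, j + 1] - 1)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - 5, Y[i + 1, j] - 1)
  }
  ## traceback from the best final state
  state <- c("M", "X", "Y")[which.max(c(M[n + 1, m + 1], X[n + 1, m + 1],
                                        Y[n + 1, m + 1]))]
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (state == "M") {
      s <- if (q[i] == t[j]) 1 else -1
      if (i == qpos) return(j)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- c("M", "X", "Y")[which.max(prev)]
      i <- i - 1; j <- j - 1
      if (i == 0 && j == 0) break
    } else if (state == "X") {   # q[i] aligned to gap
      if (i == qpos) return(NA_integer_)
      from_m <- M[i, j + 1] - 5; from_x <- X[i, j + 1] - 1
      state <- if (from_m >= from_x) "M" else "X"
      i <- i - 1
    } else {                      # t[j] aligned to gap
      from_m <- M[i + 1, j] - 5; from_y <- Y[i + 1, j] - 1
      state <- if (from_m >= from_y) "M" else "Y"
      j <- j - 1
    }
  }
  NA_integer_
}

## Plain pairwise-RMSD single-linkage components at a cutoff (oracle for
## the cluster-count checks on well-separated blobs).
rmsd_components <- function(ensemble, cutoff = 3) {
  n <- length(ensemble$poses)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- ligand_rmsd(ensemble$poses[[i]], ensemble$poses[[j]]) <= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$no
}
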