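test_that("ligand_rmsd is the direct coordinate formula without refitting", {
  p0 <- shifted_pose(c(0, 0, 0), -8, 1L)
  expect_equal(ligand_rmsd(p0, p0), 0)
  p1 <- shifted_pose(c(3, 0, 0), -8, 2L)
  expect_equal(ligand_rmsd(p0, p1), 3, tolerance = 1e-12)

  set.seed(4)
  pa <- random_pose(1L); pb <- random_pose(2L)
  a <- pa$ligand[pa$ligand$element != "H", ]
  b <- pb$ligand[pb$ligand$element != "H", ]
  m <- match(a$name, b$name)
  direct <- sqrt(mean((a$x - b$x[m])^2 + (a$y - b$y[m])^2 +
                        (a$z - b$z[m])^2))
  expect_equal(ligand_rmsd(pa, pb), direct, tolerance = 1e-12)

  pc <- pb; pc$ligand <- pc$ligand[-1, ]
  expect_error(ligand_rmsd(pa, pc), class = "plpscreen_pairing_error")
})

test_that("cluster_poses implements energy-ordered leader clustering", {
  ## identical poses collapse into one cluster
  same <- as_ensemble(lapply(1:50, function(i)
    shifted_pose(c(0, 0, 0), -7 - i * 0.01, as.integer(i))))
  cl <- cluster_poses(same)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 50)
  expect_equal(cl[[1]]$best_energy, -7.5)

  ## two tight blobs 10 A apart: exactly two clusters; oracle = pairwise
  ## single-linkage components at the same cutoff
  set.seed(8)
  blob <- function(center, n, run0, e) lapply(seq_len(n), function(j)
    shifted_pose(center + runif(3, -0.3, 0.3), e + rnorm(1, 0, 0.2),
                 as.integer(run0 + j)))
  ens <- as_ensemble(c(blob(c(0, 0, 0), 10, 0, -8),
                       blob(c(10, 0, 0), 10, 10, -7)))
  cl2 <- cluster_poses(ens, cutoff = 3)
  expect_length(cl2, 2)
  expect_equal(sort(vapply(cl2, `[[`, numeric(1), "size")), c(10, 10))
  expect_equal(rmsd_components(ens, 3), 2)

  ## leader linkage: members within the cutoff of the leader join even if
  ## mutually far apart
  star <- as_ensemble(list(shifted_pose(c(0, 0, 0), -9, 1L),
                           shifted_pose(c(2.9, 0, 0), -8, 2L),
                           shifted_pose(c(-2.9, 0, 0), -7, 3L)))
  cl3 <- cluster_poses(star, cutoff = 3)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$leader_run, 1L)
})

test_that("cluster sizes always sum to the pose count", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    ens <- as_ensemble(lapply(seq_len(n), function(i) {
      shifted_pose(runif(3, 0, 15), rnorm(1, -7), as.integer(i))
    }))
    cl <- cluster_poses(ens)
    expect_equal(sum(vapply(cl, `[[`, numeric(1), "size")), n)
    ## every run appears exactly once
    runs <- sort(unlist(lapply(cl, `[[`, "member_runs")))
    expect_equal(runs, 1:n)
  }
})

test_that("a far-away singleton never degrades existing cluster metrics", {
  set.seed(23)
  ens <- as_ensemble(lapply(1:20, function(i)
    shifted_pose(runif(3, 0, 6), rnorm(1, -7), as.integer(i))))
  cl_before <- cluster_poses(ens)
  extra <- shifted_pose(c(50, 50, 50), -6, 21L)
  cl_after <- cluster_poses(as_ensemble(c(ens$poses, list(extra))))
  expect_length(cl_after, length(cl_before) + 1)
  for (k in seq_along(cl_before)) {
    expect_equal(cl_after[[k]]$size, cl_before[[k]]$size)
    expect_equal(cl_after[[k]]$best_energy, cl_before[[k]]$best_energy)
  }
})

test_that("aa_interaction_energy matches closed forms and a hand summation", {
  far <- plpscreen:::atom_table("C1", "C", 100, 0, 0, charge = 0.5)
  rec <- plpscreen:::atom_table(c("N", "CA"), c("N", "C"), c(0, 1), 0, 0,
                                charge = c(-0.3, 0.1))
  expect_identical(aa_interaction_energy(far, rec), 0)

  ## single +1/-1 pair, LJ off: Coulomb with eps(r) = 4r at r = 4
  plus <- plpscreen:::atom_table("C1", "C", 0, 0, 0, charge = 1)
  minus <- plpscreen:::atom_table("N", "N", 4, 0, 0, charge = -1)
  expect_equal(aa_interaction_energy(plus, minus, lj = FALSE),
               332.0637 * (1 * -1) / (4 * 4^2), tolerance = 1e-12)

  ## 5-atom toy system vs an explicit term-by-term sum
  sub <- plpscreen:::atom_table(c("C1", "O1"), c("C", "O"),
                                x = c(0, 1.2), y = 0, z = 0,
                                charge = c(0.3, -0.4))
  rcp <- plpscreen:::atom_table(c("N", "C", "H"), c("N", "C", "H"),
                                x = c(3, 4, 5), y = c(1, -1, 0), z = 0,
                                charge = c(-0.5, 0.2, 0.1))
  lj_tab <- plpscreen:::LJ_TABLE
  prm <- function(e) lj_tab[match(e, lj_tab$element), ]
  total <- 0
  for (i in 1:2) for (j in 1:3) {
    d <- sqrt(sum((c(sub$x[i], sub$y[i], sub$z[i]) -
                     c(rcp$x[j], rcp$y[j], rcp$z[j]))^2))
    if (d > 8) next
    total <- total + 332.0637 * sub$charge[i] * rcp$charge[j] / (4 * d^2)
    pi_ <- prm(sub$element[i]); pj <- prm(rcp$element[j])
    rij <- (pi_$Rii + pj$Rii) / 2; eij <- sqrt(pi_$epsii * pj$epsii)
    total <- total + eij * ((rij / d)^12 - 2 * (rij / d)^6)
  }
  expect_equal(aa_interaction_energy(sub, rcp), total, tolerance = 1e-10)

  sub$charge <- NA_real_
  expect_error(aa_interaction_energy(sub, rcp),
               class = "plpscreen_scoring_error")
})

## Compact helper: build a scored cluster set from (size, bestE, cfc)
## triples by generating constructed poses.
constructed_scores <- function(layout, rule = cfc_rule("PLP", "chi2")) {
  poses <- list(); run <- 0L
  for (li in seq_along(layout)) {
    l <- layout[[li]]
    for (j in seq_len(l$size)) {
      run <- run + 1L
      fav <- j <= l$cfc
      poses[[run]] <- shifted_pose(c(20 * (li - 1), 0, 0),
                                   ifelse(j == 1, l$bestE, l$bestE + 0.5),
                                   run,
                                   chi = if (fav) c(0.3, 0.95, 0.4)
                                         else c(0.9, 0.2, 0.4),
                                   d = if (fav) 4 else 7)
    }
  }
  ens <- as_ensemble(poses)
  cl <- cluster_poses(ens)
  cfc <- cfc_table(ens, fixture_roles(), rule)
  list(ens = ens, clusters = cl, cfc = cfc)
}

test_that("score_enzyme identifies BC, LC and CC and fills the metrics", {
  x <- constructed_scores(list(list(size = 100, bestE = -8.0, cfc = 0),
                               list(size = 50, bestE = -9.5, cfc = 5),
                               list(size = 50, bestE = -7.0, cfc = 2)))
  s <- score_enzyme(x$clusters, x$cfc, cfc_rule("PLP", "chi2"), "E1")
  expect_equal(s$metrics$LCC, 100)
  expect_equal(s$metrics$BCE, -9.5)
  expect_equal(s$metrics$CC_CFC, 5)
  expect_equal(s$metrics$BCC, 50)
  expect_equal(s$metrics$LCE, -8.0)
  ## CC = the 50-pose cluster with 5 CFC; differs from LC
  expect_false(s$cluster_index[["CC"]] == s$cluster_index[["LC"]])
  expect_true(s$cluster_index[["CC"]] == s$cluster_index[["BC"]])
  ## CC-CFC equals a brute-force recount inside the argmax cluster
  runs_cc <- x$clusters[[s$cluster_index[["CC"]]]]$member_runs
  expect_equal(s$metrics$CC_CFC,
               sum(x$cfc$is_cfc[x$cfc$run_index %in% runs_cc]))

  ## all-zero CFC: CC falls back to BC
  y <- constructed_scores(list(list(size = 10, bestE = -8, cfc = 0),
                               list(size = 20, bestE = -9, cfc = 0)))
  s2 <- score_enzyme(y$clusters, y$cfc, cfc_rule("PLP", "chi2"), "E2")
  expect_equal(s2$metrics$CC_CFC, 0)
  expect_equal(s2$cluster_index[["CC"]], s2$cluster_index[["BC"]])

  ## CC, BC and LC can be three different clusters
  z <- constructed_scores(list(list(size = 30, bestE = -9.5, cfc = 1),
                               list(size = 40, bestE = -8.0, cfc = 2),
                               list(size = 20, bestE = -7.0, cfc = 9)))
  s3 <- score_enzyme(z$clusters, z$cfc, cfc_rule("PLP", "chi2"), "E3")
  expect_equal(length(unique(s3$cluster_index)), 3)
  expect_equal(s3$metrics$CC_CFC, 9)

  expect_error(score_enzyme(list(), x$cfc), class = "plpscreen_usage_error")
})

test_that("rank_enzymes orders by method with documented tie-breaks", {
  mk <- function(id, cc, bce = -8, sin = 0.9, e = -7) {
    data.frame(enzyme_id = id, chain_id = "A", LCC = 10, BCC = 10,
               LCE = -8, BCE = bce, LCaaE = NA, BCaaE = NA, CC_CFC = cc,
               mean_abs_sin_chi_inspected = sin, mean_d = 4, mean_E = e)
  }
  tab <- rbind(mk("A", 51), mk("B", 91), mk("C", 0))
  r <- rank_enzymes(tab, "CC_CFC")
  expect_equal(r$enzyme_id, c("B", "A", "C"))
  expect_equal(r$rank, 1:3)

  ## energies rank ascending
  tab2 <- rbind(mk("X", 1, bce = -7.0), mk("Y", 1, bce = -9.5))
  expect_equal(rank_enzymes(tab2, "BCE")$enzyme_id, c("Y", "X"))

  ## all-equal metric: lexicographic order with a populated tie trace
  tab3 <- rbind(mk("b", 5, sin = 0.5, e = -6), mk("a", 5, sin = 0.5, e = -6))
  r3 <- rank_enzymes(tab3, "CC_CFC")
  expect_equal(r3$enzyme_id, c("a", "b"))
  expect_true(all(nzchar(r3$tie_break)))

  ## tie broken by higher mean sin before id
  tab4 <- rbind(mk("a", 5, sin = 0.2), mk("z", 5, sin = 0.9))
  expect_equal(rank_enzymes(tab4, "CC_CFC")$enzyme_id, c("z", "a"))

  ## permutation property
  set.seed(2)
  tab5 <- do.call(rbind, lapply(1:12, function(i)
    mk(sprintf("E%02d", i), sample(0:5, 1), sin = runif(1))))
  r5 <- rank_enzymes(tab5, "CC_CFC")
  expect_setequal(r5$enzyme_id, tab5$enzyme_id)
  expect_equal(r5$rank, seq_len(nrow(tab5)))

  ## multi-chain aggregation: the best chain represents the enzyme
  two_chain <- rbind(mk("M", 3), mk("M", 8), mk("N", 5))
  two_chain$chain_id <- c("A", "B", "A")
  r6 <- rank_enzymes(two_chain, "CC_CFC")
  expect_equal(nrow(r6), 2)
  expect_equal(r6$chain_id[r6$enzyme_id == "M"], "B")

  expect_error(rank_enzymes(tab, "XXX"), class = "plpscreen_usage_error")
})
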