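test_that("contact metrics follow their definitions", {
  L <- matrix(c(0, 0, 0, 4, 0, 0), ncol = 3, byrow = TRUE)
  R <- matrix(c(0, 0, 0), ncol = 3)
  expect_equal(mean_distance(L, R), 2.0)     # minima 0 and 4
  expect_equal(mean_distance(R, R), 0)
  expect_equal(min_distance(L, R), 0)
  expect_equal(min_distance(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1)), 1)
  expect_equal(overlap_count(L, R, t_o = 1), 1)   # strict: only the touching atom
  expect_error(mean_distance(L[0, , drop = FALSE], R), "empty")
})

test_that("metric properties hold on random point sets", {
  set.seed(41)
  for (i in 1:10) {
    L <- matrix(rnorm(15, sd = 3), ncol = 3)
    R <- matrix(rnorm(21, sd = 3), ncol = 3)
    expect_gte(mean_distance(L, R), min_distance(L, R))
    expect_equal(min_distance(L, R), min_distance(R, L))
    ## overlap count is monotone nondecreasing in the threshold
    counts <- vapply(c(0.5, 1, 2, 4, 8), function(t) overlap_count(L, R, t), 0)
    expect_true(all(diff(counts) >= 0))
    ## rigid invariance of all metrics
    Rot <- random_rotation(); tr <- rnorm(3, 0, 10)
    Lr <- sweep(L %*% t(Rot), 2, tr, "+"); Rr <- sweep(R %*% t(Rot), 2, tr, "+")
    expect_equal(mean_distance(Lr, Rr), mean_distance(L, R), tolerance = 1e-9)
    expect_equal(min_distance(Lr, Rr), min_distance(L, R), tolerance = 1e-9)
    expect_equal(overlap_count(Lr, Rr), overlap_count(L, R))
  }
})

test_that("merging recovers known rigid motions of the shared subunit", {
  set.seed(43)
  A <- toy_structure(matrix(rnorm(24, sd = 4), ncol = 3), chain = "A")
  B <- toy_structure(matrix(rnorm(18, sd = 4) + 10, ncol = 3), chain = "B")
  lig <- toy_structure(matrix(rnorm(9, sd = 2) - 5, ncol = 3), chain = "L")

  ## identical A copies: identity transform, zero RMSD
  p0 <- merge_ternary(list(A = A, ligand = lig), list(A = A, B = B))
  expect_equal(p0$superposition_rmsd, 0, tolerance = 1e-9)
  expect_equal(coords(p0$B), coords(B), tolerance = 1e-9, ignore_attr = TRUE)

  for (i in 1:10) {
    Rot <- random_rotation(); tr <- rnorm(3, 0, 15)
    A2 <- transform_structure(A, Rot, tr)
    B2 <- transform_structure(B, Rot, tr)
    p <- merge_ternary(list(A = A, ligand = lig), list(A = A2, B = B2))
    expect_lt(p$superposition_rmsd, 1e-6)
    expect_equal(coords(p$B), coords(B), tolerance = 1e-6, ignore_attr = TRUE)
  }

  ## conformer noise shows up as RMSD of the same magnitude, no warning
  A_noise <- A
  A_noise$atoms[c("x", "y", "z")] <-
    A_noise$atoms[c("x", "y", "z")] + rnorm(24, sd = 0.1)
  expect_no_warning(
    pn <- merge_ternary(list(A = A, ligand = lig), list(A = A_noise, B = B)))
  expect_lt(pn$superposition_rmsd, 0.3)
  expect_gt(pn$superposition_rmsd, 0.01)

  expect_error(merge_ternary(list(A = A, ligand = lig),
                             list(A = toy_structure(diag(3), chain = "Q"), B = B)),
               "fewer than 3")
})

test_that("the pose filter keeps boundary cases and rejects violations", {
  mk_pose <- function(b_xyz) {
    A <- toy_structure(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3,
                              byrow = TRUE), chain = "A")
    lig <- toy_structure(cbind(0:11, 20, 0), chain = "L")
    merge_ternary(list(A = A, ligand = lig),
                  list(A = A, B = toy_structure(b_xyz, chain = "B")))
  }
  lig_xyz <- cbind(0:11, 20, 0)
  poses <- list(
    mk_pose(sweep(lig_xyz, 2, c(0, 5, 0), "+")),       # d = 5.0 exactly: keep
    mk_pose(sweep(lig_xyz, 2, c(0, 4, 0), "+")),       # comfortable: keep
    mk_pose(rbind(lig_xyz[1:10, ], c(100, 100, 0), c(101, 100, 0))),
                                                        # N_o = 10 at 1 A: keep
    mk_pose(lig_xyz),                                   # N_o = 12: reject
    mk_pose(rbind(lig_xyz[1:11, ], c(100, 100, 0))),    # N_o = 11: reject
    mk_pose(sweep(lig_xyz, 2, c(0, 5.01, 0), "+")),     # d = 5.01: reject
    mk_pose(sweep(lig_xyz, 2, c(0, 60, 0), "+")),       # far: reject
    mk_pose(sweep(lig_xyz, 2, c(0, 1, 0), "+"))         # close, no overlap: keep
  )
  fl <- filter_ternary(poses)
  expect_equal(fl$manifest$kept,
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(fl$manifest$n_overlap[3], 10)
  expect_equal(fl$manifest$mean_dist[1], 5.0)
  ## filtering is idempotent
  fl2 <- filter_ternary(fl$kept)
  expect_equal(length(fl2$kept), length(fl$kept))
  expect_true(all(fl2$manifest$kept))
})

test_that("pose clustering recovers planted orientation groups", {
  pb <- make_pose_batch(synth_spec(2), n_pass = 6, n_fail_overlap = 0,
                        n_fail_distance = 0, n_groups = 3)
  cl <- cluster_poses(pb$poses, rmsd_threshold = 5)
  expect_equal(cl$n_clusters, 3)
  expect_equal(unname(table(cl$assignment)), rep(2L, 3), ignore_attr = TRUE)
  ## truth groups coincide with recovered clusters (up to relabeling)
  expect_equal(length(unique(paste(cl$assignment, pb$truth$group))), 3)
  ## representatives minimise energy within their cluster
  for (g in seq_len(cl$n_clusters)) {
    idx <- which(cl$assignment == g)
    en <- vapply(pb$poses[idx], function(p) p$energy, 0)
    expect_equal(pb$poses[[cl$representatives[g]]]$energy, min(en))
  }
  ## all-identical poses collapse to one cluster
  same <- pb$poses[c(1, 1, 1)]
  cl1 <- cluster_poses(same, rmsd_threshold = 5)
  expect_equal(cl1$n_clusters, 1)
  ## threshold 0 isolates every distinct pose
  cl0 <- cluster_poses(pb$poses, rmsd_threshold = 0)
  expect_equal(cl0$n_clusters, 6)
})

test_that("site co-occurrence matches the formula and a brute-force oracle", {
  ## one model, one site {1, 2}
  m1 <- site_cooccurrence(list(list(f = 1, sites = list(c(1, 2)))))
  expect_equal(m1$M[1, 2], 1)
  expect_equal(m1$M[1, 1], 1)
  ## disjoint sites give a block-diagonal matrix
  m2 <- site_cooccurrence(list(list(f = 1, sites = list(1:2)),
                               list(f = 1, sites = list(3:4))))
  expect_equal(m2$M[1:2, 3:4], matrix(0, 2, 2))
  ## weighted models sharing a pair accumulate to 1
  m3 <- site_cooccurrence(list(list(f = 0.75, sites = list(c(2, 5))),
                               list(f = 0.25, sites = list(c(2, 5)))))
  expect_equal(m3$M[2, 5], 1.0)

  ## brute-force double loop on random instances
  set.seed(47)
  for (i in 1:15) {
    n_res <- 12
    models <- lapply(seq_len(sample(1:5, 1)), function(m) {
      list(f = runif(1, 0, 2),
           sites = lapply(seq_len(sample(1:3, 1)),
                          function(s) sample(n_res, sample(2:5, 1))))
    })
    M <- site_cooccurrence(models, n_residues = n_res)$M
    O <- matrix(0, n_res, n_res)
    for (m in models) for (s in m$sites) for (a in s) for (b in s) {
      O[a, b] <- O[a, b] + m$f
    }
    expect_equal(M, O)
    expect_equal(M, t(M))
  }
})

test_that("spectral biclustering recovers planted blocks", {
  blocks <- list(1:3, 4:6, 7:9, 10:12)
  models <- lapply(blocks, function(b) list(f = 1, sites = list(b)))
  com <- site_cooccurrence(models, n_residues = 12)
  got <- bicluster_sites(com, k = 4)
  expect_equal(length(got), 4)
  norm <- lapply(got, sort)
  expect_setequal(vapply(norm, paste, "", collapse = ","),
                  vapply(blocks, paste, "", collapse = ","))
  ## k = 1 returns all residues with signal
  expect_equal(bicluster_sites(com, 1)[[1]], 1:12)
  ## residue permutation only relabels groups
  perm <- c(12:1)
  models_p <- lapply(blocks, function(b) list(f = 1, sites = list(perm[b])))
  got_p <- bicluster_sites(site_cooccurrence(models_p, n_residues = 12), k = 4)
  expect_setequal(vapply(lapply(got_p, sort), paste, "", collapse = ","),
                  vapply(lapply(blocks, function(b) sort(perm[b])),
                         paste, "", collapse = ","))
  expect_error(bicluster_sites(com, 30), "exceeds")
})
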