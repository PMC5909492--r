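test_that("pseudo-haplotype collapsing merges planted pairs and conserves mass", {
  ## k well-separated pairs: members of a pair differ at one position,
  ## across pairs at many
  k <- 4
  blocks <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT")
  seqs <- unlist(lapply(blocks, function(b) {
    alt <- b; substr(alt, 1, 1) <- "N"
    c(b, alt)
  }))
  haps <- data.frame(sequence = seqs, count = 8:1,
                     frequency = (8:1) / sum(8:1), stringsAsFactors = FALSE)
  ps <- collapse_pseudohaplotypes(haps, k)
  expect_equal(length(ps$sequence), k)
  expect_equal(sum(ps$frequency), 1)
  ## each pair merged: pooled counts are 8+7, 6+5, 4+3, 2+1
  expect_equal(sort(ps$count, decreasing = TRUE), c(15, 11, 7, 3))
  ## representative of a group is its highest-count member
  expect_equal(ps$sequence[1], "AAAAAAAA")

  ## identity collapsing at k = n, single class at k = 1
  idc <- collapse_pseudohaplotypes(haps, nrow(haps))
  expect_equal(sort(idc$count), sort(haps$count))
  one <- collapse_pseudohaplotypes(haps, 1)
  expect_equal(one$frequency, 1)
  expect_error(collapse_pseudohaplotypes(haps, 20), "choose k")
})

test_that("3D embedding reproduces embeddable distances", {
  set.seed(5)
  pts <- matrix(rnorm(18), 6, 3)
  d <- dist(pts)
  co <- embed_3d(d)
  expect_equal(as.matrix(dist(co)), as.matrix(d), tolerance = 1e-6,
               ignore_attr = TRUE)
  ## deterministic sign convention
  expect_equal(co, embed_3d(d))

  ## regular simplex: all embedded pairwise distances equal
  simplex <- matrix(1, 4, 4) - diag(4)
  ds <- dist(embed_3d(simplex))
  expect_equal(max(ds) - min(ds), 0, tolerance = 1e-9)

  ## two points: line embedding preserves the distance, axes padded
  co2 <- embed_3d(rbind(c(0, 3), c(3, 0)))
  expect_equal(ncol(co2), 3)
  expect_equal(as.numeric(dist(co2)), 3, tolerance = 1e-9)
})

test_that("mixture L2 discrepancy is zero at identity, symmetric in components, and saturates", {
  set.seed(11)
  g <- random_gmm(5)
  expect_equal(delta_g(g, g), 0)
  gp <- g
  perm <- c(3, 1, 2, 5, 4)
  gp$means <- g$means[perm, ]; gp$weights <- g$weights[perm]
  expect_equal(delta_g(g, gp), 0, tolerance = 1e-12)

  ## translating one copy away increases the discrepancy monotonically
  ## toward the sum of self-overlap terms
  shifts <- c(1, 3, 10, 40)
  dgs <- vapply(shifts, function(s) {
    g2 <- g; g2$means <- sweep(g$means, 2, c(s, 0, 0), "+")
    delta_g(g, g2)
  }, 0)
  expect_true(all(diff(dgs) > 0))
  self <- delta_g(g, population_gmm(g$means + 1e6, g$weights, g$sigma2))
  expect_equal(dgs[4], self, tolerance = 1e-6)
})

test_that("closed-form mixture discrepancy agrees with grid integration", {
  set.seed(23)
  g1 <- random_gmm(3, scale = 1.5, sigma2 = 0.4)
  g2 <- random_gmm(3, scale = 1.5, sigma2 = 0.4)
  expect_lt(abs(delta_g(g1, g2) - grid_delta_g(g1, g2)), 1e-4)
  expect_lt(abs(delta_g(g1, g1) - grid_delta_g(g1, g1)), 1e-4)
})

test_that("Procrustes recovers rigid and mirror transforms of a mixture", {
  set.seed(31)
  for (rep_i in 1:8) {
    g <- random_gmm(6)
    R <- random_rotation()
    if (rep_i %% 2 == 0) R <- R %*% diag(c(1, 1, -1))   # improper
    g2 <- g
    g2$means <- sweep(g$means %*% t(R), 2, rnorm(3, 0, 5), "+")
    pro <- procrustes_superimpose(g, g2)
    expect_lt(pro$delta_g, 1e-8)
    expect_equal(crossprod(pro$rotation), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  ## permuting frequencies breaks the match generically
  g <- random_gmm(6)
  gp <- g; gp$weights <- g$weights[c(2, 3, 4, 5, 6, 1)]
  expect_gt(procrustes_superimpose(g, gp)$delta_g, 0)
})

test_that("Procrustes rotation agrees with the vegan oracle on weightless means", {
  set.seed(57)
  X <- matrix(rnorm(21), 7, 3)
  R <- random_rotation()
  Y <- X %*% t(R)
  g1 <- population_gmm(X, rep(1, 7), sigma2 = 1)
  g2 <- population_gmm(Y, rep(1, 7), sigma2 = 1)
  pro <- procrustes_superimpose(g1, g2)
  ## vegan's symmetric-free Procrustes on the same configurations
  veg <- vegan::procrustes(X, Y, scale = FALSE)
  aligned_veg <- Y %*% veg$rotation
  expect_equal(sweep(pro$g2_aligned$means, 2, colMeans(pro$g2_aligned$means)),
               sweep(aligned_veg, 2, colMeans(aligned_veg)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("permutation test is seeded, bounded, and degenerate on equal frequencies", {
  set.seed(71)
  g1 <- random_gmm(5)
  g2 <- random_gmm(5)
  p1 <- permutation_test(g1, g2, n_perm = 99, seed = 4)
  p2 <- permutation_test(g1, g2, n_perm = 99, seed = 4)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 100)
  expect_lte(p1$p_value, 1)

  ## equal frequencies make shuffling a no-op: p = 1
  ge1 <- population_gmm(g1$means, rep(1, 5), g1$sigma2)
  ge2 <- population_gmm(g2$means, rep(1, 5), g2$sigma2)
  expect_equal(permutation_test(ge1, ge2, n_perm = 49, seed = 1)$p_value, 1)

  ## identical mixtures with skewed distinct frequencies: minimal delta-G
  gs <- population_gmm(g1$means, c(0.4, 0.25, 0.2, 0.1, 0.05))
  ps <- permutation_test(gs, gs, n_perm = 199, seed = 2)
  expect_equal(ps$delta_g_obs, 0)
  expect_lt(ps$p_value, 0.05)
})

test_that("NJ recovers additive trees and rejects tiny inputs", {
  ## additive 4-taxon matrix from tree ((a:2,b:3):1,(c:2,d:4))
  d <- matrix(c(0, 5, 5, 7,
                5, 0, 6, 8,
                5, 6, 0, 6,
                7, 8, 6, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  ## path lengths on the tree reproduce the additive distances
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]], d,
               tolerance = 1e-9, ignore_attr = TRUE)

  ## three taxa: closed-form star branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(d3)
  bl <- setNames(tr3$edge.length[order(tr3$edge[, 2])][1:3], tr3$tip.label)
  expect_equal(sort(unname(bl)), c(1, 2, 3))
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("NJ topology matches UPGMA on an ultrametric matrix", {
  d <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 4,
                8, 8, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  nj_t <- nj_tree(d)
  up_t <- ape::as.phylo(hclust(as.dist(d), "average"))
  expect_equal(ape::dist.topo(ape::unroot(nj_t), ape::unroot(up_t)), 0,
               ignore_attr = TRUE)
})

test_that("tanglegram edges are mutual nearest neighbours", {
  set.seed(13)
  co <- matrix(rnorm(24), 8, 3)
  ## identical sets: the diagonal is always present
  e <- tanglegram_edges(co, co, k_nn = 3)
  expect_true(all(paste(1:8, 1:8) %in% paste(e[, 1], e[, 2])))
  ## k_nn = n gives the complete bipartite edge set
  efull <- tanglegram_edges(co, matrix(rnorm(24), 8, 3), k_nn = 8)
  expect_equal(nrow(efull), 64)
  ## a far outlier pair gets no incident edges
  co2 <- co
  co2[5, ] <- co2[5, ] + 1000
  e2 <- tanglegram_edges(co, co2, k_nn = 2)
  expect_false(any(e2[, 2] == 5))
})

test_that("full congruence analysis runs on synthetic populations", {
  spA <- synth_spec(19, n_hap_nt = 20, n_hap_aa = 16)
  alnA <- make_population(spA, patch_cols = 1:40)
  alnB <- make_population(synth_spec(20, n_hap_nt = 20, n_hap_aa = 16),
                          patch_cols = 1:40)
  cong <- gmm_congruence(alnA, alnB, k = 10, n_perm = 99, seed = 3)
  expect_s3_class(cong, "gmm_congruence")
  expect_true(cong$test$p_value >= 1 / 100 && cong$test$p_value <= 1)
  expect_equal(length(cong$pseudo1$sequence), 10)
  expect_s3_class(cong$tree1, "phylo")
  expect_true(nrow(cong$edges) >= 1)
})
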