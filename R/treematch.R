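## Population gene-tree congruence: pseudo-haplotype collapsing, 3D
## embedding, Gaussian mixture representation, Procrustes superimposition
## with mirror reflection, frequency-permutation significance, NJ trees and
## tanglegram edges.

#' Hamming distances between aligned sequences
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @return a `dist` of raw mismatch counts.
#' @export
hamming_dist <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  stats::as.dist(d)
}

#' Collapse haplotypes into k pseudo-haplotypes
#'
#' Average-linkage hierarchical clustering on pairwise Hamming distances,
#' cut at `k` clusters.  Each pseudo-haplotype is represented by its
#' highest-count member (ties by first occurrence) and carries the summed
#' member frequency.
#'
#' @param haps haplotype table as returned by [dedup_haplotypes()]
#'   (columns `sequence`, `count`, `frequency`).
#' @param k number of pseudo-haplotypes (default 15).
#' @return object of class `pseudo_haplotypes`: `sequence`, `count`,
#'   `frequency` per pseudo-haplotype, plus `members` (list of member row
#'   indices) and `assignment`.
#' @export
collapse_pseudohaplotypes <- function(haps, k = 15) {
  n <- nrow(haps)
  if (n < k) stop("only ", n, " haplotypes; choose k <= ", n)
  if (k == n) {
    cl <- seq_len(n)
  } else if (k == 1) {
    cl <- rep(1L, n)
  } else {
    hc <- stats::hclust(hamming_dist(haps$sequence), method = "average")
    cl <- stats::cutree(hc, k = k)
  }
  reps <- integer(k); cnt <- numeric(k); frq <- numeric(k)
  members <- vector("list", k)
  for (g in seq_len(k)) {
    idx <- which(cl == g)
    members[[g]] <- idx
    reps[g] <- idx[order(-haps$count[idx], idx)][1]
    cnt[g] <- sum(haps$count[idx])
    frq[g] <- sum(haps$frequency[idx])
  }
  ord <- order(-cnt, reps)
  structure(list(sequence = haps$sequence[reps][ord],
                 count = cnt[ord], frequency = frq[ord] / sum(frq),
                 members = members[ord],
                 assignment = match(cl, ord)),
            class = "pseudo_haplotypes")
}

#' @export
print.pseudo_haplotypes <- function(x, ...) {
  cat(sprintf("<pseudo_haplotypes> k=%d, top frequency %.3f\n",
              length(x$sequence), max(x$frequency)))
  invisible(x)
}

#' Classical 3D metric embedding of a distance matrix
#'
#' Classical (Torgerson) MDS keeping the three leading axes, with a
#' deterministic sign convention: the first nonzero loading of each axis is
#' made positive.  Degenerate axes (fewer than 3 positive eigenvalues, or
#' fewer than 4 points) are padded with zeros.
#'
#' @param d `dist` or symmetric matrix with zero diagonal.
#' @return k x 3 coordinate matrix.
#' @export
embed_3d <- function(d) {
  d <- as.matrix(d)
  k <- nrow(d)
  if (k == 1) return(matrix(0, 1, 3))
  co <- suppressWarnings(stats::cmdscale(d, k = min(3, k - 1)))
  out <- matrix(0, k, 3)
  out[, seq_len(ncol(co))] <- co
  for (ax in 1:3) {
    nz <- which(abs(out[, ax]) > 1e-12)
    if (length(nz) && out[nz[1], ax] < 0) out[, ax] <- -out[, ax]
  }
  rownames(out) <- rownames(d)
  out
}

#' Gaussian mixture representation of an embedded population
#'
#' Shared isotropic variance; by default `sigma2 = (0.1 * mean
#' inter-component distance)^2`, mixture weights are the pseudo-haplotype
#' frequencies.
#'
#' @param means k x 3 component means.
#' @param weights mixture weights, normalised internally.
#' @param sigma2 shared isotropic variance; default from mean pairwise
#'   distance between component means.
#' @return object of class `population_gmm`.
#' @export
population_gmm <- function(means, weights = NULL, sigma2 = NULL) {
  means <- as.matrix(means)
  stopifnot(ncol(means) == 3)
  k <- nrow(means)
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(length(weights) == k, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  if (is.null(sigma2)) {
    md <- mean(stats::dist(means))
    if (!is.finite(md) || md == 0) md <- 1
    sigma2 <- (0.1 * md)^2
  }
  stopifnot(sigma2 > 0)
  structure(list(means = means, weights = weights, sigma2 = sigma2),
            class = "population_gmm")
}

#' @export
print.population_gmm <- function(x, ...) {
  cat(sprintf("<population_gmm> k=%d components, sigma2=%.4g\n",
              nrow(x$means), x$sigma2))
  invisible(x)
}

## integral of N(.; m1, s1 I) * N(.; m2, s2 I) over R^3
gauss_overlap <- function(sqd, s1, s2) {
  (2 * pi * (s1 + s2))^(-3 / 2) * exp(-sqd / (2 * (s1 + s2)))
}

cross_sqdist <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
}

#' Squared L2 distance between two Gaussian mixture densities
#'
#' Closed form via pairwise Gaussian product integrals:
#' `int (f - g)^2 = f.f + g.g - 2 f.g`.  Zero for identical mixtures and
#' invariant to component reordering.
#'
#' @param g1,g2 `population_gmm` objects.
#' @return nonnegative scalar.
#' @export
delta_g <- function(g1, g2) {
  term <- function(a, b) {
    sq <- pmax(cross_sqdist(a$means, b$means), 0)
    ov <- gauss_overlap(sq, a$sigma2, b$sigma2)
    as.numeric(a$weights %*% ov %*% b$weights)
  }
  max(term(g1, g1) + term(g2, g2) - 2 * term(g1, g2), 0)
}

## Apply rotation R and translation t to GMM means
transform_gmm <- function(g, rotation, shift) {
  g$means <- sweep(g$means %*% t(rotation), 2, shift, "+")
  g
}

#' Procrustes superimposition of two population GMMs
#'
#' Aligns `g2` onto `g1` with rotation, translation and optionally mirror
#' reflection: frequency-weighted Kabsch on the component means (pair
#' weights are the mean of the two components' frequencies) for both the
#' proper and the improper fit, keeping the transform with the smaller
#' mixture L2 discrepancy.  No scaling.
#'
#' @param g1,g2 `population_gmm` objects with equal component counts,
#'   corresponding by index.
#' @return object of class `procrustes_gmm`: `rotation` (3 x 3, det +1 or
#'   -1), `shift`, `delta_g`, `mirrored`, and `g2_aligned`.
#' @export
procrustes_superimpose <- function(g1, g2) {
  k <- nrow(g1$means)
  if (nrow(g2$means) != k) stop("component counts differ")
  w <- (g1$weights + g2$weights) / 2
  fits <- lapply(c(FALSE, TRUE), function(mir) {
    fit <- kabsch(g2$means, g1$means, weights = w, allow_reflection = mir)
    if (mir && det(fit$rotation) > 0) return(NULL)  # improper branch gave proper fit
    g2t <- transform_gmm(g2, fit$rotation, fit$shift)
    list(fit = fit, dg = delta_g(g1, g2t), g2t = g2t,
         mirrored = det(fit$rotation) < 0)
  })
  fits <- Filter(Negate(is.null), fits)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "dg"))]]
  structure(list(rotation = best$fit$rotation, shift = best$fit$shift,
                 delta_g = best$dg, mirrored = best$mirrored,
                 g2_aligned = best$g2t),
            class = "procrustes_gmm")
}

#' @export
print.procrustes_gmm <- function(x, ...) {
  cat(sprintf("<procrustes_gmm> deltaG=%.6g%s\n", x$delta_g,
              if (x$mirrored) " (mirror)" else ""))
  invisible(x)
}

#' Frequency-permutation test of GMM congruence
#'
#' Null distribution: pseudo-haplotype frequencies of both mixtures are
#' independently permuted (component positions fixed) and the Procrustes
#' superimposition is recomputed.  `p = (1 + #\{dG_null <= dG_obs\}) /
#' (n_perm + 1)`.
#'
#' @param g1,g2 `population_gmm` objects.
#' @param n_perm number of shuffles (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param shuffle "both" (default) or "g2": which mixture's frequencies are
#'   permuted.
#' @return list of class `gmm_permutation`: `p_value`, `delta_g_obs`,
#'   `null_delta_g`.
#' @export
permutation_test <- function(g1, g2, n_perm = 1000, seed = NULL,
                             shuffle = c("both", "g2")) {
  shuffle <- match.arg(shuffle)
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  obs <- procrustes_superimpose(g1, g2)$delta_g
  k <- nrow(g1$means)
  null_dg <- vapply(seq_len(n_perm), function(i) {
    h1 <- g1; h2 <- g2
    if (shuffle == "both") h1$weights <- g1$weights[sample.int(k)]
    h2$weights <- g2$weights[sample.int(k)]
    procrustes_superimpose(h1, h2)$delta_g
  }, 0)
  p <- (1 + sum(null_dg <= obs)) / (n_perm + 1)
  structure(list(p_value = p, delta_g_obs = obs, null_delta_g = null_dg),
            class = "gmm_permutation")
}

#' @export
print.gmm_permutation <- function(x, ...) {
  cat(sprintf("<gmm_permutation> deltaG=%.6g, p=%.4g (%d shuffles)\n",
              x$delta_g_obs, x$p_value, length(x$null_delta_g)))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param d `dist` or symmetric matrix, at least 3 taxa.
#' @param labels optional tip labels.
#' @return an `ape` "phylo" tree.
#' @export
nj_tree <- function(d, labels = NULL) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("need at least 3 taxa for neighbor joining")
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- labels %||% paste0("h", seq_len(nrow(m)))
  ape::nj(stats::as.dist(m))
}

#' Mutual k-nearest-neighbour tanglegram edges
#'
#' Edge (i, j) is drawn iff point j of set 2 is among the `k_nn` closest
#' set-2 points to point i of set 1, and vice versa.  Distance ties are
#' broken by index.
#'
#' @param coords1,coords2 k x 3 coordinate matrices in a common frame.
#' @param k_nn neighbourhood size (default 5).
#' @return two-column integer matrix of edges (i in set 1, j in set 2).
#' @export
tanglegram_edges <- function(coords1, coords2, k_nn = 5) {
  coords1 <- as.matrix(coords1); coords2 <- as.matrix(coords2)
  n1 <- nrow(coords1); n2 <- nrow(coords2)
  sq <- cross_sqdist(coords1, coords2)
  knn_of_1 <- lapply(seq_len(n1), function(i)
    order(sq[i, ], seq_len(n2))[seq_len(min(k_nn, n2))])
  knn_of_2 <- lapply(seq_len(n2), function(j)
    order(sq[, j], seq_len(n1))[seq_len(min(k_nn, n1))])
  edges <- matrix(0L, 0, 2, dimnames = list(NULL, c("i", "j")))
  for (i in seq_len(n1)) for (j in knn_of_1[[i]]) {
    if (i %in% knn_of_2[[j]]) edges <- rbind(edges, c(i, j))
  }
  edges
}

#' Full congruence analysis of two population alignments
#'
#' Collapses each gene's haplotypes into `k` pseudo-haplotypes, embeds the
#' Hamming distances in 3D, builds frequency-weighted Gaussian mixtures,
#' superimposes them (Procrustes with mirror), tests significance by
#' frequency permutation, and derives NJ trees plus mutual-NN tanglegram
#' edges in the common frame.
#'
#' @param aln1,aln2 `population_alignment` objects (or precomputed haplotype
#'   tables from [dedup_haplotypes()]).
#' @param k pseudo-haplotype count (default 15).
#' @param level haplotype identity level, "nt" or "aa".
#' @param n_perm permutation count (default 1000).
#' @param seed RNG seed for the permutation test.
#' @return object of class `gmm_congruence` with elements `pseudo1`,
#'   `pseudo2`, `gmm1`, `gmm2`, `procrustes`, `test`, `tree1`, `tree2`,
#'   `edges`.
#' @export
gmm_congruence <- function(aln1, aln2, k = 15, level = "nt",
                           n_perm = 1000, seed = NULL) {
  as_haps <- function(x) {
    if (inherits(x, "population_alignment")) dedup_haplotypes(x, level) else x
  }
  h1 <- as_haps(aln1); h2 <- as_haps(aln2)
  p1 <- collapse_pseudohaplotypes(h1, k)
  p2 <- collapse_pseudohaplotypes(h2, k)
  d1 <- hamming_dist(p1$sequence); d2 <- hamming_dist(p2$sequence)
  c1 <- embed_3d(d1); c2 <- embed_3d(d2)
  g1 <- population_gmm(c1, p1$frequency)
  g2 <- population_gmm(c2, p2$frequency)
  pro <- procrustes_superimpose(g1, g2)
  test <- permutation_test(g1, g2, n_perm = n_perm, seed = seed)
  structure(list(pseudo1 = p1, pseudo2 = p2, gmm1 = g1, gmm2 = g2,
                 procrustes = pro, test = test,
                 tree1 = nj_tree(d1), tree2 = nj_tree(d2),
                 edges = tanglegram_edges(g1$means, pro$g2_aligned$means)),
            class = "gmm_congruence")
}

#' @export
print.gmm_congruence <- function(x, ...) {
  cat(sprintf(paste0("<gmm_congruence> k=%d pseudo-haplotypes per gene\n",
                     "  deltaG = %.6g%s, permutation p = %.4g\n",
                     "  %d mutual nearest-neighbour tanglegram edges\n"),
              length(x$pseudo1$sequence), x$procrustes$delta_g,
              if (x$procrustes$mirrored) " (mirror)" else "",
              x$test$p_value, nrow(x$edges)))
  invisible(x)
}

#' Plot a tanglegram of two NJ trees with mutual-NN edges
#'
#' @param x a `gmm_congruence` object.
#' @param ... passed to `ape::plot.phylo`.
#' @export
plot.gmm_congruence <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  ape::plot.phylo(x$tree1, main = "gene 1", ...)
  ape::plot.phylo(x$tree2, direction = "leftwards", main = "gene 2", ...)
  invisible(x)
}
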