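## Ligand-receptor metrics, merging binary docking poses into ternary
## complexes, constraint filtering, orientation clustering, and the
## active-site co-occurrence matrix with spectral biclustering.

min_dists_to <- function(L, R) {
  sq <- cross_sqdist(coords(L), coords(R))
  sqrt(pmax(apply(sq, 1, min), 0))
}

#' Mean nearest-atom distance from L to R
#'
#' `d(L,R) = (1/N_L) sum_i min_j |L_i R_j|`; asymmetric in (L, R) by design.
#'
#' @param L,R `protein_structure` objects or coordinate matrices.
#' @return distance in Angstrom.
#' @export
mean_distance <- function(L, R) {
  if (!nrow(coords(L)) || !nrow(coords(R))) stop("empty atom set")
  mean(min_dists_to(L, R))
}

#' Minimum inter-atomic distance between L and R (symmetric)
#'
#' @param L,R structures or coordinate matrices.
#' @export
min_distance <- function(L, R) {
  if (!nrow(coords(L)) || !nrow(coords(R))) stop("empty atom set")
  min(min_dists_to(L, R))
}

#' Number of overlapped atoms of L with respect to R
#'
#' `N_o = #\{i : min_j |L_i R_j| < t_o\}` (strict inequality).
#'
#' @param L,R structures or coordinate matrices.
#' @param t_o overlap threshold in Angstrom (default 1).
#' @return integer count.
#' @export
overlap_count <- function(L, R, t_o = 1) {
  stopifnot(t_o > 0)
  sum(min_dists_to(L, R) < t_o)
}

atom_keys <- function(s) paste(s$atoms$res_key, s$atoms$elety)

#' Merge two binary docking poses into a ternary complex
#'
#' Superposes the shared subunit A of the A--B pose onto the A of the
#' A--ligand pose (Kabsch on atoms matched by residue index and atom name)
#' and carries B along, so that A of the A--ligand pose is the anchor frame.
#' Reports the superposition RMSD (a warning above 1 Angstrom indicates
#' different A conformers) and the ligand--B contact metrics.
#'
#' @param poseAL list with `A` and `ligand` (`protein_structure`s).
#' @param poseAB list with `A` and `B`.
#' @param id optional pose identifier.
#' @param energy optional energy score (lower is better).
#' @param t_o overlap threshold for the `N_o` metric (default 1).
#' @return object of class `ternary_pose`: `A`, `B`, `ligand`,
#'   `superposition_rmsd`, `metrics` (`n_overlap`, `mean_dist`, `min_dist`),
#'   `id`, `energy`.
#' @export
merge_ternary <- function(poseAL, poseAB, id = NA, energy = NA_real_, t_o = 1) {
  kAL <- atom_keys(poseAL$A); kAB <- atom_keys(poseAB$A)
  common <- intersect(kAL, kAB)
  if (length(common) < 3)
    stop("shared subunits have fewer than 3 atoms in common; ",
         "incompatible A sequences?")
  iAL <- match(common, kAL); iAB <- match(common, kAB)
  fit <- kabsch(coords(poseAB$A)[iAB, , drop = FALSE],
                coords(poseAL$A)[iAL, , drop = FALSE])
  if (fit$rmsd > 1)
    warning(sprintf("A-subunit superposition RMSD %.2f A > 1 A: different conformers?",
                    fit$rmsd))
  B <- transform_structure(poseAB$B, fit$rotation, fit$shift)
  lig <- poseAL$ligand
  metrics <- list(n_overlap = overlap_count(lig, B, t_o),
                  mean_dist = mean_distance(lig, B),
                  min_dist = min_distance(lig, B))
  structure(list(A = poseAL$A, B = B, ligand = lig,
                 superposition_rmsd = fit$rmsd, metrics = metrics,
                 id = id, energy = energy),
            class = "ternary_pose")
}

#' @export
print.ternary_pose <- function(x, ...) {
  cat(sprintf("<ternary_pose> %s: N_o=%d, d=%.2f A, dm=%.2f A%s\n",
              ifelse(is.na(x$id), "(unnamed)", as.character(x$id)),
              x$metrics$n_overlap, x$metrics$mean_dist, x$metrics$min_dist,
              ifelse(is.na(x$energy), "", sprintf(", E=%.2f", x$energy))))
  invisible(x)
}

#' Filter ternary poses by overlap and mean-distance constraints
#'
#' A pose is kept iff the ligand--B overlapped-atom count is not higher than
#' `max_overlap` (at threshold `t_o`) and the ligand--B mean distance is not
#' higher than `max_mean_dist`; both bounds are inclusive.
#'
#' @param poses list of `ternary_pose` objects.
#' @param max_overlap maximal allowed N_o (default 10).
#' @param t_o overlap threshold (default 1 A); metrics are recomputed when
#'   it differs from the stored one.
#' @param max_mean_dist maximal allowed mean distance (default 5 A).
#' @return list with `kept` (surviving poses) and `manifest` data.frame
#'   recording id, metrics and verdict per pose.
#' @export
filter_ternary <- function(poses, max_overlap = 10, t_o = 1, max_mean_dist = 5) {
  rows <- lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    no <- overlap_count(p$ligand, p$B, t_o)
    md <- p$metrics$mean_dist
    data.frame(id = ifelse(is.na(p$id), i, p$id), n_overlap = no,
               mean_dist = md, min_dist = p$metrics$min_dist,
               energy = p$energy,
               kept = no <= max_overlap && md <= max_mean_dist)
  })
  manifest <- do.call(rbind, rows)
  list(kept = poses[manifest$kept], manifest = manifest)
}

#' Cluster ternary poses by heterodimer orientation
#'
#' All poses are brought to a common frame by superposing each pose's A onto
#' the first pose's A; single-linkage clustering is then applied to pairwise
#' RMSD over the B-subunit atoms and cut at `rmsd_threshold`.  (Ternary
#' poses merged from one shared A--ligand pose have identical ligands, which
#' carry no orientation information and would only dilute the RMSD.)  The
#' representative of each cluster is its lowest-energy pose (ties, or
#' missing energies, resolved by pose order with a warning for the latter).
#'
#' @param poses list of `ternary_pose` objects with identical atom layout.
#' @param rmsd_threshold single-linkage cut height in Angstrom (default 5).
#' @return list with `assignment` (integer vector), `representatives`
#'   (indices into `poses`), `n_clusters`.
#' @export
cluster_poses <- function(poses, rmsd_threshold = 5) {
  n <- length(poses)
  if (!n) stop("no poses")
  anchor <- poses[[1]]$A
  placed <- lapply(poses, function(p) {
    fit <- kabsch(coords(p$A), coords(anchor))
    sweep(coords(p$B) %*% t(fit$rotation), 2, fit$shift, "+")
  })
  if (length(unique(vapply(placed, nrow, 0L))) != 1)
    stop("poses do not share a common atom layout")
  rmsd <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rmsd[i, j] <- rmsd[j, i] <-
      sqrt(mean(rowSums((placed[[i]] - placed[[j]])^2)))
  }
  cl <- if (n == 1) 1L else {
    hc <- stats::hclust(stats::as.dist(rmsd), method = "single")
    stats::cutree(hc, h = rmsd_threshold)
  }
  energies <- vapply(poses, function(p) p$energy %||% NA_real_, 0)
  if (anyNA(energies))
    warning("missing energies: representatives chosen by pose order")
  reps <- vapply(sort(unique(cl)), function(g) {
    idx <- which(cl == g)
    e <- energies[idx]
    e[is.na(e)] <- Inf
    idx[order(e, idx)][1]
  }, 0L)
  list(assignment = as.integer(cl), representatives = reps,
       n_clusters = length(reps))
}

## ---- active-site co-occurrence ---------------------------------------------

#' Residue co-occurrence matrix over predicted active sites
#'
#' `M[i, j] = sum_m f_m sum_s I_{m,s}(i) I_{m,s}(j)`: the frequency-weighted
#' number of sites in which residues i and j appear together, accumulated
#' over models.
#'
#' @param models list of models, each a list with `f` (frequency weight) and
#'   `sites` (list of integer residue-index vectors).
#' @param n_residues matrix dimension; default the largest index seen.
#' @return object of class `site_comatrix`: symmetric numeric matrix `M`
#'   plus the model count.
#' @export
site_cooccurrence <- function(models, n_residues = NULL) {
  if (!length(models)) stop("empty model list")
  f <- vapply(models, function(m) m$f, 0)
  stopifnot(all(f >= 0))
  all_idx <- unlist(lapply(models, function(m) unlist(m$sites)), use.names = FALSE)
  if (is.null(n_residues)) n_residues <- max(all_idx)
  M <- matrix(0, n_residues, n_residues)
  for (m in models) {
    for (s in m$sites) {
      s <- unique(as.integer(s))
      M[s, s] <- M[s, s] + m$f
    }
  }
  structure(list(M = M, n_models = length(models)), class = "site_comatrix")
}

#' @export
print.site_comatrix <- function(x, ...) {
  cat(sprintf("<site_comatrix> %d x %d, %d models, max %.3g\n",
              nrow(x$M), ncol(x$M), x$n_models, max(x$M)))
  invisible(x)
}

#' Spectral biclustering of the co-occurrence matrix
#'
#' Treats `M` as an affinity matrix: residues with nonzero rows are embedded
#' with the leading eigenvectors of the symmetrically normalised affinity
#' (normalised-cuts embedding, rows re-normalised to the unit sphere) and
#' grouped by k-means with a fixed deterministic multi-start.  Groups are
#' ordered by decreasing summed within-group affinity.
#'
#' @param com a `site_comatrix` (or plain symmetric matrix).
#' @param k number of residue groups.
#' @param nstart k-means restarts (default 20).
#' @param seed RNG seed for k-means (default 1).
#' @return list of integer vectors of residue indices, one per group.
#' @export
bicluster_sites <- function(com, k, nstart = 20, seed = 1) {
  M <- if (inherits(com, "site_comatrix")) com$M else as.matrix(com)
  if (max(M) == 0) stop("co-occurrence matrix is all zero")
  active <- which(rowSums(M) > 0)
  if (k > length(active))
    stop("k = ", k, " exceeds the ", length(active), " residues with signal")
  A <- M[active, active, drop = FALSE]
  if (k == 1) return(list(active))
  dg <- rowSums(A)
  S <- A / sqrt(outer(dg, dg))
  ev <- eigen(S, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  nr <- sqrt(rowSums(U^2)); nr[nr == 0] <- 1
  U <- U / nr
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = nstart, iter.max = 100)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  groups <- lapply(seq_len(k), function(g) active[km$cluster == g])
  aff <- vapply(groups, function(g) sum(M[g, g]), 0)
  groups[order(-aff)]
}
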