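## Synthetic fixtures with planted truth: toy dimer slabs with a planar
## interface, pooled population alignments with localized polymorphic
## patches and skewed haplotype frequencies, congruent tree pairs, ligands
## and pose batches.  Every generator is deterministic given `spec$seed`.

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Default synthetic study specification
#'
#' The defaults emulate the study conditions the package is designed for: a
#' pooled population of 100 cloned gene copies collapsing to tens of
#' haplotypes with Zipf-skewed frequencies, and a two-subunit dimer with a
#' planar contact zone a few Angstrom wide.
#'
#' @param seed integer seed driving all generators.
#' @param ... overrides for any default field.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1, ...) {
  spec <- list(
    seed = seed,
    ## dimer geometry
    nx = 10, ny = 10,            # residues per side of each slab
    spacing = 2.5,               # residue lattice spacing (A)
    separation = 4,              # vertical gap between slabs (A)
    atoms_per_residue = 4,
    atom_spread = 0.6,           # intra-residue atom offsets (A)
    jitter = 0.15,               # coordinate noise (A)
    ## population alignment
    n_copies = 100,              # pooled clone count
    n_hap_nt = 40,               # distinct nucleotide haplotypes
    n_hap_aa = 25,               # distinct amino-acid haplotypes (<= nt)
    zipf_exponent = 1,           # frequency skew
    patch_rate = 0.6,            # per-site substitution rate inside patches
    syn_frac = 0.25,             # synonymous share of patch substitutions
    ## congruent pair
    k_pseudo = 15,
    geom_scale = 10,
    geom_noise = 0.03,           # relative coordinate noise of the matched set
    freq_noise = 0.05            # relative frequency noise of the matched set
  )
  over <- list(...)
  spec[names(over)] <- over
  class(spec) <- "synth_spec"
  spec
}

residue_letters <- function() {
  unique(unname(Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"]))
}

## Build one slab subunit: residues on an nx x ny lattice, aa identities
## given by `aa_seq` (length nx*ny), all atoms near z = z_center.
make_slab <- function(spec, aa_seq, z_center, chain, label) {
  nx <- spec$nx; ny <- spec$ny
  stopifnot(length(aa_seq) == nx * ny)
  aa_to3 <- stats::setNames(bio3d::aa.table$aa3, bio3d::aa.table$aa1)
  centers <- expand.grid(i = seq_len(nx), j = seq_len(ny), KEEP.OUT.ATTRS = FALSE)
  cx <- (centers$i - (nx + 1) / 2) * spec$spacing
  cy <- (centers$j - (ny + 1) / 2) * spec$spacing
  k <- spec$atoms_per_residue
  offs <- matrix(c(0, 0, 0,  1, 0, 0,  0, 1, 0,  1, 1, 0,
                   0.5, 0.5, 0.4,  -0.5, 0.5, 0.4, 0.5, -0.5, 0.4,
                   -0.5, -0.5, 0.4), ncol = 3, byrow = TRUE) * spec$atom_spread
  rows <- vector("list", nx * ny)
  for (rix in seq_len(nx * ny)) {
    o <- offs[((seq_len(k) - 1) %% nrow(offs)) + 1, , drop = FALSE]
    jit <- matrix(stats::runif(3 * k, -spec$jitter, spec$jitter), k, 3)
    rows[[rix]] <- data.frame(
      elety = paste0("C", seq_len(k)),
      resid = unname(aa_to3[aa_seq[rix]]),
      chain = chain, resno = rix, ins = "",
      x = cx[rix] + o[, 1] + jit[, 1],
      y = cy[rix] + o[, 2] + jit[, 2],
      z = z_center + o[, 3] + jit[, 3],
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  protein_structure(atoms, label)
}

#' Residue lattice coordinates of a synthetic slab
#'
#' @param spec a `synth_spec`.
#' @return data.frame with `resno`, `x`, `y` (lattice centers, A).
#' @export
slab_residue_centers <- function(spec) {
  centers <- expand.grid(i = seq_len(spec$nx), j = seq_len(spec$ny),
                         KEEP.OUT.ATTRS = FALSE)
  data.frame(resno = seq_len(nrow(centers)),
             x = (centers$i - (spec$nx + 1) / 2) * spec$spacing,
             y = (centers$j - (spec$ny + 1) / 2) * spec$spacing)
}

#' Residues of a synthetic slab within a lateral disc
#'
#' @param spec a `synth_spec`.
#' @param center length-2 (x, y) in A.
#' @param radius disc radius in A.
#' @return integer residue numbers (= alignment columns).
#' @export
slab_patch_columns <- function(spec, center, radius) {
  rc <- slab_residue_centers(spec)
  rc$resno[(rc$x - center[1])^2 + (rc$y - center[2])^2 <= radius^2]
}

#' Zipf-skewed integer copy counts
#'
#' Counts proportional to rank^(-a), scaled to sum to `n` by largest
#' remainder with a floor of one copy per haplotype.
#'
#' @param n_hap number of haplotypes.
#' @param n total copies.
#' @param a Zipf exponent (default 1).
#' @return integer vector of length `n_hap` summing to `n`.
#' @export
zipf_counts <- function(n_hap, n, a = 1) {
  stopifnot(n_hap <= n)
  raw <- (seq_len(n_hap))^(-a)
  tgt <- raw / sum(raw) * (n - n_hap)    # reserve one copy each
  base <- floor(tgt)
  rem <- n - n_hap - sum(base)
  extra <- integer(n_hap)
  if (rem > 0) {
    ord <- order(-(tgt - base), seq_len(n_hap))
    extra[ord[seq_len(rem)]] <- 1L
  }
  as.integer(base + extra + 1L)
}

synonymous_neighbor <- function(codon) {
  nb <- codon_neighbors(codon)
  nb[translate_codon(nb) == translate_codon(codon)]
}

nonsynonymous_neighbor <- function(codon) {
  nb <- codon_neighbors(codon)
  aa <- translate_codon(nb)
  nb[aa != translate_codon(codon) & aa != "*"]
}

#' Synthetic pooled population alignment with planted polymorphic patches
#'
#' Builds a dominant nucleotide haplotype of `L` codons and derives the
#' remaining haplotypes by single-nucleotide substitutions confined to
#' `patch_cols`.  The first `n_hap_aa` haplotypes differ at the amino-acid
#' level; further haplotypes (up to `n_hap_nt`) differ only synonymously
#' from an earlier haplotype.  Copy counts are Zipf-skewed and sum to
#' `n_copies`.  With an empty `patch_cols` (or `n_hap_nt = 1`) the alignment
#' is monomorphic.
#'
#' @param spec a `synth_spec`.
#' @param L number of aa columns (default `nx * ny`, matching the slab).
#' @param patch_cols aa columns where polymorphism is allowed (default: all).
#' @param syn_frac share of synonymous substitutions (default from spec).
#' @return a `population_alignment` with attribute `truth` (list with
#'   `patch_cols`, `polymorphic_cols`, `n_hap_nt`, `n_hap_aa`).
#' @export
make_population <- function(spec, L = spec$nx * spec$ny,
                            patch_cols = seq_len(L),
                            syn_frac = spec$syn_frac) {
  set.seed(spec$seed + 101)
  sense <- sense_codons()
  ## major haplotype: codons with a synonymous and a non-synonymous neighbour
  usable <- sense[vapply(sense, function(cd)
    length(synonymous_neighbor(cd)) > 0 && length(nonsynonymous_neighbor(cd)) > 0,
    NA)]
  major <- sample(usable, L, replace = TRUE)
  n_hap_nt <- spec$n_hap_nt
  n_hap_aa <- min(spec$n_hap_aa, n_hap_nt)
  if (n_hap_nt > 1 && !length(patch_cols))
    stop("cannot plant ", n_hap_nt, " haplotypes with no patch columns")
  haps <- list(major)
  nt_seen <- stats::setNames(TRUE, paste(major, collapse = ""))
  aa_key <- function(h) paste(translate_codon(h), collapse = "")
  aa_seen <- stats::setNames(TRUE, aa_key(major))
  mutate_hap <- function(base, synonymous_only) {
    for (try in 1:500) {
      h <- base
      hit <- patch_cols[stats::runif(length(patch_cols)) < spec$patch_rate]
      if (!length(hit)) hit <- sample(patch_cols, 1)
      for (cc in hit) {
        syn <- if (synonymous_only) TRUE else stats::runif(1) < syn_frac
        cand <- if (syn) synonymous_neighbor(h[cc]) else nonsynonymous_neighbor(h[cc])
        if (!length(cand)) next        # keep the codon; never break syn/nonsyn intent
        h[cc] <- sample(cand, 1)
      }
      key <- paste(h, collapse = "")
      if (!is.na(nt_seen[key])) next
      ## aa-distinct phase demands a new aa haplotype; the nt-only phase
      ## demands an already-seen one (purely synonymous divergence)
      if (synonymous_only == is.na(aa_seen[aa_key(h)])) next
      return(h)
    }
    stop("failed to generate a distinct haplotype; widen the patch or lower n_hap")
  }
  while (length(haps) < n_hap_aa) {
    h <- mutate_hap(major, synonymous_only = FALSE)
    nt_seen[paste(h, collapse = "")] <- TRUE
    aa_seen[aa_key(h)] <- TRUE
    haps[[length(haps) + 1]] <- h
  }
  ## nt-only haplotypes derive from the major haplotype with one synonymous
  ## step per mutated column, so every variant codon stays one synonymous
  ## nucleotide away from the major codon (multi-step synonymous chains can
  ## otherwise decompose into non-synonymous single events)
  while (length(haps) < n_hap_nt) {
    h <- mutate_hap(major, synonymous_only = TRUE)
    nt_seen[paste(h, collapse = "")] <- TRUE
    haps[[length(haps) + 1]] <- h
  }
  nt <- do.call(rbind, lapply(haps, function(h)
    unlist(strsplit(paste(h, collapse = ""), ""))))
  rownames(nt) <- paste0("hap", seq_len(nrow(nt)))
  aa <- translate_nt_matrix(nt)
  counts <- zipf_counts(length(haps), spec$n_copies, spec$zipf_exponent)
  aln <- population_alignment(aa, nt, counts)
  poly <- which(vapply(seq_len(L), function(j) length(unique(aa[, j])) > 1, NA))
  attr(aln, "truth") <- list(patch_cols = patch_cols, polymorphic_cols = poly,
                             n_hap_nt = length(haps),
                             n_hap_aa = nrow(unique(aa)))
  aln
}

#' Synthetic dimer: two residue slabs with a planar interface at z = 0
#'
#' Subunit A occupies z < 0 and subunit B z > 0, separated by
#' `spec$separation`; residue identities follow the major haplotypes of the
#' two supplied alignments (chains "A" and "B", residue number = alignment
#' column).
#'
#' @param spec a `synth_spec`.
#' @param aln_a,aln_b `population_alignment`s providing the residue
#'   sequences (defaults: monomorphic populations).
#' @return list with `a`, `b` (`protein_structure`s), and the ground truth
#'   `interface_z = 0`.
#' @export
make_dimer <- function(spec, aln_a = NULL, aln_b = NULL) {
  L <- spec$nx * spec$ny
  if (is.null(aln_a)) aln_a <- make_population(
    synth_spec(spec$seed + 11, n_hap_nt = 1, n_hap_aa = 1,
               nx = spec$nx, ny = spec$ny, n_copies = spec$n_copies))
  if (is.null(aln_b)) aln_b <- make_population(
    synth_spec(spec$seed + 12, n_hap_nt = 1, n_hap_aa = 1,
               nx = spec$nx, ny = spec$ny, n_copies = spec$n_copies))
  seq_a <- consensus_aa(aln_a); seq_b <- consensus_aa(aln_b)
  stopifnot(length(seq_a) == L, length(seq_b) == L)
  set.seed(spec$seed + 201)
  zoff <- spec$separation / 2 + spec$atom_spread * 0.4 + spec$jitter
  a <- make_slab(spec, seq_a, -zoff, chain = "A", label = "subunitA")
  b <- make_slab(spec, seq_b, +zoff, chain = "B", label = "subunitB")
  list(a = a, b = b, interface_z = 0)
}

#' Synthetic linear ligand
#'
#' A chain of atoms along a polyline in the oriented frame (default: a strip
#' along X at the interface plane).
#'
#' @param spec a `synth_spec`.
#' @param from,to endpoints (length-3).
#' @param n_atoms chain length.
#' @return a `protein_structure` labelled "ligand" (chain "L").
#' @export
make_ligand <- function(spec, from = c(-spec$spacing * 2, 0, 0),
                        to = c(spec$spacing * 2, 0, 0), n_atoms = 9) {
  tfrac <- seq(0, 1, length.out = n_atoms)
  xyz <- cbind(from[1] + tfrac * (to[1] - from[1]),
               from[2] + tfrac * (to[2] - from[2]),
               from[3] + tfrac * (to[3] - from[3]))
  atoms <- data.frame(eleno = seq_len(n_atoms), elety = "C1",
                      resid = "LIG", chain = "L", resno = seq_len(n_atoms),
                      ins = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  protein_structure(atoms, "ligand")
}

#' Matched and decoupled population-pair fixtures for the congruence test
#'
#' The matched pair shares one 3D geometry (small relative noise) and
#' correlated Zipf frequencies; the control pair has independent geometries
#' and independently shuffled frequencies.
#'
#' @param spec a `synth_spec`.
#' @return list with `matched` and `control`, each a list of two elements
#'   carrying `coords` (k x 3) and `frequency`.
#' @export
make_congruent_pair <- function(spec) {
  k <- spec$k_pseudo
  stopifnot(k >= 3)
  set.seed(spec$seed + 301)
  base <- matrix(stats::rnorm(k * 3), k, 3) * spec$geom_scale
  f1 <- zipf_counts(k, spec$n_copies, spec$zipf_exponent)
  f1 <- f1 / sum(f1)
  mk_matched <- function() {
    co <- base + matrix(stats::rnorm(k * 3), k, 3) * spec$geom_scale * spec$geom_noise
    f <- f1 * (1 + stats::rnorm(k) * spec$freq_noise)
    f <- pmax(f, 1e-4); f <- f / sum(f)
    list(coords = co, frequency = f)
  }
  matched <- list(mk_matched(), mk_matched())
  ctrl <- lapply(1:2, function(i) {
    co <- matrix(stats::rnorm(k * 3), k, 3) * spec$geom_scale
    f <- zipf_counts(k, spec$n_copies, spec$zipf_exponent)[sample.int(k)]
    list(coords = co, frequency = f / sum(f))
  })
  list(matched = matched, control = ctrl)
}

#' Synthetic batch of ternary poses with planted filter verdicts
#'
#' Builds a small anchor subunit A and a ligand, then places copies of a
#' B subunit: "pass" poses hug the ligand (mean distance well under the
#' 5 A bound, few overlaps), "fail_overlap" poses bury more than
#' `max_overlap` ligand atoms inside B at the 1 A threshold, and
#' "fail_distance" poses sit far away.  Orientation groups are planted for
#' the clustering step and energies are drawn per pose.
#'
#' @param spec a `synth_spec`.
#' @param n_pass,n_fail_overlap,n_fail_distance batch composition.
#' @param n_groups planted orientation groups among passing poses.
#' @return list with `poses` (list of `ternary_pose`) and `truth`
#'   (data.frame: id, planted verdict, orientation group).
#' @export
make_pose_batch <- function(spec, n_pass = 3, n_fail_overlap = 3,
                            n_fail_distance = 2, n_groups = 3) {
  set.seed(spec$seed + 401)
  simple_struct <- function(xyz, chain, label) {
    n <- nrow(xyz)
    protein_structure(data.frame(
      eleno = seq_len(n), elety = paste0("C", seq_len(n)), resid = "GLY",
      chain = chain, resno = 1L, ins = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE),
      label)
  }
  A <- simple_struct(matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0, 0, 0, 3),
                            ncol = 3, byrow = TRUE), "A", "anchor")
  lig_xyz <- cbind(seq(0, 8, length.out = 12), 6, 0)
  lig <- simple_struct(lig_xyz, "L", "ligand")
  poses <- list(); truth <- NULL
  add_pose <- function(b_xyz, verdict, group) {
    B <- simple_struct(b_xyz, "B", "partner")
    id <- length(poses) + 1L
    p <- merge_ternary(list(A = A, ligand = lig), list(A = A, B = B),
                       id = id, energy = round(stats::rnorm(1, -50, 5), 2))
    poses[[id]] <<- p
    truth <<- rbind(truth, data.frame(id = id, verdict = verdict, group = group))
  }
  ## orientation groups: B approaches the ligand from different sides, all
  ## at the same 3 A stand-off so every group passes the contact filter
  dirs <- list(c(0, 4, 0), c(0, -4, 0), c(0, 0, 4), c(0, 0, -4))
  for (i in seq_len(n_pass)) {
    g <- ((i - 1) %% n_groups) + 1
    b_xyz <- sweep(lig_xyz, 2, dirs[[g]], "+") +
      matrix(stats::runif(length(lig_xyz), -0.2, 0.2), nrow(lig_xyz), 3)
    add_pose(b_xyz, "pass", g)
  }
  for (i in seq_len(n_fail_overlap)) {
    ## B coincides with the ligand: every ligand atom overlapped
    add_pose(lig_xyz + stats::runif(length(lig_xyz), -0.05, 0.05),
             "fail_overlap", NA)
  }
  for (i in seq_len(n_fail_distance)) {
    add_pose(sweep(lig_xyz, 2, c(0, 40 + 10 * i, 0), "+"), "fail_distance", NA)
  }
  list(poses = poses, truth = truth)
}
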