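## Shared fixture builders and independent oracles.

## structure from a coordinate matrix: one residue per `res_of` value
toy_structure <- function(xyz, res_of = seq_len(nrow(xyz)), chain = "A",
                          resid = "GLY", label = "toy") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(resid) == 1) resid <- rep(resid, n)
  protein_structure(data.frame(
    eleno = seq_len(n), elety = paste0("C", stats::ave(res_of, res_of, FUN = seq_along)),
    resid = resid, chain = chain, resno = res_of, ins = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE), label)
}

## alignment from character strings (aa level only)
aln_from_strings <- function(seqs, counts = NULL) {
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- paste0("s", seq_along(seqs))
  population_alignment(m, counts = counts)
}

## alignment from codon strings (nt + aa)
aln_from_codons <- function(codon_rows, counts = NULL) {
  nt <- do.call(rbind, strsplit(codon_rows, ""))
  rownames(nt) <- paste0("s", seq_along(codon_rows))
  population_alignment(translate_nt_matrix(nt), nt, counts = counts)
}

## independent brute-force pi: expand count-weighted rows, average pairwise
## mismatch fraction over the selected columns (O(N^2 L))
brute_pi <- function(aln, columns = seq_len(ncol(aln$aa)), weights = NULL) {
  rows <- aln$aa[rep(seq_len(nrow(aln$aa)), aln$counts), columns, drop = FALSE]
  if (is.null(weights)) weights <- rep(1, length(columns))
  N <- nrow(rows)
  tot <- 0
  for (j in seq_len(N - 1)) for (k in (j + 1):N) {
    tot <- tot + sum((rows[j, ] != rows[k, ]) * weights)
  }
  2 * tot / (N * (N - 1) * length(columns))
}

## independent Nei-Gojobori site-count oracle: per-position loop (differs
## structurally from the package's whole-codon neighbour enumeration)
oracle_codon_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  nts <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) {
    s_p <- 0
    for (b in setdiff(bases, nts[p])) {
      mut <- nts; mut[p] <- b
      if (identical(unname(code[paste(mut, collapse = "")]),
                    unname(code[codon]))) s_p <- s_p + 1
    }
    syn <- syn + s_p / 3
  }
  c(syn = syn, nonsyn = 3 - syn)
}

## numeric grid integration of the squared L2 distance between two
## 3D Gaussian mixtures
grid_delta_g <- function(g1, g2, half_width = 6, n = 61) {
  sd_max <- sqrt(max(g1$sigma2, g2$sigma2))
  lims <- apply(rbind(g1$means, g2$means), 2, range)
  gx <- seq(lims[1, 1] - half_width * sd_max, lims[2, 1] + half_width * sd_max,
            length.out = n)
  gy <- seq(lims[1, 2] - half_width * sd_max, lims[2, 2] + half_width * sd_max,
            length.out = n)
  gz <- seq(lims[1, 3] - half_width * sd_max, lims[2, 3] + half_width * sd_max,
            length.out = n)
  dens <- function(g, pts) {
    out <- numeric(nrow(pts))
    for (i in seq_len(nrow(g$means))) {
      d2 <- rowSums(sweep(pts, 2, g$means[i, ])^2)
      out <- out + g$weights[i] *
        (2 * pi * g$sigma2)^(-3 / 2) * exp(-d2 / (2 * g$sigma2))
    }
    out
  }
  cell <- diff(gx)[1] * diff(gy)[1] * diff(gz)[1]
  tot <- 0
  for (zz in gz) {                       # slab-wise to limit memory
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = zz))
    tot <- tot + sum((dens(g1, pts) - dens(g2, pts))^2) * cell
  }
  tot
}

random_gmm <- function(k = 4, scale = 5, sigma2 = NULL) {
  population_gmm(matrix(stats::rnorm(k * 3), k, 3) * scale,
                 weights = stats::runif(k, 0.5, 2), sigma2 = sigma2)
}
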