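## Population diversity statistics: entropy profile, pairwise diversity pi,
## and per-codon synonymous / non-synonymous site and substitution counts.

#' Count-weighted Shannon entropy profile
#'
#' Per amino-acid column entropy in bits, with haplotype copy counts as
#' weights and the gap treated as an additional character state.  A
#' monomorphic column has entropy 0.
#'
#' @param aln a `population_alignment`.
#' @return numeric vector, one value per aa column.
#' @export
shannon_profile <- function(aln) {
  if (!nrow(aln$aa)) stop("empty alignment")
  vapply(seq_len(ncol(aln$aa)), function(j) {
    tab <- tapply(aln$counts, aln$aa[, j], sum)
    p <- tab / sum(tab)
    -sum(p * log2(p))
  }, 0)
}

## Per-column count of mismatching sequence pairs, counts expanded
## combinatorially: with n_a copies of state a, mismatching pairs are
## (N^2 - sum_a n_a^2) / 2.
column_mismatch_pairs <- function(chars, counts) {
  tab <- tapply(counts, chars, sum)
  N <- sum(tab)
  (N^2 - sum(tab^2)) / 2
}

#' Residue-weighted population diversity pi over a column set
#'
#' Average pairwise mismatch over all ordered pairs of population copies,
#' normalised by the number of selected columns and weighted per column:
#' \deqn{\pi = \frac{2}{N(N-1) L} \sum_{j>k} \sum_i (1 - I(A_{j,i}, A_{k,i}))\, w_i}
#' with `N` the population copy number (haplotype counts honoured
#' combinatorially, not by materialising rows) and `L = length(columns)`.
#'
#' @param aln a `population_alignment`.
#' @param columns aa column indices (default: all).
#' @param weights per-column nonnegative weights, default 1.
#' @return scalar pi.
#' @export
pi_sites <- function(aln, columns = seq_len(ncol(aln$aa)), weights = NULL) {
  if (!length(columns)) stop("empty column set")
  if (any(columns < 1 | columns > ncol(aln$aa))) stop("column index out of range")
  N <- n_copies(aln)
  if (N < 2) stop("need at least 2 population copies for pi")
  if (is.null(weights)) weights <- rep(1, length(columns))
  stopifnot(length(weights) == length(columns), all(weights >= 0))
  mism <- vapply(seq_along(columns), function(k) {
    column_mismatch_pairs(aln$aa[, columns[k]], aln$counts) * weights[k]
  }, 0)
  2 / (N * (N - 1) * length(columns)) * sum(mism)
}

## ---- Nei-Gojobori style codon counting -------------------------------------

codon_neighbors <- function(codon) {
  bases <- c("A", "C", "G", "T")
  nts <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) for (b in setdiff(bases, nts[p])) {
    mut <- nts; mut[p] <- b
    out <- c(out, paste(mut, collapse = ""))
  }
  out
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", unname(aa))
}

#' Expected synonymous/non-synonymous site counts of one codon
#'
#' Enumerates the nine single-nucleotide neighbours; the synonymous site
#' count is the fraction of neighbours preserving the amino acid, times 3.
#' Changes to or from stop codons count as non-synonymous, so
#' `syn + nonsyn == 3` always.
#'
#' @param codon 3-character string over ACGT.
#' @return named vector `c(syn=, nonsyn=)`.
#' @export
codon_site_counts <- function(codon) {
  stopifnot(nchar(codon) == 3)
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon)) stop("codon '", codon, "' contains non-ACGT characters")
  aa <- translate_codon(codon)
  nb <- codon_neighbors(codon)
  syn <- sum(translate_codon(nb) == aa) / 3
  c(syn = syn, nonsyn = 3 - syn)
}

#' Synonymous/non-synonymous substitution and site counts at one aa column
#'
#' Site counts are Nei-Gojobori expected counts per codon, averaged over
#' haplotype rows weighted by copy counts (rows with gapped codons are
#' excluded from the average).  Substitution counts enumerate the distinct
#' single-nucleotide differences between each observed codon and the major
#' (most frequent) codon; each is classified against the major-codon
#' background, multi-nucleotide variant codons being decomposed
#' position-wise.
#'
#' @param aln a `population_alignment` with a nucleotide matrix.
#' @param aa_column aa column index.
#' @return object of class `codon_column_counts`: list with `k_n_sub`,
#'   `k_s_sub`, `k_n_site`, `k_s_site`, `major_codon`.
#' @export
codon_column_counts <- function(aln, aa_column) {
  if (is.null(aln$nt)) stop("alignment has no nucleotide matrix")
  j <- aa_column
  cod <- apply(aln$nt[, (3 * j - 2):(3 * j), drop = FALSE], 1, paste, collapse = "")
  gapped <- grepl("-", cod)
  if (all(gapped)) stop("aa column ", j, " is all-gap at the nucleotide level")
  tab <- tapply(aln$counts[!gapped], cod[!gapped], sum)
  ## major codon: highest count, ties by first occurrence among rows
  first_seen <- match(names(tab), cod)
  major <- names(tab)[order(-tab, first_seen)][1]
  if (grepl("-", major)) stop("major codon at aa column ", j, " contains gaps")

  sites <- vapply(names(tab), codon_site_counts, c(syn = 0, nonsyn = 0))
  w <- as.vector(tab) / sum(tab)
  k_s_site <- sum(sites["syn", ] * w)
  k_n_site <- sum(sites["nonsyn", ] * w)

  ## distinct single-nt events relative to the major codon
  maj_nts <- strsplit(major, "")[[1]]
  events <- character(0)
  for (v in setdiff(names(tab), major)) {
    v_nts <- strsplit(v, "")[[1]]
    for (p in which(v_nts != maj_nts)) {
      events <- c(events, paste0(p, v_nts[p]))
    }
  }
  events <- unique(events)
  k_s_sub <- 0L; k_n_sub <- 0L
  for (e in events) {
    p <- as.integer(substr(e, 1, 1)); b <- substr(e, 2, 2)
    mut <- maj_nts; mut[p] <- b
    mutc <- paste(mut, collapse = "")
    if (translate_codon(mutc) == translate_codon(major)) k_s_sub <- k_s_sub + 1L
    else k_n_sub <- k_n_sub + 1L
  }
  structure(list(k_n_sub = k_n_sub, k_s_sub = k_s_sub,
                 k_n_site = k_n_site, k_s_site = k_s_site,
                 major_codon = major),
            class = "codon_column_counts")
}

#' Weighted dN/dS over a set of aa columns
#'
#' \deqn{dN/dS = \frac{\sum_i k_i^{n,sub} w_i / \sum_i k_i^{n,site} w_i}
#'                    {\sum_i k_i^{s,sub} w_i / \sum_i k_i^{s,site} w_i}}
#' When the synonymous substitution total is 0 but non-synonymous variation
#' exists, the ratio is undefined on the high side (`status =
#' "undefined-high"`); when no substitutions exist at all, `status =
#' "no-variation"`.
#'
#' @param aln a `population_alignment` with nucleotides.
#' @param columns aa column indices.
#' @param weights per-column weights, default 1.
#' @return object of class `dnds_estimate`: list with weighted totals
#'   `kn_sub`, `ks_sub`, `kn_site`, `ks_site`, the `ratio` (NA when not
#'   defined) and `status` in `"ok"`, `"undefined-high"`, `"no-variation"`.
#' @export
dnds_region <- function(aln, columns, weights = NULL) {
  if (!length(columns)) stop("empty column set")
  if (is.null(weights)) weights <- rep(1, length(columns))
  stopifnot(length(weights) == length(columns), all(weights >= 0))
  kn_sub <- ks_sub <- kn_site <- ks_site <- 0
  for (k in seq_along(columns)) {
    cc <- codon_column_counts(aln, columns[k])
    w <- weights[k]
    kn_sub <- kn_sub + cc$k_n_sub * w
    ks_sub <- ks_sub + cc$k_s_sub * w
    kn_site <- kn_site + cc$k_n_site * w
    ks_site <- ks_site + cc$k_s_site * w
  }
  status <- "ok"
  ratio <- NA_real_
  if (kn_sub == 0 && ks_sub == 0) {
    status <- "no-variation"
  } else if (ks_sub == 0) {
    status <- "undefined-high"
  } else if (kn_site > 0 && ks_site > 0) {
    ratio <- (kn_sub / kn_site) / (ks_sub / ks_site)
  } else {
    status <- "undefined-high"
  }
  structure(list(kn_sub = kn_sub, ks_sub = ks_sub, kn_site = kn_site,
                 ks_site = ks_site, ratio = ratio, status = status),
            class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("<dnds_estimate> status=%s ratio=%s (kn_sub=%.3g ks_sub=%.3g kn_site=%.3g ks_site=%.3g)\n",
              x$status, ifelse(is.na(x$ratio), "NA", sprintf("%.4f", x$ratio)),
              x$kn_sub, x$ks_sub, x$kn_site, x$ks_site))
  invisible(x)
}

#' Per-region diversity table
#'
#' @param aln a `population_alignment`.
#' @param regions named list of aa column index vectors (defaults to
#'   `aln$regions`).
#' @return data.frame with `region`, `n_columns`, `pi`.
#' @export
region_pi_table <- function(aln, regions = aln$regions) {
  if (!length(regions)) stop("no regions given")
  rows <- lapply(names(regions), function(nm) {
    cols <- regions[[nm]]
    if (!length(cols)) stop("region '", nm, "' is empty")
    data.frame(region = nm, n_columns = length(cols),
               pi = pi_sites(aln, cols), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
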