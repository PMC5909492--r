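## Structures, population alignments, and the residue <-> column mapping.

res_key <- function(chain, resno, ins = "") {
  ins <- ifelse(is.na(ins) | ins == " ", "", ins)
  paste0(chain, ":", resno, ins)
}

#' Construct a protein structure object
#'
#' @param atoms data.frame with columns `eleno`, `elety` (atom name),
#'   `resid` (3-letter residue name), `chain`, `resno`, `ins`
#'   (insertion code, "" if none), `x`, `y`, `z`.
#' @param label free-text label.
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, label = "") {
  need <- c("eleno", "elety", "resid", "chain", "resno", "ins", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("structure has no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  atoms$res_key <- res_key(atoms$chain, atoms$resno, atoms$ins)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<protein_structure> %s: %d atoms, %d residues, chains %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms), nrow(rt),
              paste(unique(rt$chain), collapse = ",")))
  invisible(x)
}

#' Residues of a structure, in file order
#'
#' @param s a `protein_structure`.
#' @return data.frame with `res_key`, `resid`, `chain`, `resno`, `ins`,
#'   `n_atoms`, ordered as residues first appear in the source file.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  first <- !duplicated(a$res_key)
  rt <- a[first, c("res_key", "resid", "chain", "resno", "ins")]
  rt$n_atoms <- as.integer(table(a$res_key)[rt$res_key])
  rownames(rt) <- NULL
  rt
}

#' Read a PDB file into a protein structure
#'
#' Single-model files; for alternate locations the highest-occupancy copy of
#' each atom is kept.  Insertion codes are preserved.  ATOM and HETATM
#' records are both retained.
#'
#' @param path PDB file.
#' @param label optional label, default the file name.
#' @return a `protein_structure`.
#' @export
read_structure <- function(path, label = basename(path)) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || !nrow(a)) stop("no ATOM/HETATM records in '", path, "'")
  a$chain[is.na(a$chain)] <- "A"
  a$insert[is.na(a$insert)] <- ""
  a$o[is.na(a$o)] <- 1
  ## altloc: keep the highest-occupancy record per (residue, atom name)
  if (any(!is.na(a$alt) & a$alt != "")) {
    key <- paste(res_key(a$chain, a$resno, a$insert), a$elety)
    ord <- order(key, -a$o)
    a <- a[ord, ][!duplicated(key[ord]), ]
    a <- a[order(a$eleno), ]
  }
  atoms <- data.frame(eleno = a$eleno, elety = a$elety, resid = a$resid,
                      chain = a$chain, resno = a$resno, ins = a$insert,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  protein_structure(atoms, label)
}

#' Write a protein structure as PDB
#'
#' Coordinates are written at standard PDB precision (3 decimals), so a
#' read/write round trip preserves them to 1e-3 Angstrom.
#'
#' @param s a `protein_structure`.
#' @param path output file.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   eleno = a$eleno, elety = a$elety, chain = a$chain,
                   insert = ifelse(a$ins == "", NA, a$ins))
  invisible(path)
}

## ---- population alignments -------------------------------------------------

#' Construct a population alignment
#'
#' Rows are haplotypes; `counts` carries the number of population copies per
#' row, so `sum(counts)` is the population (clone) size.  The nucleotide
#' matrix, when present, is in-frame and codon-aligned with the amino-acid
#' matrix (3 nt columns per aa column; gap codon "---" pairs with aa "-").
#'
#' @param aa character matrix (N x L_aa) of amino acids, gaps "-".
#' @param nt optional character matrix (N x 3 L_aa) of nucleotides.
#' @param counts positive integer copy counts per row, default 1.
#' @param regions optional named list of alignment-column index vectors.
#' @return object of class `population_alignment`.
#' @export
population_alignment <- function(aa, nt = NULL, counts = NULL, regions = list()) {
  aa <- toupper(as.matrix(aa))
  if (is.null(counts)) counts <- rep(1L, nrow(aa))
  counts <- as.integer(round(counts))
  stopifnot(length(counts) == nrow(aa), all(counts >= 1))
  if (!is.null(nt)) {
    nt <- toupper(as.matrix(nt))
    if (ncol(nt) != 3L * ncol(aa))
      stop("nt matrix must have 3 columns per aa column (",
           ncol(nt), " vs ", ncol(aa), " aa)")
    if (nrow(nt) != nrow(aa)) stop("nt and aa row counts differ")
    tr <- translate_nt_matrix(nt)
    bad <- which(tr != aa & tr != "X", arr.ind = TRUE)
    if (nrow(bad)) {
      i <- bad[1, 1]; j <- bad[1, 2]
      stop(sprintf(paste0("nt/aa mismatch at row %d ('%s'), aa column %d: ",
                          "codon %s translates to %s, aa row has %s"),
                   i, rownames(aa)[i] %||% i, j,
                   paste(nt[i, (3 * j - 2):(3 * j)], collapse = ""),
                   tr[i, j], aa[i, j]))
    }
  }
  structure(list(aa = aa, nt = nt, counts = counts, regions = regions),
            class = "population_alignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.population_alignment <- function(x, ...) {
  cat(sprintf("<population_alignment> %d haplotypes (%d copies), %d aa columns%s\n",
              nrow(x$aa), sum(x$counts), ncol(x$aa),
              if (is.null(x$nt)) "" else ", with nucleotides"))
  invisible(x)
}

#' Population size (total copy count) of an alignment
#' @param aln a `population_alignment`.
#' @export
n_copies <- function(aln) sum(aln$counts)

#' Translate a codon-aligned nucleotide matrix
#'
#' Standard genetic code; an all-gap codon gives "-", a partially gapped or
#' ambiguous codon gives "X", stop codons give "*".
#'
#' @param nt character matrix with 3k columns.
#' @return character matrix with k columns.
#' @export
translate_nt_matrix <- function(nt) {
  nt <- toupper(as.matrix(nt))
  L <- ncol(nt) / 3
  stopifnot(L == round(L))
  code <- Biostrings::GENETIC_CODE
  out <- matrix("", nrow(nt), L)
  for (j in seq_len(L)) {
    cod <- paste0(nt[, 3 * j - 2], nt[, 3 * j - 1], nt[, 3 * j])
    aa <- unname(code[cod])
    aa[cod == "---"] <- "-"
    aa[is.na(aa)] <- "X"
    out[, j] <- aa
  }
  rownames(out) <- rownames(nt)
  out
}

parse_header_counts <- function(ids) {
  m <- regmatches(ids, regexec("_n([0-9]+)$", ids))
  vapply(m, function(g) if (length(g) == 2) as.integer(g[2]) else 1L, 1L)
}

read_fasta_matrix <- function(path) {
  aln <- bio3d::read.fasta(path)
  m <- toupper(aln$ali)
  if (!nrow(m)) stop("no sequences in '", path, "'")
  m[m == "."] <- "-"
  m
}

#' Read a population alignment from FASTA
#'
#' Reads an in-frame nucleotide alignment and/or an amino-acid alignment.
#' When only nucleotides are given they are translated internally (standard
#' code, all-gap codons to "-").  Copy counts default to 1 per record and
#' may be supplied as a sidecar TSV (columns `id`, `count`), as a named
#' vector, or embedded in headers as a `_n<k>` suffix.  Identical records
#' (nucleotide level when nucleotides are present, otherwise amino-acid
#' level) are merged with summed counts.
#'
#' @param nt_path FASTA of aligned in-frame nucleotide sequences (optional if
#'   `aa_path` given).
#' @param aa_path FASTA of aligned amino-acid sequences (optional).
#' @param counts named integer vector, or path to a two-column TSV.
#' @return a `population_alignment`.
#' @export
read_population_fasta <- function(nt_path = NULL, aa_path = NULL, counts = NULL) {
  if (is.null(nt_path) && is.null(aa_path))
    stop("give at least one of nt_path, aa_path")
  nt <- if (!is.null(nt_path)) read_fasta_matrix(nt_path)
  aa <- if (!is.null(aa_path)) read_fasta_matrix(aa_path)
  if (!is.null(nt)) {
    lens <- ncol(nt)
    if (lens %% 3 != 0) stop("nt alignment length ", lens, " not divisible by 3")
  }
  if (is.null(aa)) aa <- translate_nt_matrix(nt)
  if (!is.null(nt) && nrow(nt) != nrow(aa))
    stop("nt and aa FASTA files have different sequence counts")
  ids <- rownames(aa) %||% as.character(seq_len(nrow(aa)))

  cnt <- parse_header_counts(ids)
  if (!is.null(counts)) {
    if (is.character(counts) && length(counts) == 1) {
      tab <- utils::read.table(counts, header = FALSE, sep = "\t",
                               col.names = c("id", "count"),
                               stringsAsFactors = FALSE)
      counts <- stats::setNames(as.integer(tab$count), tab$id)
    }
    hit <- ids %in% names(counts)
    cnt[hit] <- as.integer(counts[ids[hit]])
  }

  ## merge duplicate records
  keyseq <- if (!is.null(nt)) apply(nt, 1, paste, collapse = "")
            else apply(aa, 1, paste, collapse = "")
  grp <- match(keyseq, unique(keyseq))
  keep <- !duplicated(grp)
  agg <- as.integer(tapply(cnt, grp, sum)[as.character(grp[keep])])
  aa2 <- aa[keep, , drop = FALSE]
  nt2 <- if (!is.null(nt)) nt[keep, , drop = FALSE]
  rownames(aa2) <- ids[keep]
  if (!is.null(nt2)) rownames(nt2) <- ids[keep]
  population_alignment(aa2, nt2, agg)
}

#' Write a population alignment to FASTA
#'
#' Copy counts are embedded in the headers as a `_n<count>` suffix, so the
#' file round-trips through [read_population_fasta()].
#'
#' @param aln a `population_alignment`.
#' @param nt_path output path for the nucleotide FASTA (if `aln` has one).
#' @param aa_path optional output path for the amino-acid FASTA.
#' @export
write_population_fasta <- function(aln, nt_path = NULL, aa_path = NULL) {
  ids <- rownames(aln$aa) %||% paste0("hap", seq_len(nrow(aln$aa)))
  hdr <- paste0(">", sub("_n[0-9]+$", "", ids), "_n", aln$counts)
  dump <- function(m, path) {
    writeLines(paste0(hdr, "\n", apply(m, 1, paste, collapse = "")), path)
  }
  if (!is.null(nt_path)) {
    if (is.null(aln$nt)) stop("alignment has no nucleotide matrix")
    dump(aln$nt, nt_path)
  }
  if (!is.null(aa_path)) dump(aln$aa, aa_path)
  invisible(aln)
}

#' Unique haplotypes with counts and frequencies
#'
#' @param aln a `population_alignment`.
#' @param level "nt" or "aa": which sequence level defines identity.
#' @return data.frame with `sequence`, `count`, `frequency`, sorted by
#'   descending count (ties by first occurrence); frequencies sum to 1.
#' @export
dedup_haplotypes <- function(aln, level = c("aa", "nt")) {
  level <- match.arg(level)
  m <- if (level == "nt") {
    if (is.null(aln$nt)) stop("alignment has no nucleotide matrix")
    aln$nt
  } else aln$aa
  seqs <- apply(m, 1, paste, collapse = "")
  uniq <- unique(seqs)
  grp <- match(seqs, uniq)
  cnt <- as.vector(tapply(aln$counts, grp, sum)[as.character(seq_along(uniq))])
  ord <- order(-cnt, seq_along(cnt))
  data.frame(sequence = uniq[ord], count = cnt[ord],
             frequency = cnt[ord] / sum(cnt), stringsAsFactors = FALSE)
}

## ---- structure <-> alignment mapping ---------------------------------------

#' Count-weighted consensus of an amino-acid alignment
#' @param aln a `population_alignment`.
#' @return character vector of per-column consensus residues ("-" possible).
#' @export
consensus_aa <- function(aln) {
  apply_cols <- function(j) {
    tab <- tapply(aln$counts, aln$aa[, j], sum)
    tab <- tab[order(-tab, names(tab))]     # ties broken alphabetically
    names(tab)[1]
  }
  vapply(seq_len(ncol(aln$aa)), apply_cols, "")
}

aa3to1 <- function(resid) {
  out <- bio3d::aa321(resid)
  out[is.na(out) | out == ""] <- "X"
  out
}

#' Map structure residues to alignment columns
#'
#' Slides the (ungapped) one-letter sequence of the chosen chain along the
#' count-weighted alignment consensus and picks the offset with maximal
#' identity.  Gap consensus columns never match.  Fails when the best
#' identity is below `threshold`, which usually means a wrong chain or a
#' wrong alignment was supplied.
#'
#' @param s a `protein_structure`.
#' @param aln a `population_alignment`.
#' @param chain chain id, default the first chain.
#' @param threshold minimum acceptable identity fraction (default 0.9).
#' @return object of class `residue_column_map`: data.frame-style `pairs`
#'   (`res_key`, `column`), plus `offset` (0-based) and `identity`.
#' @export
map_structure_to_alignment <- function(s, aln, chain = NULL, threshold = 0.9) {
  rt <- residue_table(s)
  if (is.null(chain)) chain <- rt$chain[1]
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (!nrow(rt)) stop("chain '", chain, "' not present in structure")
  sq <- aa3to1(rt$resid)
  cons <- consensus_aa(aln)
  Ls <- length(sq); La <- length(cons)
  if (Ls > La) stop("structure chain longer than alignment (", Ls, " > ", La, ")")
  idents <- vapply(0:(La - Ls), function(off) {
    mean(sq == cons[(off + 1):(off + Ls)])
  }, 0)
  best <- which.max(idents)                 # ties: lowest offset
  identity <- idents[best]
  if (identity < threshold)
    stop(sprintf(paste0("best identity %.3f below threshold %.2f; ",
                        "check that the chain and alignment correspond"),
                 identity, threshold))
  off <- best - 1L
  structure(list(pairs = data.frame(res_key = rt$res_key,
                                    column = off + seq_len(Ls),
                                    stringsAsFactors = FALSE),
                 offset = off, identity = identity, chain = chain),
            class = "residue_column_map")
}

#' @export
print.residue_column_map <- function(x, ...) {
  cat(sprintf("<residue_column_map> chain %s: %d residues, offset %d, identity %.3f\n",
              x$chain, nrow(x$pairs), x$offset, x$identity))
  invisible(x)
}

#' Read region annotations from TSV
#'
#' Two columns: region name and comma-separated 1-based alignment column
#' indices.
#'
#' @param path TSV file.
#' @return named list of integer vectors.
#' @export
read_region_annotations <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("name", "cols"),
                           stringsAsFactors = FALSE)
  stats::setNames(lapply(strsplit(tab$cols, ","), function(v) as.integer(v)),
                  tab$name)
}
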