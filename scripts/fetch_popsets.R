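#!/usr/bin/env Rscript
## Downloads the two deposited population sequence sets from GenBank and
## prepares the aligned FASTA files expected under inst/extdata/.  Requires
## network access and (for alignment) mafft on the PATH; none of the test
## suite depends on running this script.
##
##   NFR5: GenBank Popset ID 1041522217 (100 cloned fragments)
##   K1:   GenBank Nucleotide IDs MF692841-MF692940 (100 cloned fragments)
##
## Usage: Rscript scripts/fetch_popsets.R

eutils <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)

fetch <- function(query, raw_path) {
  url <- paste0(eutils, "?db=nucleotide&rettype=fasta&retmode=text&", query)
  message("fetching ", url)
  download.file(url, raw_path, quiet = TRUE)
}

align <- function(raw_path, out_path) {
  if (nzchar(Sys.which("mafft"))) {
    system2("mafft", c("--auto", "--quiet", raw_path), stdout = out_path)
  } else {
    warning("mafft not found; copying unaligned sequences (equal-length sets only)")
    file.copy(raw_path, out_path, overwrite = TRUE)
  }
  ## in-frame trimming is data-dependent: inspect the alignment and trim to
  ## the coding frame before use (codon-aligned length divisible by 3)
  message("wrote ", out_path, " - verify reading frame before installing")
}

tmp1 <- tempfile(fileext = ".fasta")
fetch("id=1041522217", tmp1)                      # popset: NFR5
align(tmp1, "inst/extdata/nfr5_population_nt.fasta")

ids <- paste0("MF", 692841:692940)                # K1
tmp2 <- tempfile(fileext = ".fasta")
fetch(paste0("id=", paste(ids, collapse = ",")), tmp2)
align(tmp2, "inst/extdata/k1_population_nt.fasta")
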