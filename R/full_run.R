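## Pipeline orchestration: alignments -> congruence -> surface -> maps ->
## RG classification -> ligand colocalization, with TSV/PNG/markdown output.

#' Default run configuration
#'
#' All tunable pipeline parameters with their defaults: cylinder radius
#' `r = 4` A, grid `step = 1` A, `gap_threshold = 8` A, overlap threshold
#' `t_o = 1` A, pose constraints `max_overlap = 10` and
#' `max_mean_dist = 5` A, RG filter `black_frac = 0.2` and `ratio = 2`,
#' `k_pseudo = 15`, `n_perm = 1000`, `k_nn = 5`.  Unknown keys are rejected.
#'
#' @param ... overrides.
#' @return named list.
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1, r = 4, step = 1, gap_threshold = 8, t_o = 1,
              max_overlap = 10, max_mean_dist = 5, black_frac = 0.2,
              ratio = 2, k_pseudo = 15, n_perm = 1000, k_nn = 5,
              measure = "pi", map_threshold = 0.9,
              aln_a = NULL, aln_b = NULL, pdb_a = NULL, pdb_b = NULL,
              ligand = NULL, synthetic = TRUE)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full contact-zone pipeline
#'
#' Executes the analysis end to end: load (or synthesise) the two
#' population alignments and the dimer structure, test gene-tree
#' congruence, orient the complex, build the contact surface, compute both
#' subunits' sliding-cylinder diversity maps, classify the RG plot, and
#' project the ligand if one is given.  All randomness is driven by
#' `config$seed`; rerunning with the same seed reproduces every output
#' byte for byte.
#'
#' @param config list from [run_config()]; with `synthetic = TRUE` (default)
#'   fixtures are generated, otherwise `aln_a`, `aln_b` (FASTA paths),
#'   `pdb_a`, `pdb_b` and optionally `ligand` must point to input files.
#' @param out_dir output directory (created); TSVs, PNGs, Newick trees and
#'   a `report.md` are written there.
#' @return invisibly, a list with all intermediate objects and the summary.
#' @export
full_run <- function(config = run_config(), out_dir = tempfile("slidecyl_run_")) {
  cfg <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  if (isTRUE(cfg$synthetic)) {
    sp <- synth_spec(cfg$seed)
    patch <- slab_patch_columns(sp, c(0, 0), 4)
    aln_a <- stage("alignments", make_population(sp, patch_cols = patch))
    aln_b <- stage("alignments", make_population(
      synth_spec(cfg$seed + 1000, n_hap_nt = sp$n_hap_nt,
                 n_hap_aa = sp$n_hap_aa), patch_cols = patch))
    dim_ab <- stage("structures", make_dimer(sp, aln_a, aln_b))
    a <- dim_ab$a; b <- dim_ab$b
    ligand <- make_ligand(sp)
  } else {
    aln_a <- stage("alignments", read_population_fasta(cfg$aln_a))
    aln_b <- stage("alignments", read_population_fasta(cfg$aln_b))
    a <- stage("structures", read_structure(cfg$pdb_a))
    b <- stage("structures", read_structure(cfg$pdb_b))
    ligand <- if (!is.null(cfg$ligand)) stage("structures", read_structure(cfg$ligand))
  }

  hap_a <- dedup_haplotypes(aln_a, "nt"); hap_b <- dedup_haplotypes(aln_b, "nt")
  utils::write.table(
    data.frame(gene = c("A", "B"),
               n_copies = c(n_copies(aln_a), n_copies(aln_b)),
               nt_haplotypes = c(nrow(hap_a), nrow(hap_b)),
               aa_haplotypes = c(nrow(dedup_haplotypes(aln_a, "aa")),
                                 nrow(dedup_haplotypes(aln_b, "aa")))),
    file.path(out_dir, "haplotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(column = seq_len(ncol(aln_a$aa)),
               entropy_a = shannon_profile(aln_a),
               entropy_b = shannon_profile(aln_b)),
    file.path(out_dir, "entropy.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  cong <- stage("congruence",
                gmm_congruence(aln_a, aln_b, k = cfg$k_pseudo,
                               n_perm = cfg$n_perm, seed = cfg$seed))
  ape::write.tree(cong$tree1, file.path(out_dir, "tree_a.nwk"))
  ape::write.tree(cong$tree2, file.path(out_dir, "tree_b.nwk"))
  utils::write.table(as.data.frame(cong$edges),
                     file.path(out_dir, "tanglegram_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ori <- stage("surface", orient_complex(a, b))
  surf <- stage("surface", build_surface(ori$a, ori$b, step = cfg$step,
                                         gap_threshold = cfg$gap_threshold))
  write_map_tsv(surf, file.path(out_dir, "surface.tsv"))

  map_a <- stage("maps", diversity_map(
    surf, ori$a, aln_a, map_structure_to_alignment(ori$a, aln_a,
                                                   threshold = cfg$map_threshold),
    measure = cfg$measure, r = cfg$r))
  map_b <- stage("maps", diversity_map(
    surf, ori$b, aln_b, map_structure_to_alignment(ori$b, aln_b,
                                                   threshold = cfg$map_threshold),
    measure = cfg$measure, r = cfg$r))
  write_map_tsv(map_a, file.path(out_dir, "map_a.tsv"))
  write_map_tsv(map_b, file.path(out_dir, "map_b.tsv"))

  cls <- stage("rgplot", classify_rg(normalize_channels(map_a, map_b),
                                     black_frac = cfg$black_frac,
                                     ratio = cfg$ratio))
  write_rg_tsv(cls, file.path(out_dir, "rg_nodes.tsv"))
  fr <- area_fractions(cls)
  utils::write.table(data.frame(label = names(fr), percent = as.numeric(fr)),
                     file.path(out_dir, "area_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  grDevices::png(file.path(out_dir, "rg_plot.png"), 700, 700)
  plot(cls)
  grDevices::dev.off()

  coloc <- NULL
  if (!is.null(ligand)) {
    lig_o <- transform_structure(ligand, ori$rotation, ori$shift)
    nodes <- stage("colocalization",
                   suppressWarnings(project_ligand(lig_o, surf)))
    if (length(nodes)) coloc <- colocalization(cls, nodes)
  }

  rep_lines <- c(
    "# slidecyl pipeline report", "",
    sprintf("seed: %d", cfg$seed),
    sprintf("haplotypes (nt/aa): gene A %d/%d, gene B %d/%d",
            nrow(hap_a), nrow(dedup_haplotypes(aln_a, "aa")),
            nrow(hap_b), nrow(dedup_haplotypes(aln_b, "aa"))),
    sprintf("congruence: deltaG = %.6g, permutation p = %.4g",
            cong$procrustes$delta_g, cong$test$p_value),
    sprintf("surface: %d defined nodes (step %g A, gap <= %g A)",
            sum(surf$nodes$defined), cfg$step, cfg$gap_threshold),
    paste0("area fractions: ",
           paste(sprintf("%s %.1f%%", names(fr), fr), collapse = ", ")),
    if (!is.null(coloc))
      paste0("ligand colocalization: ",
             paste(sprintf("%s %.2f", names(coloc), coloc), collapse = ", "))
    else "ligand colocalization: (no ligand)")
  writeLines(rep_lines, file.path(out_dir, "report.md"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, NA)],
                   file.path(out_dir, "config.yaml"))

  invisible(list(config = cfg, aln_a = aln_a, aln_b = aln_b,
                 congruence = cong, oriented = ori, surface = surf,
                 map_a = map_a, map_b = map_b, classification = cls,
                 area_fractions = fr, colocalization = coloc,
                 out_dir = out_dir))
}
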