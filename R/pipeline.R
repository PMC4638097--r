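#' Run the full clonality pipeline for one patient
#'
#' Orchestrates every stage in order: VCF reading, high-confidence filtering,
#' known-site exclusion, binarization, sharing partition, BioNJ tree with
#' column-bootstrap support (rooted on the reference pseudo-sample), UPGMA
#' concordance, monophyly verdict and contamination checks, sequence-context
#' classification with TpC* comparisons, functional enrichment and candidate
#' driver overlap. Deterministic given `seed`. With `outdir` set, all
#' intermediates are persisted as plain-text artifacts (TSV, Newick, JSON)
#' from which every reported number can be re-derived.
#'
#' @param vcf multi-sample VCF path.
#' @param sample_roles named role vector (`"normal"` / `"tumour"`).
#' @param genome reference FASTA path, or named character vector of contigs.
#' @param known optional known-sites VCF path (dbSNP stand-in).
#' @param gene_list optional candidate driver gene list (vector or file).
#' @param min_reads per-sample supporting-read threshold (default 4).
#' @param boot_reps bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param ta_threshold tumour-associated-fraction contamination threshold.
#' @param outdir optional artifact directory.
#' @return a `patient_report` list: `roles`, `attrition`, `n_known_removed`,
#'   `partition` (counts object), `tree` (rooted, support-annotated `phylo`),
#'   `newick`, `splits`, `monophyly`, `upgma_concordant`, `contamination`,
#'   `verdict`, `context_tallies`, `functional` and `tpc_trunk_germline` /
#'   `tpc_trunk_private` (`enrichment_result`s), `drivers`, `parameters`.
#' @export
run_pipeline <- function(vcf, sample_roles, genome, known = NULL,
                         gene_list = NULL, min_reads = 4L, boot_reps = 1000L,
                         seed = 1L, ta_threshold = 0.20, outdir = NULL) {
  check_roles(sample_roles)
  vs <- read_multisample_vcf(vcf, sample_roles)
  vs <- filter_high_confidence(vs, min_reads = min_reads)
  attrition <- attr(vs, "attrition")
  n_known_removed <- 0L
  if (!is.null(known)) {
    vs <- exclude_known_sites(vs, known)
    n_known_removed <- attr(vs, "n_known_removed")
  }
  mmat <- binarize(vs)
  if (ncol(mmat$mat) == 0L)
    stop("stage binarize: no markers retained after filtering")
  mref <- add_reference_row(mmat)

  part <- partition_markers(mmat)
  pcounts <- partition_counts(mmat)

  bs <- bootstrap_support(mref, reps = boot_reps, seed = seed)
  rooted <- annotate_supports(root_with_reference(bs$tree), bs$splits)
  mono <- tumour_monophyly(rooted, mref$roles, bs$splits)
  # contamination branch criterion on the additive (Hamming) scale, where
  # terminal branch lengths count lineage-specific markers
  hamming_rooted <- root_with_reference(
    bionj_tree(binary_distance(mref)^2))
  contam <- flag_normal_contamination(hamming_rooted, pcounts, sample_roles,
                                      ta_threshold = ta_threshold)
  upgma <- upgma_tree(binary_distance(mref))
  upgma_mono <- tumour_monophyly(upgma, mref$roles)
  verdict <- if (mono$monophyletic)
    "clonal origin (tumour samples monophyletic)"
  else "not monophyletic / field-consistent"

  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- load_genome(genome)
  contexts <- classify_contexts(mmat$info, genome)
  tallies <- tally_contexts(contexts, part$class)
  impacts <- classify_impacts(mmat)
  functional <- compare_functional(part, impacts)
  tpc_tg <- compare_tpc(part, contexts, "trunk_vs_germline")
  tpc_tp <- compare_tpc(part, contexts, "trunk_vs_private")
  drivers <- if (!is.null(gene_list))
    driver_overlap(mmat, gene_list, part, impacts, contexts) else NULL

  report <- structure(list(
    roles = sample_roles,
    attrition = attrition,
    n_known_removed = n_known_removed,
    n_markers = ncol(mmat$mat),
    partition = pcounts,
    tree = rooted,
    newick = ape::write.tree(rooted),
    splits = bs$splits,
    monophyly = mono,
    upgma_concordant = upgma_mono$monophyletic == mono$monophyletic,
    contamination = contam,
    verdict = verdict,
    context_tallies = tallies,
    functional = functional,
    tpc_trunk_germline = tpc_tg,
    tpc_trunk_private = tpc_tp,
    drivers = drivers,
    parameters = list(min_reads = min_reads, boot_reps = boot_reps,
                      seed = seed, ta_threshold = ta_threshold)),
    class = "patient_report")

  if (!is.null(outdir))
    write_report_artifacts(report, mref, part, contexts, impacts, outdir)
  report
}

#' @noRd
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  stats::setNames(as.character(g), names(g))
}

#' @export
print.patient_report <- function(x, ...) {
  cat("clonetrace patient report\n")
  cat("  markers retained:", x$n_markers,
      sprintf("(attrition: %s)",
              paste(names(x$attrition), x$attrition, sep = "=",
                    collapse = ", ")), "\n")
  cat("  sharing classes:",
      paste(names(x$partition$counts), x$partition$counts, sep = "=",
            collapse = ", "), "\n")
  cat(sprintf("  tumour-associated fraction: %.3f\n",
              x$partition$tumour_associated_fraction))
  cat(sprintf("  verdict: %s (support %.1f%%)\n", x$verdict,
              x$monophyly$support))
  if (x$contamination$flagged)
    cat("  WARNING: normal-sample contamination criteria fired:",
        paste(names(which(x$contamination$criteria)), collapse = ", "), "\n")
  cat(sprintf("  TpC* trunk vs germline: fold %.2f, p = %.3g\n",
              x$tpc_trunk_germline$fold, x$tpc_trunk_germline$p))
  cat(sprintf("  TpC* trunk vs private:  fold %.2f, p = %.3g\n",
              x$tpc_trunk_private$fold, x$tpc_trunk_private$p))
  cat(sprintf("  functional trunk vs germline: fold %.2f, p = %.3g\n",
              x$functional$fold, x$functional$p))
  invisible(x)
}

#' @noRd
enrichment_row <- function(name, e) {
  data.frame(comparison = name,
             g1 = e$groups[1], g1_hit = e$table[1, 1], g1_n = sum(e$table[1, ]),
             g2 = e$groups[2], g2_hit = e$table[2, 1], g2_n = sum(e$table[2, ]),
             fold = e$fold, p = e$p, stringsAsFactors = FALSE)
}

#' @noRd
write_report_artifacts <- function(report, mref, part, contexts, impacts,
                                   outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_marker_matrix(mref, file.path(outdir, "matrix.tsv"))
  utils::write.table(cbind(part, contexts, impacts[, c("tier", "functional",
                                                       "genes")]),
                     file.path(outdir, "markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(report$newick, file.path(outdir, "tree.nwk"))
  utils::write.table(report$splits, file.path(outdir, "splits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stats_df <- rbind(enrichment_row("functional_trunk_vs_germline",
                                   report$functional),
                    enrichment_row("tpc_trunk_vs_germline",
                                   report$tpc_trunk_germline),
                    enrichment_row("tpc_trunk_vs_private",
                                   report$tpc_trunk_private))
  utils::write.table(stats_df, file.path(outdir, "stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$drivers))
    utils::write.table(report$drivers$hits, file.path(outdir, "drivers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    roles = as.list(report$roles),
    attrition = as.list(report$attrition),
    n_known_removed = report$n_known_removed,
    n_markers = report$n_markers,
    class_counts = as.list(report$partition$counts),
    tumour_associated_fraction = report$partition$tumour_associated_fraction,
    newick = report$newick,
    monophyletic = report$monophyly$monophyletic,
    tumour_clade_support = report$monophyly$support,
    upgma_concordant = report$upgma_concordant,
    contamination_flagged = report$contamination$flagged,
    contamination_criteria = as.list(report$contamination$criteria),
    verdict = report$verdict,
    tpc_fraction_by_class = report$context_tallies$tpc,
    functional = enrichment_row("functional_trunk_vs_germline",
                                report$functional),
    tpc_trunk_germline = enrichment_row("tpc_trunk_vs_germline",
                                        report$tpc_trunk_germline),
    tpc_trunk_private = enrichment_row("tpc_trunk_vs_private",
                                       report$tpc_trunk_private),
    parameters = report$parameters)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  md <- c("# clonetrace patient report", "",
          sprintf("- markers retained: %d", report$n_markers),
          sprintf("- verdict: **%s** (tumour clade support %.1f%%)",
                  report$verdict, report$monophyly$support),
          sprintf("- contamination flag: %s",
                  if (report$contamination$flagged) "FIRED" else "clean"),
          sprintf("- TpC* trunk vs germline: fold %.2f (p = %.3g)",
                  report$tpc_trunk_germline$fold, report$tpc_trunk_germline$p),
          sprintf("- TpC* trunk vs private: fold %.2f (p = %.3g)",
                  report$tpc_trunk_private$fold, report$tpc_trunk_private$p),
          sprintf("- functional trunk vs germline: fold %.2f (p = %.3g)",
                  report$functional$fold, report$functional$p))
  writeLines(md, file.path(outdir, "report.md"))
  invisible(outdir)
}
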