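#' Configuration for the synthetic multifocal patient generator
#'
#' Defines one simulated patient: a small random reference genome, one normal
#' mucosa sample and `n_tumours` tumour samples, and planted markers in each
#' sharing class. The defaults emulate the scale of a real multifocal
#' bladder-cancer exome patient of clonal origin: ~900 germline variants
#' shared by all samples, a trunk of 450 somatic variants shared by all
#' tumours, small private sets per tumour (40/25/15), a handful of mixed
#' ("other") classes and 3 normal-private variants. Class-specific TpC*
#' context fractions (0.60 trunk, 0.20 private, 0.10 germline) plant the
#' APOBEC timing signal, and functional fractions (0.40 trunk vs 0.20
#' germline) plant the functional enrichment.
#'
#' @param model `"clonal"` (trunk present) or `"field"` (independent foci:
#'   `n_trunk` is forced to 0; supplying a positive `n_trunk` is an error).
#' @param n_tumours number of tumour samples (>= 2; default 3).
#' @param n_germline,n_trunk,n_private,n_other_normal,n_other_tumour,n_normal_private
#'   class sizes; `n_private` is a vector of length `n_tumours`.
#' @param tpc_frac,functional_frac named fractions per class
#'   (germline, trunk, private, other_normal, other_tumour, normal_private).
#' @param contamination fraction of trunk markers leaked into the normal
#'   sample (patient-3-like neoplastic contamination; default 0).
#' @param known_germline_frac fraction of germline markers also written to
#'   the known-sites VCF (default 0.05).
#' @param mean_depth,dropout depth model: mean sequencing depth and the
#'   probability that a (marker, sample) genotype is given a sub-threshold
#'   depth (< 4 reads) to exercise the high-confidence filter (default 0).
#' @param genome_contigs,contig_length,gc genome model (default 2 contigs of
#'   100 kb at GC 0.41).
#' @param boot_reps default bootstrap replicates for downstream runs.
#' @param seed integer seed driving all randomness of
#'   [simulate_dataset()] through a single RNG stream.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(model = c("clonal", "field"),
                       n_tumours = 3L,
                       n_germline = 900L,
                       n_trunk = if (match.arg(model) == "field") 0L else 450L,
                       n_private = c(40L, 25L, 15L),
                       n_other_normal = 12L,
                       n_other_tumour = 12L,
                       n_normal_private = 3L,
                       tpc_frac = c(germline = 0.10, trunk = 0.60,
                                    private = 0.20, other_normal = 0.10,
                                    other_tumour = 0.20, normal_private = 0.10),
                       functional_frac = c(germline = 0.20, trunk = 0.40,
                                           private = 0.40, other_normal = 0.20,
                                           other_tumour = 0.40,
                                           normal_private = 0.20),
                       contamination = 0,
                       known_germline_frac = 0.05,
                       mean_depth = 30,
                       dropout = 0,
                       genome_contigs = 2L,
                       contig_length = 100000L,
                       gc = 0.41,
                       boot_reps = 1000L,
                       seed = 1L) {
  model <- match.arg(model)
  if (model == "field" && n_trunk > 0L)
    stop("field model is incompatible with n_trunk > 0 (foci share no trunk)")
  if (model == "clonal" && n_trunk <= 0L)
    stop("clonal model requires n_trunk > 0")
  if (n_tumours < 2L) stop("need at least 2 tumour samples")
  if (length(n_private) == 1L) n_private <- rep(n_private, n_tumours)
  if (length(n_private) != n_tumours)
    stop("`n_private` must have one entry per tumour")
  if (n_tumours < 3L && n_other_tumour > 0L)
    stop("OTHER_TUMOUR markers need >= 3 tumours")
  counts <- c(n_germline, n_trunk, n_private, n_other_normal, n_other_tumour,
              n_normal_private)
  if (any(counts < 0L)) stop("class sizes must be non-negative")
  need <- c("germline", "trunk", "private", "other_normal", "other_tumour",
            "normal_private")
  if (!all(need %in% names(tpc_frac)) || !all(need %in% names(functional_frac)))
    stop("tpc_frac and functional_frac must name all classes: ",
         paste(need, collapse = ", "))
  stopifnot(all(tpc_frac >= 0 & tpc_frac <= 1),
            all(functional_frac >= 0 & functional_frac <= 1),
            contamination >= 0, contamination <= 1,
            known_germline_frac >= 0, known_germline_frac <= 1,
            gc > 0, gc < 1, mean_depth > 0,
            dropout >= 0, dropout <= 1)
  samples <- c("N", paste0("T", seq_len(n_tumours)))
  roles <- stats::setNames(c("normal", rep("tumour", n_tumours)), samples)
  structure(list(model = model, n_tumours = n_tumours,
                 n_germline = as.integer(n_germline),
                 n_trunk = as.integer(n_trunk),
                 n_private = as.integer(n_private),
                 n_other_normal = as.integer(n_other_normal),
                 n_other_tumour = as.integer(n_other_tumour),
                 n_normal_private = as.integer(n_normal_private),
                 tpc_frac = tpc_frac, functional_frac = functional_frac,
                 contamination = contamination,
                 known_germline_frac = known_germline_frac,
                 mean_depth = mean_depth, dropout = dropout,
                 genome_contigs = as.integer(genome_contigs),
                 contig_length = as.integer(contig_length), gc = gc,
                 boot_reps = as.integer(boot_reps), seed = as.integer(seed),
                 samples = samples, roles = roles),
            class = "sim_config")
}

# Bladder-relevant driver symbols mixed with anonymous gene symbols; the
# packaged candidate list (inst/extdata/bladder_driver_genes.txt) names the
# drivers, so simulated patients have discoverable driver hits.
#' @noRd
SIM_DRIVER_GENES <- c("FGFR3", "TP53", "PIK3CA", "KMT2D", "ATM", "STAG2",
                      "KDM6A", "ARID1A", "RB1", "TSC1", "ERBB2", "ERCC2",
                      "CREBBP", "EP300", "ELF3", "FBXW7", "HRAS")
#' @noRd
sim_gene_pool <- function() c(SIM_DRIVER_GENES, sprintf("GENE%03d", 1:60))

#' Simulate a random reference genome
#'
#' Independent bases at the configured GC fraction. Uses the current RNG
#' stream: call inside [simulate_dataset()] (which seeds once) or after
#' `set.seed()` for reproducibility.
#'
#' @param cfg a `sim_config`.
#' @return named character vector of contig sequences (`chr1`, `chr2`, ...).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
         T = (1 - cfg$gc) / 2)
  seqs <- vapply(seq_len(cfg$genome_contigs), function(i) {
    paste(sample(names(p), cfg$contig_length, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  stats::setNames(seqs, paste0("chr", seq_len(cfg$genome_contigs)))
}

# Strand-collapsed context status of every internal position of the genome.
# Returns data.frame(chrom, pos, base, tpc_site).
#' @noRd
genome_sites <- function(genome) {
  out <- lapply(names(genome), function(chrom) {
    b <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    n <- length(b)
    idx <- 2:(n - 1L)
    bb <- b[idx]
    plus <- bb %in% c("A", "C")
    central <- ifelse(plus, bb, dna_complement(bb))
    five <- ifelse(plus, b[idx - 1L], dna_complement(b[idx + 1L]))
    data.frame(chrom = chrom, pos = idx, base = bb,
               tpc_site = central == "C" & five == "T",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate one multifocal patient's variant truth
#'
#' Plants markers of every sharing class on genome sites matching their
#' assigned dinucleotide context (TpC* markers on strand-collapsed TpC sites,
#' the rest elsewhere), assigns zygosity (germline variants are het with
#' probability 2/3, hom-alt otherwise, identical across samples; somatic
#' variants are het), functional tiers and gene symbols, and — under a
#' clonal model with `contamination > 0` — leaks trunk markers into the
#' normal sample. Field-model patients have no trunk. Uses the current RNG
#' stream (see [simulate_dataset()]).
#'
#' @param cfg a `sim_config`.
#' @param genome output of [simulate_genome()].
#' @return an object of class `sim_patient`: list with `truth` (data.frame:
#'   chrom, pos, ref, alt, class, private_sample, tpc, functional, tier,
#'   gene, known, leaked, zygosity), `mat` (samples x markers observed 0/1
#'   membership, leak applied), `roles`, `cfg`.
#' @export
simulate_patient <- function(cfg, genome) {
  stopifnot(inherits(cfg, "sim_config"))
  nt <- cfg$n_tumours
  tumours <- cfg$samples[-1L]

  cls <- c(rep("ALL_SHARED", cfg$n_germline),
           rep("TUMOUR_SHARED", cfg$n_trunk),
           rep("TUMOUR_PRIVATE", sum(cfg$n_private)),
           rep("OTHER_NORMAL", cfg$n_other_normal),
           rep("OTHER_TUMOUR", cfg$n_other_tumour),
           rep("NORMAL_PRIVATE", cfg$n_normal_private))
  priv <- c(rep(NA_character_, cfg$n_germline + cfg$n_trunk),
            rep(tumours, times = cfg$n_private),
            rep(NA_character_, cfg$n_other_normal + cfg$n_other_tumour +
                  cfg$n_normal_private))
  n <- length(cls)
  frac_key <- c(ALL_SHARED = "germline", TUMOUR_SHARED = "trunk",
                TUMOUR_PRIVATE = "private", OTHER_NORMAL = "other_normal",
                OTHER_TUMOUR = "other_tumour", NORMAL_PRIVATE = "normal_private")
  tpc <- stats::rbinom(n, 1L, cfg$tpc_frac[frac_key[cls]]) == 1L
  func <- stats::rbinom(n, 1L, cfg$functional_frac[frac_key[cls]]) == 1L

  sites <- genome_sites(genome)
  n_tpc <- sum(tpc)
  avail_tpc <- sum(sites$tpc_site)
  if (n_tpc > avail_tpc)
    stop("genome too short: need ", n_tpc, " TpC sites, only ", avail_tpc,
         " available; increase contig_length")
  if (n - n_tpc > sum(!sites$tpc_site))
    stop("genome too short: need ", n - n_tpc, " non-TpC sites")
  resample <- function(x, k) x[sample.int(length(x), k)]
  site_idx <- integer(n)
  site_idx[tpc] <- resample(which(sites$tpc_site), n_tpc)
  site_idx[!tpc] <- resample(which(!sites$tpc_site), n - n_tpc)

  ref <- sites$base[site_idx]
  # draw the substitution on the collapsed strand, then map back
  plus <- ref %in% c("A", "C")
  central <- ifelse(plus, ref, dna_complement(ref))
  coll_alt <- vapply(central, function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1), USE.NAMES = FALSE)
  alt <- ifelse(plus, coll_alt, dna_complement(coll_alt))

  zyg <- ifelse(cls == "ALL_SHARED",
                ifelse(stats::runif(n) < 2 / 3, "het", "hom"), "het")
  tier <- ifelse(func,
                 sample(c("MODERATE", "HIGH", "LOW"), n, replace = TRUE,
                        prob = c(0.70, 0.15, 0.15)),
                 ifelse(stats::runif(n) < 0.6, "MODIFIER", "UNANNOTATED"))
  gene <- sample(sim_gene_pool(), n, replace = TRUE)
  known <- cls == "ALL_SHARED" &
    stats::runif(n) < cfg$known_germline_frac
  leaked <- cls == "TUMOUR_SHARED" & stats::runif(n) < cfg$contamination

  # observed membership matrix (leak applied)
  mat <- matrix(0L, nrow = length(cfg$samples), ncol = n,
                dimnames = list(cfg$samples, NULL))
  mat["N", cls %in% c("ALL_SHARED", "OTHER_NORMAL", "NORMAL_PRIVATE") | leaked] <- 1L
  for (tm in tumours)
    mat[tm, cls %in% c("ALL_SHARED", "TUMOUR_SHARED") |
          (!is.na(priv) & priv == tm)] <- 1L
  for (i in which(cls == "OTHER_NORMAL")) {
    k <- sample.int(nt - 1L, 1L)
    mat[resample(tumours, k), i] <- 1L
  }
  for (i in which(cls == "OTHER_TUMOUR")) {
    ks <- 2:(nt - 1L)
    mat[resample(tumours, ks[sample.int(length(ks), 1L)]), i] <- 1L
  }

  ord <- order(sites$chrom[site_idx], sites$pos[site_idx])
  truth <- data.frame(chrom = sites$chrom[site_idx], pos = sites$pos[site_idx],
                      ref = ref, alt = alt, class = cls,
                      private_sample = priv, tpc = tpc, functional = func,
                      tier = tier, gene = gene, known = known,
                      leaked = leaked, zygosity = zyg,
                      stringsAsFactors = FALSE)[ord, ]
  rownames(truth) <- NULL
  mat <- mat[, ord, drop = FALSE]
  colnames(mat) <- paste0(truth$chrom, ":", truth$pos, "_", truth$ref, ">",
                          truth$alt)
  structure(list(truth = truth, mat = mat, roles = cfg$roles, cfg = cfg),
            class = "sim_patient")
}

#' Truth marker matrix of a simulated patient
#'
#' The simulator's observed membership matrix as a `marker_matrix`, bypassing
#' VCF emission — convenient for tree-level experiments.
#'
#' @param sim a `sim_patient`.
#' @param exclude_known drop markers flagged for the known-sites file
#'   (mirroring the pipeline's exclusion; default TRUE).
#' @return a `marker_matrix`.
#' @export
truth_marker_matrix <- function(sim, exclude_known = TRUE) {
  stopifnot(inherits(sim, "sim_patient"))
  keep <- if (exclude_known) !sim$truth$known else rep(TRUE, nrow(sim$truth))
  info <- sim$truth[keep, c("chrom", "pos", "ref", "alt")]
  info$ann <- NA_character_
  rownames(info) <- NULL
  structure(list(mat = sim$mat[, keep, drop = FALSE], info = info,
                 roles = sim$roles),
            class = "marker_matrix")
}

#' @noRd
sim_ann_string <- function(alt, tier, gene) {
  cons <- switch(tier,
                 HIGH = "stop_gained", MODERATE = "missense_variant",
                 LOW = "splice_region_variant", MODIFIER = "intergenic_region",
                 return(NA_character_))
  sprintf("%s|%s|%s|%s|%s|transcript|%s.t1|protein_coding||", alt, cons, tier,
          gene, gene, gene)
}

#' Emit a simulated patient as multi-sample VCF files
#'
#' Writes `calls.vcf` (GT:AD:DP per sample, snpEff-style ANN INFO entries
#' encoding the planted functional tiers) and `known.vcf` (the germline
#' markers flagged as known sites, a dbSNP stand-in). Depths follow the
#' configured model: DP is Poisson around `mean_depth` floored at 12 and het
#' alt reads are binomial thinned within \[6, DP-6\], so at zero `dropout`
#' every planted genotype clears the >= 4-read filter; with `dropout > 0`
#' random genotype entries are instead given 0-3 reads and are removed by
#' the filter. Uses the current RNG stream (see [simulate_dataset()]).
#'
#' @param sim a `sim_patient`.
#' @param dir output directory (created if needed).
#' @return invisible list with `calls` and `known` paths and `low_depth`, a
#'   logical vector marking markers that received a sub-threshold depth in at
#'   least one sample (and are therefore removed by the default filter).
#' @export
emit_vcf <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_patient"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$cfg
  truth <- sim$truth
  samples <- cfg$samples
  n <- nrow(truth)

  header <- c("##fileformat=VCFv4.2",
              "##source=clonetrace-simulator",
              sprintf("##contig=<ID=chr%d,length=%d>",
                      seq_len(cfg$genome_contigs), cfg$contig_length),
              "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank | HGVS.c'\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))

  body <- character(n)
  low_depth <- logical(n)
  for (i in seq_len(n)) {
    carrier <- sim$mat[, i] == 1L
    gt <- ifelse(carrier,
                 if (truth$zygosity[i] == "hom") "1/1" else "0/1", "0/0")
    fields <- character(length(samples))
    for (k in seq_along(samples)) {
      if (stats::runif(1) < cfg$dropout) {
        low_depth[i] <- TRUE
        dp <- sample(0:3, 1L)
        ad_alt <- if (carrier[k]) as.integer(round(dp / 2)) else 0L
      } else {
        dp <- max(stats::rpois(1L, cfg$mean_depth), 12L)
        ad_alt <- if (!carrier[k]) 0L
        else if (truth$zygosity[i] == "hom" && carrier[k]) dp
        else min(max(stats::rbinom(1L, dp, 0.5), 6L), dp - 6L)
      }
      fields[k] <- sprintf("%s:%d,%d:%d", gt[k], dp - ad_alt, ad_alt, dp)
    }
    ann <- sim_ann_string(truth$alt[i], truth$tier[i], truth$gene[i])
    info <- if (is.na(ann)) "." else paste0("ANN=", ann)
    body[i] <- paste(c(truth$chrom[i], truth$pos[i], ".", truth$ref[i],
                       truth$alt[i], "100", "PASS", info, "GT:AD:DP", fields),
                     collapse = "\t")
  }
  calls <- file.path(dir, "calls.vcf")
  writeLines(c(header, body), calls)

  kn <- which(truth$known)
  known_lines <- vapply(kn, function(i) {
    paste(c(truth$chrom[i], truth$pos[i], sprintf("rs%07d", i), truth$ref[i],
            truth$alt[i], ".", ".", "."), collapse = "\t")
  }, character(1))
  known <- file.path(dir, "known.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=chr%d,length=%d>",
                       seq_len(cfg$genome_contigs), cfg$contig_length),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"),
               known_lines), known)
  invisible(list(calls = calls, known = known, low_depth = low_depth))
}

#' Simulate a complete dataset for one patient
#'
#' Seeds the RNG once from `cfg$seed` and runs genome simulation, patient
#' simulation and (optionally) VCF emission in a single stream, so the whole
#' dataset is byte-reproducible. With `dir` set, writes `genome.fa`,
#' `calls.vcf`, `known.vcf`, `truth.tsv` and `config.json`.
#'
#' @param cfg a `sim_config`.
#' @param dir output directory, or NULL for in-memory only (no VCF files).
#' @return list with `cfg`, `genome` (named character vector), `sim` (the
#'   `sim_patient`) and, when `dir` is set, `paths`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genome <- simulate_genome(cfg)
    sim <- simulate_patient(cfg, genome)
    paths <- NULL
    low_depth <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      vcfs <- emit_vcf(sim, dir)
      low_depth <- vcfs$low_depth
      fa <- file.path(dir, "genome.fa")
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fa)
      truth_path <- file.path(dir, "truth.tsv")
      utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      cfg_path <- file.path(dir, "config.json")
      jsonlite::write_json(cfg[setdiff(names(cfg), "roles")], cfg_path,
                           auto_unbox = TRUE, digits = NA)
      paths <- list(genome = fa, calls = vcfs$calls, known = vcfs$known,
                    truth = truth_path, config = cfg_path)
    }
    list(cfg = cfg, genome = genome, sim = sim, paths = paths,
         low_depth = low_depth)
  })
}
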