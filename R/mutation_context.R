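#' Dinucleotide context classes
#'
#' After strand collapsing, every valid SNV has a central reference base of A
#' or C and one of eight 5'-dinucleotide classes: ApA*, CpA*, GpA*, TpA*,
#' ApC*, CpC*, GpC*, TpC* (the asterisk marks the mutated base). TpC* is the
#' hallmark context of APOBEC cytidine-deaminase mutagenesis.
#'
#' @keywords internal
#' @noRd
DINUC_CLASSES <- paste0(rep(c("A", "C", "G", "T"), times = 2), "p",
                        rep(c("A", "C"), each = 4), "*")

#' Strand-collapsed dinucleotide context of one SNV
#'
#' Mutations are recorded at A and C reference positions only, together with
#' the preceding (5') nucleotide on whichever strand carries the A/C. SNVs
#' with a reference G or T are read off the minus strand: the central base
#' and the alternate allele are complemented, and the 5' neighbour of the
#' minus strand is the complement of the plus-strand base *following* the
#' site. Positions at a contig edge, or whose neighbour is N, are classified
#' `UNKNOWN`.
#'
#' @param chrom contig name.
#' @param pos 1-based position.
#' @param ref,alt single-base reference and alternate alleles. `ref` must
#'   match the genome at `pos` (a mismatch signals a coordinate bug and is
#'   fatal).
#' @param genome reference sequences: a named character vector of contig
#'   strings or a `Biostrings::DNAStringSet`.
#' @return list with `valid`, `five` (5' neighbour), `central` (A or C),
#'   `alt` (collapsed), `class` (e.g. `"TpC*"` or `"UNKNOWN"`), `tpc`
#'   (logical) and `substitution` (e.g. `"TpC*>TpT*"`).
#' @export
dinucleotide_context <- function(chrom, pos, ref, alt, genome) {
  ctx <- snv_context(chrom, pos, ref, alt, genome, three_prime = FALSE)
  ctx[c("valid", "five", "central", "alt", "class", "tpc", "substitution")]
}

#' Strand-collapsed trinucleotide context of one SNV
#'
#' As [dinucleotide_context()] but also records the 3' neighbour (on the
#' collapsed strand the minus-strand 3' neighbour is the complement of the
#' plus-strand base preceding the site).
#'
#' @inheritParams dinucleotide_context
#' @return as [dinucleotide_context()] plus `three` and `trinuc_class`
#'   (e.g. `"TpC*pA"`).
#' @export
trinucleotide_context <- function(chrom, pos, ref, alt, genome) {
  snv_context(chrom, pos, ref, alt, genome, three_prime = TRUE)
}

#' @noRd
genome_base <- function(genome, chrom, pos) {
  if (inherits(genome, "DNAStringSet")) {
    seqlen <- Biostrings::width(genome)[match(chrom, names(genome))]
    if (is.na(seqlen)) stop("contig not in genome: ", chrom)
    if (pos < 1L || pos > seqlen) return(NA_character_)
    return(as.character(Biostrings::subseq(genome[[chrom]], pos, pos)))
  }
  s <- genome[[chrom]]
  if (is.null(s)) stop("contig not in genome: ", chrom)
  if (pos < 1L || pos > nchar(s)) return(NA_character_)
  substr(s, pos, pos)
}

#' @noRd
snv_context <- function(chrom, pos, ref, alt, genome, three_prime = FALSE) {
  unknown <- list(valid = FALSE, five = NA_character_, central = NA_character_,
                  alt = NA_character_, three = NA_character_,
                  class = "UNKNOWN", trinuc_class = "UNKNOWN",
                  tpc = NA, substitution = NA_character_)
  if (!ref %in% DNA_BASES || !alt %in% DNA_BASES || ref == alt)
    return(unknown)
  gbase <- genome_base(genome, chrom, pos)
  if (is.na(gbase)) stop("position ", pos, " outside contig ", chrom)
  if (gbase != ref)
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (VCF says ", ref, ", genome says ", gbase, ")")
  if (ref %in% c("A", "C")) {
    five <- genome_base(genome, chrom, pos - 1L)
    three <- genome_base(genome, chrom, pos + 1L)
    central <- ref; calt <- alt
  } else {
    five <- dna_complement(genome_base(genome, chrom, pos + 1L))
    three <- dna_complement(genome_base(genome, chrom, pos - 1L))
    central <- dna_complement(ref); calt <- dna_complement(alt)
  }
  if (is.na(five) || !five %in% DNA_BASES) return(unknown)
  if (three_prime && (is.na(three) || !three %in% DNA_BASES)) return(unknown)
  cls <- paste0(five, "p", central, "*")
  list(valid = TRUE, five = five, central = central, alt = calt,
       three = if (three_prime) three else NA_character_,
       class = cls,
       trinuc_class = if (three_prime) paste0(cls, "p", three) else NA_character_,
       tpc = cls == "TpC*",
       substitution = paste0(cls, ">", five, "p", calt, "*"))
}

#' Classify the contexts of every marker in a matrix
#'
#' @param info per-marker metadata data.frame with chrom, pos, ref, alt (for
#'   example the `info` element of a `marker_matrix`).
#' @param genome reference sequences (named character vector or
#'   `DNAStringSet`).
#' @param trinucleotide also record the 3' neighbour (default TRUE).
#' @return data.frame with one row per marker: `valid`, `five`, `central`,
#'   `alt_collapsed`, `three`, `class`, `trinuc_class`, `tpc`,
#'   `substitution`. Non-SNV markers (multi-base alleles) are `UNKNOWN`.
#' @export
classify_contexts <- function(info, genome, trinucleotide = TRUE) {
  if (inherits(genome, "DNAStringSet"))
    genome <- vapply(seq_along(genome),
                     function(i) as.character(genome[[i]]), character(1),
                     USE.NAMES = FALSE) |> stats::setNames(names(genome))
  n <- nrow(info)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ctx <- snv_context(info$chrom[i], info$pos[i], info$ref[i], info$alt[i],
                       genome, three_prime = trinucleotide)
    out[[i]] <- data.frame(valid = ctx$valid, five = ctx$five,
                           central = ctx$central, alt_collapsed = ctx$alt,
                           three = ctx$three, class = ctx$class,
                           trinuc_class = ctx$trinuc_class, tpc = ctx$tpc,
                           substitution = ctx$substitution,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(valid = logical(), five = character(),
                      central = character(), alt_collapsed = character(),
                      three = character(), class = character(),
                      trinuc_class = character(), tpc = logical(),
                      substitution = character())
  rownames(res) <- NULL
  res
}

#' Context frequency tables per marker group
#'
#' Tallies dinucleotide classes (and substitutions) within groups of markers,
#' typically sharing classes: germline (`ALL_SHARED`) vs trunk
#' (`TUMOUR_SHARED`) vs pooled private. Frequencies are over valid contexts
#' only; `UNKNOWN` contexts are excluded from the denominators and reported
#' separately.
#'
#' @param contexts data.frame from [classify_contexts()].
#' @param groups factor/character vector, one group label per marker (NA
#'   markers are ignored).
#' @return list with `class_freq` (groups x 8 classes frequency matrix,
#'   rows sum to 1 where defined), `class_counts`, `substitution_counts`
#'   (named counts per group), `tpc` (per group: n valid, count, fraction),
#'   `n_unknown` per group.
#' @export
tally_contexts <- function(contexts, groups) {
  stopifnot(nrow(contexts) == length(groups))
  keep <- !is.na(groups)
  contexts <- contexts[keep, , drop = FALSE]
  groups <- as.character(groups[keep])
  glev <- unique(groups)
  counts <- matrix(0L, nrow = length(glev), ncol = length(DINUC_CLASSES),
                   dimnames = list(glev, DINUC_CLASSES))
  n_unknown <- stats::setNames(integer(length(glev)), glev)
  subs <- stats::setNames(vector("list", length(glev)), glev)
  tpc <- data.frame(group = glev, n_valid = 0L, n_tpc = 0L,
                    fraction = NA_real_, stringsAsFactors = FALSE)
  for (g in glev) {
    sel <- groups == g
    cls <- contexts$class[sel]
    valid <- contexts$valid[sel]
    n_unknown[g] <- sum(!valid)
    tab <- table(factor(cls[valid], levels = DINUC_CLASSES))
    counts[g, ] <- as.integer(tab)
    subs[[g]] <- table(contexts$substitution[sel][valid])
    i <- which(tpc$group == g)
    tpc$n_valid[i] <- sum(valid)
    tpc$n_tpc[i] <- sum(contexts$tpc[sel][valid])
    tpc$fraction[i] <- if (sum(valid) > 0) tpc$n_tpc[i] / tpc$n_valid[i] else NA_real_
  }
  freq <- counts / pmax(rowSums(counts), 1L)
  freq[rowSums(counts) == 0L, ] <- NA_real_
  list(class_freq = freq, class_counts = counts,
       substitution_counts = subs, tpc = tpc, n_unknown = n_unknown)
}
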