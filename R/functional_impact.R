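IMPACT_TIERS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Functional impact call from a snpEff-style ANN annotation
#'
#' Parses the comma-separated transcript annotations of an ANN string
#' (`Allele|Annotation|Impact|Gene_Name|...`), takes the highest-severity
#' impact tier across transcripts (HIGH > MODERATE > LOW > MODIFIER) and
#' flags the variant "functional" when that tier is HIGH, MODERATE or LOW —
#' i.e. any predicted effect on protein sequence or splicing. Absent or
#' malformed annotations yield tier `UNANNOTATED`, which is non-functional
#' and counted separately.
#'
#' @param ann ANN string (or NA).
#' @return list with `tier`, `functional` (logical), `genes` (character
#'   vector of gene symbols at the top tier; empty when none).
#' @export
classify_functional <- function(ann) {
  if (is.na(ann) || !nzchar(ann))
    return(list(tier = "UNANNOTATED", functional = FALSE, genes = character(0)))
  entries <- strsplit(ann, ",", fixed = TRUE)[[1]]
  tiers <- character(0); genes <- character(0)
  for (e in entries) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(f) < 3L || !f[3] %in% IMPACT_TIERS) next
    tiers <- c(tiers, f[3])
    genes <- c(genes, if (length(f) >= 4L) f[4] else NA_character_)
  }
  if (!length(tiers)) {
    warning("malformed ANN annotation: ", substr(ann, 1, 60))
    return(list(tier = "UNANNOTATED", functional = FALSE, genes = character(0)))
  }
  best <- IMPACT_TIERS[min(match(tiers, IMPACT_TIERS))]
  g <- unique(genes[tiers == best])
  g <- g[!is.na(g) & nzchar(g)]
  list(tier = best, functional = best %in% c("HIGH", "MODERATE", "LOW"),
       genes = g)
}

#' Impact calls for every marker of a matrix
#'
#' @param mmat a `marker_matrix` whose `info` carries an `ann` column.
#' @return data.frame with one row per marker: `tier`, `functional`, `genes`
#'   (comma-joined symbols).
#' @export
classify_impacts <- function(mmat) {
  stopifnot(inherits(mmat, "marker_matrix"))
  ann <- mmat$info$ann
  calls <- lapply(ann, classify_functional)
  data.frame(marker = colnames(mmat$mat),
             tier = vapply(calls, `[[`, character(1), "tier"),
             functional = vapply(calls, `[[`, logical(1), "functional"),
             genes = vapply(calls, function(x) paste(x$genes, collapse = ","),
                            character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap of functional tumour variants with a candidate driver gene list
#'
#' Reports every functional SNV that lies in a listed gene and is carried by
#' at least one tumour sample, one row per (gene, marker) pair (a variant
#' annotated to several listed genes yields one row each). The fraction of
#' listed-gene missense/functional variants that are TpC* is also returned,
#' since roughly half the driver-gene missense mutations in APOBEC-driven
#' bladder tumours sit in that context.
#'
#' @param mmat a `marker_matrix`.
#' @param gene_list character vector of gene symbols, or path to a plain-text
#'   file with one symbol per line.
#' @param partition result of [partition_markers()].
#' @param impacts result of [classify_impacts()].
#' @param contexts optional result of [classify_contexts()] for the TpC*
#'   flag.
#' @return list with `hits` (data.frame: gene, marker, class, tier, tpc) and
#'   `tpc_fraction` (fraction of hit markers in TpC* context; NA without
#'   contexts or hits).
#' @export
driver_overlap <- function(mmat, gene_list, partition, impacts,
                           contexts = NULL) {
  stopifnot(inherits(mmat, "marker_matrix"))
  if (is.character(gene_list) && length(gene_list) == 1L && file.exists(gene_list))
    gene_list <- readLines(gene_list)
  gene_list <- unique(trimws(gene_list))
  gene_list <- gene_list[nzchar(gene_list)]
  tumours <- names(mmat$roles)[mmat$roles == "tumour"]
  in_tumour <- colSums(mmat$mat[tumours, , drop = FALSE]) > 0L
  rows <- list()
  for (i in seq_len(ncol(mmat$mat))) {
    if (!impacts$functional[i] || !in_tumour[i]) next
    genes <- strsplit(impacts$genes[i], ",", fixed = TRUE)[[1]]
    hit <- intersect(genes, gene_list)
    for (g in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, marker = colnames(mmat$mat)[i],
        class = partition$class[i], tier = impacts$tier[i],
        tpc = if (is.null(contexts)) NA else isTRUE(contexts$tpc[i]),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), marker = character(), class = character(),
               tier = character(), tpc = logical())
  tpc_fraction <- NA_real_
  if (!is.null(contexts) && nrow(hits) > 0) {
    u <- !duplicated(hits$marker)
    tpc_fraction <- mean(hits$tpc[u], na.rm = TRUE)
  }
  list(hits = hits, tpc_fraction = tpc_fraction)
}
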