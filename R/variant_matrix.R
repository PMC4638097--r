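#' Read a multi-sample VCF into a variant set
#'
#' Parses a multi-sample VCF (one normal mucosa sample plus two or more tumour
#' samples from the same patient) into a `variant_set`: per-variant metadata,
#' a per-sample genotype carrier matrix and a per-sample supporting-read
#' matrix. Multi-allelic rows are split into one record per alternate allele,
#' so every marker is biallelic; a sample is a carrier of a marker iff its
#' genotype contains that specific alternate allele.
#'
#' Supporting reads are the reads backing the *called* allele: the AD entry of
#' the alternate allele for carriers, the reference AD entry for
#' homozygous-reference samples, with DP as fallback when AD is absent.
#'
#' @param path path to a VCF v4.x file (may be multi-allelic; GT required,
#'   AD or DP used for depth).
#' @param sample_roles named character vector mapping sample label to
#'   `"normal"` or `"tumour"`. Every named sample must be present in the VCF;
#'   exactly one normal and at least two tumours are required.
#' @return an object of class `variant_set`: a list with elements
#'   `variants` (data.frame: chrom, pos, ref, alt, filter_pass, ann),
#'   `gt` (variants x samples integer matrix, 1 = carries the alt,
#'   0 = homozygous reference, NA = missing genotype),
#'   `support` (variants x samples supporting-read counts) and `roles`.
#'   Attribute `n_skipped` counts malformed rows that were skipped.
#' @export
read_multisample_vcf <- function(path, sample_roles) {
  check_roles(sample_roles)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- names(sample_roles)
  have <- colnames(vcf@gt)[-1L]
  missing_samples <- setdiff(samples, have)
  if (length(missing_samples))
    stop("sample(s) declared in `sample_roles` but absent from VCF: ",
         paste(missing_samples, collapse = ", "))

  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_str <- vcfR::extract.gt(vcf, element = "GT")
  ad_str <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                     error = function(e) NULL)
  dp_str <- tryCatch(vcfR::extract.gt(vcf, element = "DP"),
                     error = function(e) NULL)
  ann <- extract_ann_info(vcf)

  n <- nrow(fix)
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  ref <- fix[, "REF"]
  alt_field <- fix[, "ALT"]
  malformed <- is.na(pos) | pos < 1L | is.na(ref) | !nzchar(ref) |
    is.na(alt_field) | !nzchar(alt_field) | alt_field == "."
  n_skipped <- sum(malformed)
  if (n_skipped > 0)
    warning(n_skipped, " malformed VCF row(s) skipped")

  rows <- list(); gts <- list(); sups <- list()
  for (i in seq_len(n)) {
    if (malformed[i]) next
    alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
    gvec <- gt_str[i, samples]
    alleles <- lapply(gvec, parse_gt_alleles)
    ad <- if (!is.null(ad_str)) ad_str[i, samples] else rep(NA_character_, length(samples))
    dp <- if (!is.null(dp_str)) dp_str[i, samples] else rep(NA_character_, length(samples))
    for (a in seq_along(alts)) {
      g <- integer(length(samples)); s <- integer(length(samples))
      for (k in seq_along(samples)) {
        al <- alleles[[k]]
        if (is.null(al)) { g[k] <- NA_integer_; s[k] <- NA_integer_; next }
        carrier <- any(al == a)
        g[k] <- as.integer(carrier)
        s[k] <- support_reads(ad[k], dp[k], if (carrier) a + 1L else 1L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = pos[i], ref = ref[i], alt = alts[a],
        filter_pass = fix[i, "FILTER"] %in% c("PASS", "."),
        ann = if (is.na(ann[i])) NA_character_ else ann[i],
        stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- g
      sups[[length(sups) + 1L]] <- s
    }
  }

  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), filter_pass = logical(), ann = character())
  gt <- matrix(unlist(gts), ncol = length(samples), byrow = TRUE,
               dimnames = list(NULL, samples))
  support <- matrix(unlist(sups), ncol = length(samples), byrow = TRUE,
                    dimnames = list(NULL, samples))
  if (!length(rows)) {
    gt <- matrix(integer(), ncol = length(samples), dimnames = list(NULL, samples))
    support <- gt
  }
  structure(list(variants = variants, gt = gt, support = support,
                 roles = sample_roles),
            class = "variant_set", n_skipped = n_skipped)
}

# Allele indices of a GT string ("0/1", "1|1", "./."); NULL when any allele
# is missing; indices are 0 = ref, 1 = first alt, ...
#' @noRd
parse_gt_alleles <- function(g) {
  if (is.na(g) || g == "." || !nzchar(g)) return(NULL)
  al <- strsplit(g, "[/|]")[[1]]
  if (any(al == "." | !nzchar(al))) return(NULL)
  as.integer(al)
}

# Supporting reads for a called allele: AD entry `idx` (1 = ref, 2 = first
# alt, ...) when parseable, else DP, else 0.
#' @noRd
support_reads <- function(ad, dp, idx) {
  if (!is.na(ad) && nzchar(ad)) {
    parts <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
    if (length(parts) >= idx && !is.na(parts[idx])) return(parts[idx])
  }
  d <- suppressWarnings(as.integer(dp))
  if (!is.na(d)) return(d)
  0L
}

# ANN= value from the INFO column, NA where absent.
#' @noRd
extract_ann_info <- function(vcf) {
  info <- vcf@fix[, "INFO"]
  vapply(info, function(s) {
    if (is.na(s)) return(NA_character_)
    m <- regmatches(s, regexpr("(?:^|;)ANN=[^;]*", s))
    if (!length(m)) return(NA_character_)
    sub("^;?ANN=", "", m)
  }, character(1), USE.NAMES = FALSE)
}

#' High-confidence filter on a variant set
#'
#' Retains records whose site filter status is pass, whose genotype is called
#' in every sample, and whose called allele is supported by at least
#' `min_reads` reads in *every* sample. Record order is preserved and the
#' operation is idempotent. Attrition counts (by first failing reason, in the
#' order site-filter, missing genotype, low support) are attached as the
#' `attrition` attribute.
#'
#' @param vs a `variant_set`.
#' @param min_reads minimum supporting reads required in every sample
#'   (default 4).
#' @return the filtered `variant_set`.
#' @export
filter_high_confidence <- function(vs, min_reads = 4L) {
  stopifnot(inherits(vs, "variant_set"))
  n <- nrow(vs$variants)
  if (n == 0L) {
    attr(vs, "attrition") <- c(site_filter = 0L, missing_genotype = 0L,
                               low_support = 0L, retained = 0L)
    return(vs)
  }
  fail_filter <- !vs$variants$filter_pass
  miss <- apply(is.na(vs$gt), 1L, any)
  sup <- vs$support
  sup[is.na(sup)] <- 0L
  low <- apply(sup < min_reads, 1L, any)
  reason <- ifelse(fail_filter, "site_filter",
                   ifelse(miss, "missing_genotype",
                          ifelse(low, "low_support", "retained")))
  keep <- reason == "retained"
  out <- subset_variant_set(vs, keep)
  attr(out, "attrition") <- c(site_filter = sum(reason == "site_filter"),
                              missing_genotype = sum(reason == "missing_genotype"),
                              low_support = sum(reason == "low_support"),
                              retained = sum(keep))
  out
}

#' @noRd
subset_variant_set <- function(vs, keep) {
  structure(list(variants = vs$variants[keep, , drop = FALSE],
                 gt = vs$gt[keep, , drop = FALSE],
                 support = vs$support[keep, , drop = FALSE],
                 roles = vs$roles),
            class = "variant_set")
}

#' Exclude known (population) sites from a variant set
#'
#' Removes every record matching a site in a known-sites VCF (a dbSNP
#' stand-in) on the triple (chrom, pos, alt). Matching on the specific
#' alternate allele rather than position alone avoids discarding somatic
#' alleles that happen to coincide with common SNP positions.
#'
#' @param vs a `variant_set`.
#' @param known path to a VCF of sites to exclude.
#' @return the filtered `variant_set`, with attribute `n_known_removed`.
#' @export
exclude_known_sites <- function(vs, known) {
  stopifnot(inherits(vs, "variant_set"))
  kv <- vcfR::read.vcfR(known, verbose = FALSE)
  keys <- character(0)
  if (nrow(kv@fix) > 0) {
    fix <- vcfR::getFIX(kv)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    keys <- unlist(lapply(seq_len(nrow(fix)), function(i) {
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      paste(fix[i, "CHROM"], fix[i, "POS"], alts, sep = ":")
    }))
  }
  rec_keys <- paste(vs$variants$chrom, vs$variants$pos, vs$variants$alt, sep = ":")
  keep <- !(rec_keys %in% keys)
  out <- subset_variant_set(vs, keep)
  attr(out, "n_known_removed") <- sum(!keep)
  out
}

#' Binarize a filtered variant set into a marker matrix
#'
#' Encodes each (sample, marker) entry as 1 when the sample's genotype carries
#' at least one copy of the marker's alternate allele (heterozygous or
#' homozygous non-reference) and 0 for homozygous reference. Columns that are
#' 0 in every sample carry no signal and are dropped. Missing genotypes must
#' have been filtered out beforehand.
#'
#' @param vs a filtered `variant_set` (no missing genotypes).
#' @return an object of class `marker_matrix`: list with `mat` (samples x
#'   markers 0/1 integer matrix), `info` (per-marker metadata data.frame) and
#'   `roles`.
#' @export
binarize <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  if (any(is.na(vs$gt)))
    stop("missing genotypes present: run filter_high_confidence() first")
  mat <- t(vs$gt)            # samples x markers
  info <- vs$variants
  keep <- colSums(mat) > 0L
  mat <- mat[, keep, drop = FALSE]
  info <- info[keep, , drop = FALSE]
  rownames(info) <- NULL
  colnames(mat) <- marker_ids(info)
  structure(list(mat = mat, info = info, roles = vs$roles),
            class = "marker_matrix")
}

#' @noRd
marker_ids <- function(info) {
  if (nrow(info) == 0) return(character(0))
  paste0(info$chrom, ":", info$pos, "_", info$ref, ">", info$alt)
}

#' Append the all-zero reference pseudo-sample
#'
#' Adds a row labelled `"reference"` with 0 at every marker, representing the
#' reference genome; this pseudo-sample later serves as the outgroup that
#' roots the tree.
#'
#' @param mmat a `marker_matrix` without a reference row.
#' @return the `marker_matrix` with the reference row appended and its role
#'   set to `"reference"`.
#' @export
add_reference_row <- function(mmat) {
  stopifnot(inherits(mmat, "marker_matrix"))
  if ("reference" %in% rownames(mmat$mat))
    stop("matrix already contains a 'reference' row")
  mmat$mat <- rbind(mmat$mat,
                    reference = rep(0L, ncol(mmat$mat)))
  mmat$roles <- c(mmat$roles, reference = "reference")
  mmat
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix: ", nrow(x$mat), " samples x ", ncol(x$mat),
      " binary markers\n", sep = "")
  cat("samples:", paste0(rownames(x$mat), " (", x$roles[rownames(x$mat)], ")",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a marker matrix as TSV
#'
#' The TSV has columns chrom, pos, ref, alt, then one 0/1 column per sample.
#' Roles are not stored in the TSV and must be supplied when reading.
#'
#' @param mmat a `marker_matrix`.
#' @param path output path.
#' @return `write_marker_matrix()` returns `path` invisibly;
#'   `read_marker_matrix()` returns a `marker_matrix`.
#' @export
write_marker_matrix <- function(mmat, path) {
  df <- cbind(mmat$info[, c("chrom", "pos", "ref", "alt")],
              as.data.frame(t(mmat$mat)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_matrix
#' @param roles named role vector for the sample columns of the TSV.
#' @export
read_marker_matrix <- function(path, roles) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("chrom", "pos", "ref", "alt")
  samples <- setdiff(colnames(df), meta)
  if (!all(names(roles) %in% samples))
    stop("roles name samples absent from the TSV: ",
         paste(setdiff(names(roles), samples), collapse = ", "))
  mat <- t(as.matrix(df[, samples, drop = FALSE]))
  storage.mode(mat) <- "integer"
  info <- df[, meta, drop = FALSE]
  info$ann <- NA_character_
  colnames(mat) <- marker_ids(info)
  structure(list(mat = mat, info = info, roles = roles),
            class = "marker_matrix")
}
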