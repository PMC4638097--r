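#' Sharing classes for multifocal tumour markers
#'
#' Every post-filter marker falls into exactly one sharing class, determined
#' by which samples carry it (normal bit `n`, tumour bits `T`):
#'
#' * `ALL_SHARED` — in the normal and every tumour (the individual's
#'   germline genotype);
#' * `TUMOUR_SHARED` — in every tumour but not the normal (the clonal
#'   "trunk");
#' * `TUMOUR_PRIVATE` — in exactly one tumour and not the normal;
#' * `NORMAL_PRIVATE` — only in the normal;
#' * `OTHER_NORMAL` — in the normal and some but not all tumours;
#' * `OTHER_TUMOUR` — in two or more but not all tumours, not in the normal.
#'
#' "Tumour-associated" means present in at least one tumour and absent from
#' the normal: `TUMOUR_SHARED`, `TUMOUR_PRIVATE` or `OTHER_TUMOUR`.
#'
#' @name sharing-classes
#' @keywords internal
NULL

SHARING_CLASSES <- c("ALL_SHARED", "TUMOUR_SHARED", "TUMOUR_PRIVATE",
                     "NORMAL_PRIVATE", "OTHER_NORMAL", "OTHER_TUMOUR")
TUMOUR_ASSOCIATED <- c("TUMOUR_SHARED", "TUMOUR_PRIVATE", "OTHER_TUMOUR")

#' Classify one marker column into a sharing class
#'
#' @param column named 0/1 vector over the real samples (no reference row);
#'   must not be all zero.
#' @param roles named role vector (`"normal"`/`"tumour"`) covering the
#'   column's samples.
#' @return the class label (character scalar). For `TUMOUR_PRIVATE` the
#'   carrying sample's label is attached as attribute `"sample"`.
#' @export
classify_marker <- function(column, roles) {
  check_roles(roles)
  normal <- names(roles)[roles == "normal"]
  tumours <- names(roles)[roles == "tumour"]
  if (!all(c(normal, tumours) %in% names(column)))
    stop("column lacks entries for some samples named in `roles`")
  n <- column[[normal]]
  tv <- unlist(column[tumours])
  if (n == 0L && all(tv == 0L))
    stop("all-zero marker column: violates the marker-matrix invariant")
  k <- sum(tv)
  if (n == 1L) {
    if (k == length(tv)) return("ALL_SHARED")
    if (k == 0L) return("NORMAL_PRIVATE")
    return("OTHER_NORMAL")
  }
  if (k == length(tv)) return("TUMOUR_SHARED")
  if (k == 1L)
    return(structure("TUMOUR_PRIVATE", sample = tumours[tv == 1L]))
  "OTHER_TUMOUR"
}

#' Classify every marker of a matrix
#'
#' @param mmat a `marker_matrix` (reference row, if present, is ignored).
#' @return data.frame with one row per marker: `marker`, `class`,
#'   `private_sample` (NA except for `TUMOUR_PRIVATE`).
#' @export
partition_markers <- function(mmat) {
  stopifnot(inherits(mmat, "marker_matrix"))
  roles <- mmat$roles[mmat$roles != "reference"]
  check_roles(roles)
  normal <- names(roles)[roles == "normal"]
  tumours <- names(roles)[roles == "tumour"]
  mat <- mmat$mat[c(normal, tumours), , drop = FALSE]
  if (any(colSums(mat) == 0L))
    stop("all-zero marker column: violates the marker-matrix invariant")
  n <- mat[normal, ]
  k <- colSums(mat[tumours, , drop = FALSE])
  nt <- length(tumours)
  cls <- ifelse(n == 1L,
                ifelse(k == nt, "ALL_SHARED",
                       ifelse(k == 0L, "NORMAL_PRIVATE", "OTHER_NORMAL")),
                ifelse(k == nt, "TUMOUR_SHARED",
                       ifelse(k == 1L, "TUMOUR_PRIVATE", "OTHER_TUMOUR")))
  priv <- rep(NA_character_, ncol(mat))
  is_priv <- cls == "TUMOUR_PRIVATE"
  if (any(is_priv)) {
    tm <- mat[tumours, is_priv, drop = FALSE]
    priv[is_priv] <- tumours[apply(tm == 1L, 2L, which)]
  }
  data.frame(marker = colnames(mat), class = cls, private_sample = priv,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tabulate sharing-class counts and fractions
#'
#' @param mmat a `marker_matrix`.
#' @return list with `counts` (named integer over all six classes),
#'   `per_tumour_private` (private counts by tumour sample), `fractions`
#'   (over all markers), `tumour_associated` (total count),
#'   `tumour_associated_fraction` (over all markers) and
#'   `tumour_shared_fraction_of_associated` (trunk share among
#'   tumour-associated markers).
#' @export
partition_counts <- function(mmat) {
  part <- partition_markers(mmat)
  counts <- vapply(SHARING_CLASSES, function(cl) sum(part$class == cl),
                   integer(1))
  total <- nrow(part)
  ta <- sum(counts[TUMOUR_ASSOCIATED])
  roles <- mmat$roles[mmat$roles == "tumour"]
  per_priv <- vapply(names(roles),
                     function(s) sum(part$private_sample == s, na.rm = TRUE),
                     integer(1))
  list(counts = counts,
       per_tumour_private = per_priv,
       total = total,
       fractions = if (total > 0) counts / total else counts * NA_real_,
       tumour_associated = ta,
       tumour_associated_fraction = if (total > 0) ta / total else NA_real_,
       tumour_shared_fraction_of_associated =
         if (ta > 0) unname(counts["TUMOUR_SHARED"] / ta) else NA_real_)
}
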