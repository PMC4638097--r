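#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditioning on both margins, the count in cell (1,1) is hypergeometric;
#' the two-sided p-value is the total probability of all tables with the same
#' margins whose point probability does not exceed that of the observed table
#' (the minimum-likelihood rule used by `fisher.test`), with a relative
#' slack of 1e-7 on the comparison to absorb floating-point ties.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `p` (in (0, 1\]) and `degenerate` (TRUE when a margin is
#'   zero, in which case `p` is 1).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab)))
    stop("`tab` must be a 2x2 matrix of non-negative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(p = 1, degenerate = TRUE))
  x <- tab[1, 1]
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(x, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p = min(p, 1), degenerate = FALSE)
}

#' Fold ratio of two proportions
#'
#' `(k1/n1) / (k2/n2)`. A zero numerator proportion gives fold 0; a zero
#' denominator proportion gives `Inf` (no pseudocounts are applied).
#'
#' @param k1,n1 successes and size of the first group.
#' @param k2,n2 successes and size of the second group.
#' @return the fold (possibly `Inf`).
#' @export
proportion_fold <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  p1 <- k1 / n1; p2 <- k2 / n2
  if (p2 == 0) return(Inf)
  p1 / p2
}

#' @noRd
enrichment_result <- function(tab, groups, outcome) {
  f <- fisher_exact_2x2(tab)
  fold <- if (sum(tab[1, ]) > 0 && sum(tab[2, ]) > 0)
    proportion_fold(tab[1, 1], sum(tab[1, ]), tab[2, 1], sum(tab[2, ]))
  else NA_real_
  structure(list(table = tab, groups = groups, outcome = outcome,
                 p = f$p, fold = fold, degenerate = f$degenerate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("2x2 enrichment: ", x$groups[1], " vs ", x$groups[2],
      " / outcome ", x$outcome, "\n", sep = "")
  print(x$table)
  cat(sprintf("fold = %.3g, two-sided Fisher p = %.3g%s\n", x$fold, x$p,
              if (x$degenerate) " [degenerate margin]" else ""))
  invisible(x)
}

#' Functional enrichment: trunk vs germline
#'
#' Compares the proportion of functional variants among trunk markers
#' (`TUMOUR_SHARED`) against germline markers (`ALL_SHARED`) with an exact
#' 2x2 test; in clonal multifocal tumours functional variants are roughly
#' twice as common on the trunk as in the germline background.
#'
#' @param partition result of [partition_markers()].
#' @param impacts result of [classify_impacts()] (same marker order).
#' @return an `enrichment_result` (table rows: trunk, germline; columns:
#'   functional, non-functional).
#' @export
compare_functional <- function(partition, impacts) {
  stopifnot(nrow(partition) == nrow(impacts))
  sel1 <- partition$class == "TUMOUR_SHARED"
  sel2 <- partition$class == "ALL_SHARED"
  tab <- rbind(TUMOUR_SHARED = c(sum(impacts$functional[sel1]),
                                 sum(!impacts$functional[sel1])),
               ALL_SHARED = c(sum(impacts$functional[sel2]),
                              sum(!impacts$functional[sel2])))
  colnames(tab) <- c("functional", "non_functional")
  enrichment_result(tab, c("TUMOUR_SHARED", "ALL_SHARED"), "functional")
}

#' TpC* context enrichment between two sharing-class groups
#'
#' Compares the proportion of TpC*-context variants between two disjoint
#' marker sets with an exact 2x2 test. Two presets cover the questions of
#' interest: `"trunk_vs_germline"` (APOBEC elevation among tumour-shared
#' variants relative to the individual's genotype) and `"trunk_vs_private"`
#' (the timing contrast: ancestral trunk branch vs recent private branches,
#' private markers pooled across tumours). Markers with `UNKNOWN` context are
#' excluded.
#'
#' @param partition result of [partition_markers()].
#' @param contexts result of [classify_contexts()] (same marker order).
#' @param sets preset name, or a list of two character vectors of sharing
#'   classes, named for the two groups.
#' @return an `enrichment_result` (columns: TpC*, non-TpC*).
#' @export
compare_tpc <- function(partition, contexts,
                        sets = c("trunk_vs_germline", "trunk_vs_private")) {
  stopifnot(nrow(partition) == nrow(contexts))
  if (is.character(sets)) {
    sets <- match.arg(sets)
    sets <- switch(sets,
      trunk_vs_germline = list(trunk = "TUMOUR_SHARED",
                               germline = "ALL_SHARED"),
      trunk_vs_private = list(trunk = "TUMOUR_SHARED",
                              private = "TUMOUR_PRIVATE"))
  }
  if (length(sets) != 2L || length(intersect(sets[[1]], sets[[2]])))
    stop("`sets` must be two disjoint groups of sharing classes")
  cell <- function(classes) {
    sel <- partition$class %in% classes & contexts$valid
    c(sum(contexts$tpc[sel]), sum(!contexts$tpc[sel]))
  }
  tab <- rbind(cell(sets[[1]]), cell(sets[[2]]))
  dimnames(tab) <- list(names(sets), c("TpC", "non_TpC"))
  enrichment_result(tab, names(sets), "TpC*")
}
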