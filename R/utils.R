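#' @keywords internal
#' @noRd
DNA_BASES <- c("A", "C", "G", "T")

#' Complement DNA bases (character vector of single bases or strings)
#' @keywords internal
#' @noRd
dna_complement <- function(x) chartr("ACGTacgtN", "TGCAtgcaN", x)

#' Reverse-complement a set of sequences given as character strings
#' @keywords internal
#' @noRd
dna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Run code with a temporarily seeded RNG, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  force(code)
}

#' Check roles vector: named character with exactly one "normal", >=2 "tumour"
#' @keywords internal
#' @noRd
check_roles <- function(roles) {
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    stop("`roles` must be a named character vector (names are sample labels)")
  bad <- setdiff(unique(roles), c("normal", "tumour", "reference"))
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (sum(roles == "normal") != 1L)
    stop("exactly one sample must have role 'normal'")
  if (sum(roles == "tumour") < 2L)
    stop("at least two samples must have role 'tumour'")
  invisible(roles)
}
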