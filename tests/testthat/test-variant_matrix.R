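samples <- names(test_roles)

basic_rows <- function() {
  data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    ref = c("C", "A", "G", "T"), alt = c("T", "G", "A", "C"),
    filter = c("PASS", "PASS", "q10", "PASS"),
    info = ".",
    N  = c(gtf("0/1"), gtf("0/0", 20, 0), gtf("0/1"), "./.:.:."),
    T1 = c(gtf("0/1"), gtf("0/1"), gtf("0/1"), gtf("0/1")),
    T2 = c(gtf("1/1", 0, 25), gtf("0/1"), gtf("0/1"), gtf("0/1")),
    T3 = c(gtf("0/0", 18, 0), gtf("0/1"), gtf("0/1"), gtf("0/1")),
    stringsAsFactors = FALSE)
}

test_that("VCF reading preserves rows, attaches roles and handles missing genotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, basic_rows(), samples)
  vs <- read_multisample_vcf(path, test_roles)
  expect_equal(nrow(vs$variants), 4L)
  expect_equal(colnames(vs$gt), samples)
  expect_identical(vs$roles, test_roles)
  # "./." genotype is missing
  expect_true(is.na(vs$gt[4, "N"]))
  # hom-ref, het and hom-alt all carry the right 0/1
  expect_equal(unname(vs$gt[1, ]), c(1L, 1L, 1L, 0L))
  # called-allele support: alt reads for carriers, ref reads for hom-ref
  expect_equal(unname(vs$support[1, ]), c(10L, 10L, 25L, 18L))
  # site filter column parsed
  expect_equal(vs$variants$filter_pass, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("a declared sample absent from the VCF is a fatal, named error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, basic_rows(), samples)
  roles <- c(test_roles, T9 = "tumour")
  expect_error(read_multisample_vcf(path, roles), "T9")
})

test_that("multi-allelic rows split into one biallelic record per alt", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- data.frame(
    chrom = "chr1", pos = 500L, ref = "A", alt = "G,T",
    filter = "PASS", info = ".",
    N = "0/1:10,8,0:18", T1 = "0/2:12,0,9:21", T2 = "1/2:0,7,6:13",
    T3 = "0/0:22,0,0:22", stringsAsFactors = FALSE)
  write_test_vcf(path, rows, samples)
  vs <- read_multisample_vcf(path, test_roles)
  expect_equal(nrow(vs$variants), 2L)
  expect_equal(vs$variants$alt, c("G", "T"))
  # carrier iff the genotype contains that specific alt
  expect_equal(unname(vs$gt[1, ]), c(1L, 0L, 1L, 0L))
  expect_equal(unname(vs$gt[2, ]), c(0L, 1L, 1L, 0L))
  # support follows the allele: alt AD for carriers of that alt
  expect_equal(unname(vs$support[1, ]), c(8L, 12L, 7L, 22L))
  expect_equal(unname(vs$support[2, ]), c(10L, 9L, 6L, 22L))
})

test_that("high-confidence filter enforces pass status, called genotypes and depth in every sample", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- basic_rows()
  # row 5: depth (4,4,3,4) -> boundary failure; row 6: (4,4,4,4) -> retained
  rows <- rbind(rows, data.frame(
    chrom = "chr1", pos = c(500L, 600L), ref = "C", alt = "A",
    filter = "PASS", info = ".",
    N  = c(gtf("0/1", 4, 4), gtf("0/1", 4, 4)),
    T1 = c(gtf("0/1", 4, 4), gtf("0/1", 4, 4)),
    T2 = c(gtf("0/1", 9, 3), gtf("0/1", 9, 4)),
    T3 = c(gtf("0/1", 4, 4), gtf("0/1", 4, 4))))
  write_test_vcf(path, rows, samples)
  vs <- read_multisample_vcf(path, test_roles)
  f <- filter_high_confidence(vs, min_reads = 4)
  expect_equal(f$variants$pos, c(100L, 200L, 600L))
  att <- attr(f, "attrition")
  expect_equal(unname(att["site_filter"]), 1L)      # the q10 row
  expect_equal(unname(att["missing_genotype"]), 1L) # the ./. row
  expect_equal(unname(att["low_support"]), 1L)      # the depth-3 row
  # idempotence
  f2 <- filter_high_confidence(f, min_reads = 4)
  expect_identical(f2$variants, f$variants)
  expect_identical(f2$gt, f$gt)
  # every retained record has >= min_reads in every sample
  expect_true(all(f$support >= 4))
})

test_that("known-site exclusion matches on chrom, pos and the specific alt", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, basic_rows(), samples)
  vs <- read_multisample_vcf(path, test_roles)

  known <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"),
               "chr1\t100\trs1\tC\tT\t.\t.\t.",   # matches record 1
               "chr1\t200\trs2\tA\tC\t.\t.\t."),  # alt mismatch: record 2 kept
             known)
  out <- exclude_known_sites(vs, known)
  expect_equal(out$variants$pos, c(200L, 300L, 400L))
  expect_equal(attr(out, "n_known_removed"), 1L)

  # header-only known file leaves the input unchanged
  empty <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t")), empty)
  same <- exclude_known_sites(vs, empty)
  expect_equal(nrow(same$variants), nrow(vs$variants))

  suppressWarnings(expect_error(exclude_known_sites(vs,
                                                    withr::local_tempfile())))
})

test_that("binarize encodes carriers as 1, drops signal-free columns, and refuses missing genotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- basic_rows()[c(1, 2), ]
  rows <- rbind(rows, data.frame(
    chrom = "chr1", pos = 700L, ref = "G", alt = "C", filter = "PASS",
    info = ".",
    N = gtf("0/0", 20, 0), T1 = gtf("0/0", 20, 0), T2 = gtf("0/0", 20, 0),
    T3 = gtf("0/0", 20, 0)))
  write_test_vcf(path, rows, samples)
  vs <- filter_high_confidence(read_multisample_vcf(path, test_roles))
  mm <- binarize(vs)
  # the all-hom-ref column is dropped
  expect_equal(ncol(mm$mat), 2L)
  expect_equal(unname(mm$mat[, 1]), c(1L, 1L, 1L, 0L))
  expect_equal(rownames(mm$mat), samples)

  vs_bad <- read_multisample_vcf(path, test_roles)
  vs_bad$gt[1, 1] <- NA_integer_
  expect_error(binarize(vs_bad), "missing")
})

test_that("reference pseudo-sample row is all zero, appended once, and valid on empty matrices", {
  mat <- rbind(N = c(1L, 0L), T1 = c(1L, 1L), T2 = c(0L, 1L), T3 = c(0L, 1L))
  mm <- add_reference_row(make_mmat(mat))
  expect_equal(nrow(mm$mat), 5L)
  expect_equal(sum(mm$mat["reference", ]), 0L)
  expect_equal(unname(mm$roles["reference"]), "reference")
  expect_error(add_reference_row(mm), "reference")

  empty <- make_mmat(mat[, 0, drop = FALSE])
  me <- add_reference_row(empty)
  expect_equal(dim(me$mat), c(5L, 0L))
})

test_that("marker matrix TSV round-trips through write/read", {
  mat <- rbind(N = c(1L, 0L, 1L), T1 = c(1L, 1L, 0L), T2 = c(0L, 1L, 0L),
               T3 = c(0L, 1L, 1L))
  mm <- make_mmat(mat)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_matrix(mm, path)
  back <- read_marker_matrix(path, test_roles)
  expect_equal(unname(back$mat), unname(mm$mat))
  expect_equal(back$info$pos, mm$info$pos)
})
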