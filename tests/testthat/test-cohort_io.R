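write_vcf_lines <- function(body, samples, file) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), file)
}

meta3 <- data.frame(sample = c("S1", "S2", "S3"),
                    sex = c("male", "female", "female"),
                    cohort_label = "rare_disease", stringsAsFactors = FALSE)

test_that("read_vcf parses genotype codes, splits multi-allelics, and collapses male X", {
  f <- tempfile(fileext = ".vcf")
  write_vcf_lines(c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tA\tC,T\t.\tPASS\t.\tGT\t0/1\t1/2\t2/2",
    "X\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1\t0/1\t./."),
    c("S1", "S2", "S3"), f)
  g <- read_vcf(f, meta3)
  expect_equal(nrow(g$variants), 4)   # multi-allelic site split into 2 rows
  expect_equal(unname(g$calls[, 1]), c(0L, 1L, 2L))
  # split rows carry per-allele counts
  expect_equal(unname(g$calls[, 2]), c(1L, 1L, 0L))  # C allele
  expect_equal(unname(g$calls[, 3]), c(0L, 1L, 2L))  # T allele
  # male hemizygous X kept as single-allele code; missing preserved
  expect_equal(unname(g$calls[, 4]), c(1L, 1L, NA))

  # per-allele tallies agree with direct parsing of the multi-allelic site
  gt <- c("0/1", "1/2", "2/2")
  for (k in 1:2) {
    direct <- vapply(strsplit(gt, "/"), function(a) sum(a == k), 0L)
    expect_equal(unname(g$calls[, 1 + k]), direct)
  }
})

test_that("read_vcf rejects samples missing from metadata and drops het male X", {
  f <- tempfile(fileext = ".vcf")
  write_vcf_lines("1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
                  c("S1", "S2", "S99"), f)
  expect_error(read_vcf(f, meta3), "S99")

  write_vcf_lines("X\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/1\t1/1",
                  c("S1", "S2", "S3"), f)
  g <- read_vcf(f, meta3)
  expect_true(is.na(g$calls[1, 1]))   # heterozygous male X call -> missing
  expect_equal(unname(g$calls[2:3, 1]), c(1L, 2L))
})

test_that("HLA table reader enforces explicit homozygotes and uniqueness", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tlocus\tallele1\tallele2",
               "S1\tHLA-B\tB*15:02\tB*40:01",
               "S2\tHLA-B\tB*58:01\tB*58:01"), f)
  h <- read_hla_table(f)
  expect_equal(nrow(h), 2)
  st <- hla_carrier_status(h, data.frame(locus = "HLA-B", allele = "B*58:01"))
  expect_equal(st$positive, c(FALSE, TRUE))

  writeLines(c("sample\tlocus\tallele1\tallele2",
               "S1\tHLA-B\tB*15:02\t"), f)
  expect_error(read_hla_table(f), "explicit")
  writeLines(c("sample\tlocus\tallele1\tallele2",
               "S1\tHLA-B\tB*15:02\tB*40:01",
               "S1\tHLA-B\tB*15:02\tB*40:01"), f)
  expect_error(read_hla_table(f), "duplicated")
})

test_that("QC drops low call-rate variants and high-missingness samples", {
  # 10 samples x 10 variants; sample 10 missing at half the variants
  calls <- matrix(1L, 10, 10)
  calls[10, 1:5] <- NA
  g <- make_geno(calls)
  out <- apply_qc(g, thresholds = qc_thresholds(variant_call_rate = 0.9,
                                                sample_missingness = 0.2))
  expect_equal(out$report$samples_dropped, 1)
  expect_equal(nrow(out$geno$samples), 9)
  expect_equal(out$report$variants_dropped, 0)

  # a variant with 50% call rate under a 0.9 threshold is dropped
  calls2 <- matrix(1L, 10, 2)
  calls2[1:5, 1] <- NA
  out2 <- apply_qc(make_geno(calls2))
  expect_equal(out2$report$variants_dropped, 1)

  # clean matrix passes unchanged
  out3 <- apply_qc(make_geno(matrix(0L, 4, 3)))
  expect_equal(out3$report$variants_dropped, 0)
  expect_equal(out3$report$samples_dropped, 0)

  # retained variants but every sample above the missingness cap
  diag_na <- matrix(0L, 3, 3); diag(diag_na) <- NA_integer_
  expect_error(
    apply_qc(make_geno(diag_na),
             thresholds = qc_thresholds(variant_call_rate = 0,
                                        sample_missingness = 0)),
    "all samples")
})

test_that("QC is idempotent", {
  set.seed(42)
  calls <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                         prob = c(.4, .3, .2, .1)), 20, 10)
  g <- make_geno(calls)
  once <- apply_qc(g)
  twice <- apply_qc(once$geno)
  expect_identical(once$geno$calls, twice$geno$calls)
  expect_equal(twice$report$variants_dropped, 0)
  expect_equal(twice$report$samples_dropped, 0)
})

test_that("allele frequency counts allele slots correctly", {
  g <- make_geno(matrix(c(0L, 1L, 2L), 3, 1))
  expect_equal(unname(compute_allele_frequency(g)), 0.5)

  g2 <- make_geno(matrix(c(1L, NA, NA), 3, 1))
  expect_equal(unname(compute_allele_frequency(g2)), 0.5)  # denominator 2

  # X-linked: 2 males [1, 0], 1 female [2] -> 3 alt / 4 slots
  g3 <- make_geno(matrix(c(1L, 0L, 2L), 3, 1),
                  sex = c("male", "male", "female"), chrom = "X")
  expect_equal(unname(compute_allele_frequency(g3)), 0.75)

  # no called slots -> undefined (NA), not zero
  g4 <- make_geno(matrix(NA_integer_, 2, 1))
  expect_true(is.na(compute_allele_frequency(g4)))

  expect_error(compute_allele_frequency(g, "rs_nope"), "not in matrix")
})

test_that("cohort AF converges to the generating frequency under HWE", {
  set.seed(11)
  q <- 0.23; n <- 4000
  g <- make_geno(matrix(rbinom(n, 2, q), n, 1))
  af <- unname(compute_allele_frequency(g))
  se <- sqrt(q * (1 - q) / (2 * n))
  expect_lt(abs(af - q), 3 * se)
})
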