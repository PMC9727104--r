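# hand-written five-record VCF exercising dosage parsing, missingness,
# phased calls, a multi-allelic record and partial INFO annotations
toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\t.\tA\tG\t.\tPASS\tQD=30;FS=1.5\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\tQD=1.5\tGT\t0/1\t./.\t0/0",
    "chr1\t300\t.\tG\tC\t.\tPASS\tFS=80\tGT\t0|1\t1|1\t0|0",
    "chr1\t400\t.\tT\tA,G\t.\tPASS\tQD=25\tGT\t1/2\t0/1\t0/0",
    "chr1\t500\t.\tA\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t1/1"),
    path)
  path
}

test_that("VCF parsing matches a hand parse of the toy file", {
  gm <- read_vcf(toy_vcf(tempfile(fileext = ".vcf")))
  expect_equal(dim(gm), c(3L, 5L))
  expect_identical(gm$samples, c("s1", "s2", "s3"))
  # dosage = count of non-reference alleles; ./. missing; phased accepted
  expect_identical(unname(gm$geno[, 1]), c(0L, 1L, 2L))
  expect_identical(unname(gm$geno[, 2]), c(1L, NA_integer_, 0L))
  expect_identical(unname(gm$geno[, 3]), c(1L, 2L, 0L))
  expect_identical(unname(gm$geno[, 4]), c(2L, 1L, 0L))
  expect_identical(gm$sites$multiallelic, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(gm$sites$qd, c(30, 1.5, NA, 25, NA))
  expect_equal(gm$sites$fs, c(1.5, NA, 80, NA, NA))
})

test_that("malformed GT records are rejected with their line number", {
  path <- tempfile(fileext = ".vcf")
  lines <- readLines(toy_vcf(tempfile(fileext = ".vcf")))
  lines[8] <- "chr1\t200\t.\tC\tT\t.\tPASS\tQD=1.5\tGT\t0/x\t./.\t0/0"
  writeLines(lines, path)
  expect_error(read_vcf(path), "line 8")
})

test_that("INFO hard filters remove exactly the violating sites and are idempotent", {
  # 10 sites: 4 violate one threshold each, 6 pass (some with absent INFO)
  sites <- data.frame(scaffold = "s", pos = 1:10 * 10, ref = "A", alt = "G",
                      qd = c(1.5, 5, 10, NA, 20, 30, 8, 9, 10, 11),
                      fs = c(1, 70, 2, 3, NA, 4, 5, 6, 7, 8),
                      mq = c(50, 50, 35, 50, 50, NA, 52, 53, 54, 55),
                      mq_rank_sum = c(0, 0, 0, -13, 0, 0, NA, 1, 1, 1),
                      read_pos_rank_sum = 0)
  gm <- genotype_matrix(matrix(1L, 2, 10), sites, c("a", "b"))
  filt <- apply_info_filters(gm)
  expect_equal(n_sites(filt), 6L)
  expect_equal(filt$sites$pos, c(50, 60, 70, 80, 90, 100))
  expect_identical(apply_info_filters(filt)$sites, filt$sites)
  # inverted missing-INFO policy drops the un-annotated sites too
  strict <- apply_info_filters(gm, drop_missing_info = TRUE)
  expect_equal(n_sites(strict), 3L)
})

test_that("a QD 1.5 site is removed and a fully clean site retained", {
  sites <- data.frame(scaffold = "s", pos = c(1L, 2L), ref = "A", alt = "G",
                      qd = c(1.5, 5), fs = c(10, 10), mq = c(50, 50),
                      mq_rank_sum = 0, read_pos_rank_sum = 0)
  gm <- genotype_matrix(matrix(0L, 1, 2), sites, "a")
  expect_identical(apply_info_filters(gm)$sites$pos, 2L)
})

test_that("complete-case biallelic selection keeps exactly the qualifying sites", {
  geno <- rbind(c(0L, 1L, NA, 2L, 0L, 1L, 0L, 2L),
                c(1L, 1L, 0L, 2L, 1L, NA, 0L, 2L))
  sites <- data.frame(scaffold = "s", pos = 1:8 * 10,
                      ref = c("A", "A", "A", "AT", "A", "A", "A", "A"),
                      alt = c("G", "T,C", "G", "T", "C", "G", "G", "T"),
                      multiallelic = c(FALSE, TRUE, rep(FALSE, 6)))
  gm <- genotype_matrix(geno, sites, c("a", "b"))
  out <- select_biallelic_complete(gm)
  # site 2 multi-allelic, 3 and 6 missing, 4 an indel: 1, 5, 7, 8 survive
  expect_equal(out$sites$pos, c(10, 50, 70, 80))
  expect_equal(sum(is.na(out$geno)), 0L)
})

test_that("substitution classification follows the purine/pyrimidine rule", {
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("C", "T"), "transition")
  expect_identical(classify_substitution("A", "T"), "transversion")
  expect_identical(classify_substitution("C", "G"), "transversion")
  expect_identical(classify_substitution(c("G", "T", "A"), c("A", "C", "C")),
                   c("transition", "transition", "transversion"))
  expect_error(classify_substitution("A", "N"), "ambiguity")
  expect_error(classify_substitution("A", "A"), "differ")
})

test_that("write_vcf / read_vcf round-trips the supported dialect", {
  scen <- simulate_scenario(scenario_config(n_sites = 200, seed = 13,
                                            missing_rate = 0.02))
  path <- tempfile(fileext = ".vcf")
  write_vcf(scen$nuclear, path)
  back <- read_vcf(path)
  expect_identical(back$samples, scen$nuclear$samples)
  expect_identical(unname(back$geno), unname(scen$nuclear$geno))
  expect_equal(back$sites$pos, scen$nuclear$sites$pos)
  expect_equal(back$sites$qd, scen$nuclear$sites$qd)
  expect_equal(back$sites$read_pos_rank_sum,
               scen$nuclear$sites$read_pos_rank_sum)
})
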