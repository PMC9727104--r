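# VCF dialect: biallelic-oriented VCF 4.2 with diploid GT calls and the
# five variant-caller INFO annotations used for hard filtering
# (QD, FS, MQ, MQRankSum, ReadPosRankSum).

.info_keys <- c(qd = "QD", fs = "FS", mq = "MQ",
                mq_rank_sum = "MQRankSum", read_pos_rank_sum = "ReadPosRankSum")

#' Read a VCF file into a genotype matrix
#'
#' Parses diploid GT fields to dosages (count of non-reference alleles;
#' \code{"./."} becomes missing). Multi-allelic records are retained but
#' flagged, so parsing is lossless; they are excluded later by
#' \code{\link{select_biallelic_complete}}. The INFO annotations QD, FS,
#' MQ, MQRankSum and ReadPosRankSum are parsed where present.
#'
#' @param path a VCF 4.x file with GT in the FORMAT column.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  n_head <- sum(startsWith(readLines(path, warn = FALSE), "#"))

  alleles <- gsub("[|]", "/", gt)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- !is.na(alleles)
  parts <- strsplit(alleles[known], "/", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) == 2 &&
                 all(grepl("^([0-9]+|\\.)$", p)), logical(1))
  if (!all(ok)) {
    bad_site <- row(alleles)[known][which(!ok)[1]]
    stop(sprintf("malformed GT field at VCF line %d (%s:%s)",
                 n_head + bad_site, fix[bad_site, "CHROM"], fix[bad_site, "POS"]),
         call. = FALSE)
  }
  val <- vapply(parts, function(p) {
    if (any(p == ".")) NA_integer_ else sum(p != "0")
  }, integer(1))
  dos[known] <- val

  info_cols <- lapply(.info_keys, function(k)
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = k))))
  sites <- data.frame(scaffold = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  for (nm in names(.info_keys)) sites[[nm]] <- info_cols[[nm]]
  sites$multiallelic <- grepl(",", sites$alt, fixed = TRUE)
  genotype_matrix(t(dos), sites, colnames(gt))
}

#' Write a genotype matrix as VCF 4.2
#'
#' Inverse of \code{\link{read_vcf}} on the supported dialect: GT genotypes
#' plus the five filtering INFO keys (absent annotations are simply
#' omitted from the INFO column).
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param path output file path (plain text).
#' @export
write_vcf <- function(x, path) {
  s <- x$sites
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(s$scaffold)),
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  info <- vapply(seq_len(nrow(s)), function(i) {
    vals <- vapply(names(.info_keys), function(nm) {
      v <- s[[nm]][i]
      if (is.na(v)) NA_character_ else sprintf("%s=%s", .info_keys[[nm]],
                                               format(v, scientific = FALSE))
    }, character(1))
    vals <- vals[!is.na(vals)]
    if (length(vals)) paste(vals, collapse = ";") else "."
  }, character(1))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(x$geno), ncol(x$geno))
  known <- !is.na(x$geno)
  gt[known] <- gt_code[x$geno[known] + 1L]
  body <- paste(s$scaffold, s$pos, ".", s$ref, s$alt, ".", "PASS", info, "GT",
                sep = "\t")
  gt_lines <- apply(gt, 2, paste, collapse = "\t")
  writeLines(c(hdr, paste(body, gt_lines, sep = "\t")), path)
  invisible(path)
}

#' Hard-filter sites on variant-caller INFO annotations
#'
#' Removes a site when QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < -12.5 or
#' ReadPosRankSum < -8.0. A site whose annotation is absent passes that
#' particular filter by default (callers do not emit rank-sum annotations
#' at homozygous-only sites); set \code{drop_missing_info = TRUE} to remove
#' such sites instead. The operation is idempotent.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param qd_min,fs_max,mq_min,mq_rank_sum_min,read_pos_rank_sum_min filter
#'   thresholds.
#' @param drop_missing_info if TRUE, a missing annotation fails its filter.
#' @return the filtered \code{genotype_matrix}.
#' @export
apply_info_filters <- function(x, qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                               mq_rank_sum_min = -12.5,
                               read_pos_rank_sum_min = -8.0,
                               drop_missing_info = FALSE) {
  s <- x$sites
  pass1 <- function(v, ok) if (drop_missing_info) !is.na(v) & ok else is.na(v) | ok
  keep <- pass1(s$qd, s$qd >= qd_min) &
    pass1(s$fs, s$fs <= fs_max) &
    pass1(s$mq, s$mq >= mq_min) &
    pass1(s$mq_rank_sum, s$mq_rank_sum >= mq_rank_sum_min) &
    pass1(s$read_pos_rank_sum, s$read_pos_rank_sum >= read_pos_rank_sum_min)
  gm_subset(x, sites = which(keep))
}

#' Keep biallelic SNVs genotyped in every sample
#'
#' Restricts to single-nucleotide, biallelic sites with zero missing
#' dosages across all samples - the complete-case substrate required by
#' the individual-distance phylogeny and the frequency-based statistics.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @return the restricted \code{genotype_matrix} (no missing entries).
#' @export
select_biallelic_complete <- function(x) {
  s <- x$sites
  acgt <- c("A", "C", "G", "T")
  snv <- !s$multiallelic & toupper(s$ref) %in% acgt & toupper(s$alt) %in% acgt &
    toupper(s$ref) != toupper(s$alt)
  complete <- colSums(is.na(x$geno)) == 0
  gm_subset(x, sites = which(snv & complete))
}
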