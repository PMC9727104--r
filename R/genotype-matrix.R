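#' Genotype matrix container
#'
#' The substrate of all nuclear statistics in the package: a samples x sites
#' matrix of allele dosages (0, 1, 2 copies of the ALT allele; \code{NA} for
#' a missing call) together with per-site metadata (scaffold, position,
#' REF/ALT alleles and the variant-caller INFO annotations used for
#' filtering).
#'
#' @param geno integer matrix, samples in rows, sites in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param sites data.frame with one row per site; must contain columns
#'   \code{scaffold}, \code{pos}, \code{ref}, \code{alt}. Optional columns:
#'   \code{qd}, \code{fs}, \code{mq}, \code{mq_rank_sum},
#'   \code{read_pos_rank_sum} (INFO annotations, \code{NA} when absent) and
#'   \code{multiallelic} (logical).
#' @param samples character vector of unique sample ids, one per row of
#'   \code{geno}.
#'
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(geno, sites, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  .check(nrow(geno) == length(samples),
         "geno has %d rows but %d sample ids given", nrow(geno), length(samples))
  .check(ncol(geno) == nrow(sites),
         "geno has %d columns but %d site rows given", ncol(geno), nrow(sites))
  .check(!anyDuplicated(samples), "sample ids must be unique")
  need <- c("scaffold", "pos", "ref", "alt")
  .check(all(need %in% names(sites)),
         "sites must contain columns: %s", paste(need, collapse = ", "))
  bad <- geno[!is.na(geno)]
  .check(all(bad %in% 0:2), "dosages must be 0, 1, 2 or NA")
  .check(all(sites$pos >= 1), "positions are 1-based; pos >= 1 required")
  if (is.null(sites$multiallelic)) sites$multiallelic <- FALSE
  for (f in c("qd", "fs", "mq", "mq_rank_sum", "read_pos_rank_sum"))
    if (is.null(sites[[f]])) sites[[f]] <- NA_real_
  rownames(geno) <- samples
  rownames(sites) <- NULL
  structure(list(geno = geno, sites = sites, samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites on %d scaffold(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$sites$scaffold))))
  cat(sprintf("  missing calls: %d\n", sum(is.na(x$geno))))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param x a \code{genotype_matrix}
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname n_samples
#' @export
n_sites <- function(x) ncol(x$geno)

#' Subset a genotype matrix
#'
#' @param x a \code{genotype_matrix}
#' @param samples sample ids (or logical/integer index) to keep
#' @param sites logical/integer index over sites to keep
#' @return a \code{genotype_matrix}
#' @export
gm_subset <- function(x, samples = NULL, sites = NULL) {
  geno <- x$geno; meta <- x$sites; ids <- x$samples
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, ids) else seq_along(ids)[samples]
    .check(!anyNA(idx), "unknown sample id(s): %s",
           paste(setdiff(samples, ids), collapse = ", "))
    geno <- geno[idx, , drop = FALSE]; ids <- ids[idx]
  }
  if (!is.null(sites)) {
    geno <- geno[, sites, drop = FALSE]
    meta <- meta[sites, , drop = FALSE]
  }
  genotype_matrix(geno, meta, ids)
}

#' Classify a single-nucleotide substitution
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) changes are
#' transitions; every other pair is a transversion.
#'
#' @param ref,alt single nucleotides in \{A, C, G, T\} (vectorised).
#' @return character vector, \code{"transition"} or \code{"transversion"}.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  .check(all(ok), "ref/alt must be single nucleotides A/C/G/T (no ambiguity codes)")
  .check(all(ref != alt), "ref and alt must differ")
  purine <- c("A", "G")
  same_class <- (ref %in% purine) == (alt %in% purine)
  ifelse(same_class, "transition", "transversion")
}

#' Transversion flags for the sites of a genotype matrix
#' @param x a \code{genotype_matrix}
#' @return logical vector, one per site (NA for non-SNV records)
#' @export
site_is_transversion <- function(x) {
  ref <- toupper(x$sites$ref); alt <- toupper(x$sites$alt)
  snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
  out <- rep(NA, length(ref))
  out[snv] <- classify_substitution(ref[snv], alt[snv]) == "transversion"
  out
}
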