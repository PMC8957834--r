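#' Construct a genotype matrix
#'
#' The central container of the package: an `n_samples x n_loci` matrix of
#' diploid biallelic genotype calls plus locus metadata. Calls are stored as
#' ALT-allele dosages: `0` = homozygous reference (0/0), `1` = heterozygous
#' (0/1), `2` = homozygous alternate (1/1), `NA` = missing (./.).
#'
#' Loci are sorted by (chromosome, position), chromosomes kept in order of
#' first appearance (VCF header order), position ascending, ties stable.
#'
#' @param calls integer matrix, samples in rows, loci in columns; values
#'   0, 1, 2 or NA.
#' @param samples character vector of unique sample IDs (one per row).
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `id`, and
#'   optionally `ref`, `alt` (single-base alleles; defaulted to A/G when
#'   absent, e.g. for matrices read from plain TSV).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples, loci) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.character(samples)
  if (nrow(calls) != length(samples))
    stop("number of rows of `calls` must equal length of `samples`")
  if (anyDuplicated(samples))
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (length(samples) < 1L) stop("need at least one sample")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "id")
  if (!all(required %in% names(loci)))
    stop("`loci` needs columns chrom, pos, id")
  if (nrow(loci) != ncol(calls))
    stop("number of loci must equal number of columns of `calls`")
  if (is.null(loci$ref)) loci$ref <- rep("A", nrow(loci))
  if (is.null(loci$alt)) loci$alt <- rep("G", nrow(loci))
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  loci$id <- as.character(loci$id)
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("calls must be 0, 1, 2 or NA")
  # sort loci by (chrom appearance order, pos), stable
  ord <- order(match(loci$chrom, unique(loci$chrom)), loci$pos)
  loci <- loci[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(loci) <- NULL
  dimnames(calls) <- list(samples, loci$id)
  structure(list(calls = calls, samples = samples, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d chromosome%s)\n",
              n_samples(x), n_loci(x), length(unique(x$loci$chrom)),
              if (length(unique(x$loci$chrom)) == 1L) "" else "s"))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer scalar.
#' @export
n_samples <- function(gm) length(gm$samples)

#' Number of loci in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer scalar.
#' @export
n_loci <- function(gm) nrow(gm$loci)

#' Restrict a genotype matrix to a set of loci
#'
#' Column indices are kept in the order given (a panel is an ordered
#' collection), so the result's loci are only (chrom, pos)-sorted when
#' `idx` is.
#'
#' @param gm a `genotype_matrix`.
#' @param idx integer vector of locus (column) indices.
#' @return a `genotype_matrix` over the selected loci.
#' @export
subset_loci <- function(gm, idx) {
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_loci(gm)))
    stop("locus indices out of range")
  out <- gm
  out$calls <- gm$calls[, idx, drop = FALSE]
  out$loci <- gm$loci[idx, , drop = FALSE]
  rownames(out$loci) <- NULL
  out
}

stopifnot_gm <- function(gm) {
  if (!inherits(gm, "genotype_matrix"))
    stop("expected a `genotype_matrix`")
  invisible(gm)
}
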