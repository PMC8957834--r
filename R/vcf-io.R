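#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads diploid GT calls from a VCF 4.x file. Only biallelic SNP records
#' (single-base REF and a single single-base ALT) are retained; skipped
#' records are counted and reported via a message. Phased separators are
#' treated as unphased (`0|1` is read as `0/1`).
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return a [genotype_matrix()]. The number of skipped non-biallelic /
#'   non-SNP records is attached as attribute `"skipped"`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (!"GT" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
    stop("VCF has no GT FORMAT field: ", path)
  samples <- colnames(vcf)
  if (anyDuplicated(samples))
    stop("duplicate sample IDs in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(S4Vectors::mcols(rr)$REF)
  altl <- S4Vectors::mcols(rr)$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(rr))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message(n_skipped, " non-biallelic or non-SNP record(s) skipped")

  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  calls <- matrix(gt_to_dosage(gt), nrow = nrow(gt), ncol = ncol(gt))
  rr <- rr[keep]
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0(as.character(GenomicRanges::seqnames(rr)),
                                  "_", GenomicRanges::start(rr))
  loci <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = ids,
    ref = ref[keep],
    alt = alt1[keep],
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(t(calls), samples, loci)
  attr(gm, "skipped") <- n_skipped
  gm
}

# "0/0","0|1","1/1","./.",".","0/1:..." -> dosage 0/1/2/NA
gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", as.character(gt))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt == "0/0"] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt == "1/1"] <- 2L
  out
}

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}

#' Write a genotype matrix (or a panel of its loci) to a VCF file
#'
#' Emits a minimal valid VCFv4.2 with a GT FORMAT field, one record per
#' selected locus, in (chrom, pos) order, original sample order preserved.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param panel optional integer vector of locus indices (defaults to all
#'   loci). Indices are written in (chrom, pos)-sorted order as VCF requires.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(gm, path, panel = seq_len(n_loci(gm))) {
  stopifnot_gm(gm)
  panel <- as.integer(panel)
  if (length(panel) && (min(panel) < 1L || max(panel) > n_loci(gm)))
    stop("panel indices out of range")
  sub <- subset_loci(gm, panel)
  ord <- order(match(sub$loci$chrom, unique(gm$loci$chrom)), sub$loci$pos)
  sub <- subset_loci(sub, ord)

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=corepanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  for (chr in unique(sub$loci$chrom))
    writeLines(sprintf("##contig=<ID=%s>", chr), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  if (nrow(sub$loci) > 0L) {
    gt <- apply(sub$calls, 2, dosage_to_gt)
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L)  # single sample
    lines <- vapply(seq_len(nrow(sub$loci)), function(j) {
      paste(c(sub$loci$chrom[j], sub$loci$pos[j], sub$loci$id[j],
              sub$loci$ref[j], sub$loci$alt[j], ".", "PASS", ".", "GT",
              gt[, j]), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a genotype matrix from a plain TSV file
#'
#' Alternate input dialect: samples as rows, loci as columns, header row of
#' locus IDs, first column of sample IDs. Genotype symbols follow the
#' A/B/h/- convention: `A` = 1/1 (homozygous alternate), `B` = 0/0
#' (homozygous reference), `h` = 0/1 (heterozygous), `-` = missing.
#'
#' Locus metadata is not carried by the TSV; locus IDs of the form
#' `chrom_pos` are split back into coordinates, anything else is placed on
#' a single pseudo-chromosome `"un"` at consecutive positions.
#'
#' @param path path to the TSV file.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  sym <- as.matrix(tab)
  bad <- setdiff(unique(as.vector(sym)), c("A", "B", "h", "-"))
  if (length(bad))
    stop("unknown genotype symbol(s): ", paste(bad, collapse = ", "))
  calls <- matrix(NA_integer_, nrow(sym), ncol(sym))
  calls[sym == "B"] <- 0L
  calls[sym == "h"] <- 1L
  calls[sym == "A"] <- 2L
  ids <- colnames(sym)
  m <- regmatches(ids, regexec("^(.+)_([0-9]+)$", ids))
  ok <- lengths(m) == 3L
  loci <- data.frame(
    chrom = ifelse(ok, vapply(m, function(x) x[2][1], character(1)), "un"),
    pos = ifelse(ok, as.integer(vapply(m, function(x) x[3][1], character(1))),
                 seq_along(ids)),
    id = ids, stringsAsFactors = FALSE
  )
  genotype_matrix(calls, rownames(sym), loci)
}

#' Write a genotype matrix as a plain TSV file
#'
#' Inverse of [read_genotype_tsv()]: samples as rows, loci as columns,
#' symbols `A` = 1/1, `B` = 0/0, `h` = 0/1, `-` = missing.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(gm, path) {
  stopifnot_gm(gm)
  sym <- matrix("-", n_samples(gm), n_loci(gm))
  sym[!is.na(gm$calls) & gm$calls == 0L] <- "B"
  sym[!is.na(gm$calls) & gm$calls == 1L] <- "h"
  sym[!is.na(gm$calls) & gm$calls == 2L] <- "A"
  df <- data.frame(sample = gm$samples, sym, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample", gm$loci$id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode genotype calls as the genetic algorithm's integer codes
#'
#' Maps the four genotype states to the integer alphabet used inside the
#' GA: missing (./.) -> 45, homozygous reference (0/0) -> 97, homozygous
#' alternate (1/1) -> 98, heterozygous (0/1) -> 104. The map is a bijection
#' on the four-state alphabet; [decode_genotypes()] inverts it.
#'
#' @param gm a [genotype_matrix()].
#' @return an integer matrix of class `encoded_matrix` (samples x loci,
#'   dimnames preserved) with locus metadata attached as attribute `"loci"`.
#' @export
encode_genotypes <- function(gm) {
  stopifnot_gm(gm)
  enc <- matrix(45L, n_samples(gm), n_loci(gm),
                dimnames = dimnames(gm$calls))
  enc[!is.na(gm$calls) & gm$calls == 0L] <- 97L
  enc[!is.na(gm$calls) & gm$calls == 2L] <- 98L
  enc[!is.na(gm$calls) & gm$calls == 1L] <- 104L
  attr(enc, "loci") <- gm$loci
  attr(enc, "samples") <- gm$samples
  class(enc) <- c("encoded_matrix", class(enc))
  enc
}

#' Decode an encoded matrix back to a genotype matrix
#'
#' @param enc an `encoded_matrix` produced by [encode_genotypes()].
#' @return the original [genotype_matrix()]; `decode(encode(gm))` is the
#'   identity.
#' @export
decode_genotypes <- function(enc) {
  if (!inherits(enc, "encoded_matrix"))
    stop("expected an `encoded_matrix`")
  loci <- attr(enc, "loci")
  samples <- attr(enc, "samples")
  codes <- unclass(enc)
  bad <- setdiff(unique(as.vector(codes)), c(45L, 97L, 98L, 104L))
  if (length(bad)) stop("invalid codes: ", paste(bad, collapse = ", "))
  calls <- matrix(NA_integer_, nrow(codes), ncol(codes))
  calls[codes == 97L] <- 0L
  calls[codes == 104L] <- 1L
  calls[codes == 98L] <- 2L
  genotype_matrix(calls, samples, loci)
}
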