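# Small in-code fixture builders shared across test files.

# Build a genotype_matrix from dosage rows (one numeric vector per sample);
# loci placed on one chromosome at positions 100, 200, ... unless chrom/pos
# are given.
make_gm <- function(..., chrom = NULL, pos = NULL, samples = NULL) {
  rows <- list(...)
  calls <- do.call(rbind, rows)
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  genotype_matrix(calls, samples,
                  data.frame(chrom = chrom, pos = pos,
                             id = paste0(chrom, "_", pos)))
}

# Write a minimal VCF from header fields + body lines (character vector).
write_test_vcf <- function(body, samples, path = tempfile(fileext = ".vcf"),
                           format_gt = TRUE) {
  header <- c(
    "##fileformat=VCFv4.2",
    if (format_gt)
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
    else
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    "##contig=<ID=chr1>",
    "##contig=<ID=chr2>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

# A deterministic small diverse population for GA tests.
small_enc <- function(n = 8, m = 15, seed = 42) {
  cfg <- sim_config(n_samples = n, n_loci = m, n_chromosomes = 3,
                    n_subgroups = 2, divergence = 0.2,
                    missing_rate = 0.05, dup_fraction = 0,
                    rng_seed = seed)
  encode_genotypes(simulate_population(cfg))
}
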