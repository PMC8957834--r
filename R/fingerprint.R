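#' Per-sample binary fingerprint codes
#'
#' Converts panel genotypes into the compact fingerprint code strings used
#' for variety identification: homozygous reference (0/0) -> `1`,
#' homozygous alternate (1/1) -> `2`, heterozygous (0/1) -> `0`, missing
#' -> `-`, concatenated in panel locus order. Two samples receive distinct
#' codes exactly when their panel genotype profiles differ (with missing
#' treated as an ordinary symbol).
#'
#' @param gm a [genotype_matrix()].
#' @param panel integer vector of locus indices; defaults to all loci.
#' @return data.frame with columns `sample` and `code` (strings of length
#'   `length(panel)` over `{0,1,2,-}`).
#' @export
binary_fingerprint <- function(gm, panel = seq_len(n_loci(gm))) {
  stopifnot_gm(gm)
  panel <- as.integer(panel)
  if (length(panel) && (min(panel) < 1L || max(panel) > n_loci(gm)))
    stop("panel indices out of range")
  sub <- gm$calls[, panel, drop = FALSE]
  sym <- matrix("-", nrow(sub), ncol(sub))
  sym[!is.na(sub) & sub == 0L] <- "1"
  sym[!is.na(sub) & sub == 2L] <- "2"
  sym[!is.na(sub) & sub == 1L] <- "0"
  codes <- if (ncol(sym) == 0L) rep("", nrow(sym))
           else do.call(paste0, as.data.frame(sym))
  data.frame(sample = gm$samples, code = codes, stringsAsFactors = FALSE)
}

# pairwise counts of (shared non-missing, differing) loci via indicator
# cross-products: shared = B B^T with B = !is.na; equal = sum_g A_g A_g^T
pairwise_counts <- function(calls) {
  B <- (!is.na(calls)) * 1
  shared <- B %*% t(B)
  equal <- matrix(0, nrow(calls), nrow(calls))
  for (g in 0:2) {
    A <- (!is.na(calls) & calls == g) * 1
    equal <- equal + A %*% t(A)
  }
  list(shared = shared, differing = shared - equal)
}

#' Pairwise differing-locus counts over a panel
#'
#' Entry (i, j) counts the panel loci at which samples i and j carry
#' different genotypes, both calls non-missing. Symmetric, zero diagonal,
#' entries in `[0, C]`.
#'
#' @param gm a [genotype_matrix()].
#' @param panel integer vector of locus indices; defaults to all loci.
#' @return symmetric integer matrix with sample IDs as dimnames.
#' @export
pairwise_differing_loci <- function(gm, panel = seq_len(n_loci(gm))) {
  stopifnot_gm(gm)
  sub <- subset_loci(gm, panel)
  d <- pairwise_counts(sub$calls)$differing
  storage.mode(d) <- "integer"
  dimnames(d) <- list(gm$samples, gm$samples)
  d
}

#' Genotype mismatch distance matrix
#'
#' d(i, j) = (number of loci where i and j differ, both non-missing) /
#' (number of loci non-missing in both). Symmetric with zero diagonal,
#' entries in `[0, 1]`. A pair sharing no non-missing locus gets distance
#' 1 with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param loci integer vector of locus indices; defaults to all loci.
#' @return symmetric numeric distance matrix with sample IDs as dimnames.
#' @export
mismatch_distance_matrix <- function(gm, loci = seq_len(n_loci(gm))) {
  stopifnot_gm(gm)
  if (length(loci) < 1L) stop("need at least one locus")
  sub <- subset_loci(gm, loci)
  pc <- pairwise_counts(sub$calls)
  if (any(pc$shared == 0 & row(pc$shared) != col(pc$shared)))
    warning("sample pair(s) share no non-missing locus; distance set to 1")
  d <- ifelse(pc$shared > 0, pc$differing / pc$shared, 1)
  diag(d) <- 0
  dimnames(d) <- list(gm$samples, gm$samples)
  d
}

#' Correlation between panel and full-set distance matrices
#'
#' Mantel-style statistic: Pearson correlation between the strictly upper
#' triangular entries of the two distance matrices. Used to check how well
#' a small panel preserves the pairwise genetic distances of the full
#' locus set. Optionally a permutation p-value (random relabelings of the
#' panel matrix's samples) is attached.
#'
#' @param full_dm,panel_dm square distance matrices over the same samples
#'   in the same order.
#' @param permutations number of sample-relabeling permutations for a
#'   p-value; 0 (default) skips the test.
#' @return correlation in `[-1, 1]`; with `permutations > 0`, attribute
#'   `"p_value"` holds the one-sided permutation p-value.
#' @export
panel_fit_correlation <- function(full_dm, panel_dm, permutations = 0) {
  if (!all(dim(full_dm) == dim(panel_dm)))
    stop("distance matrices must have identical dimensions")
  ut <- upper.tri(full_dm)
  x <- full_dm[ut]; y <- panel_dm[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (constant) distance triangle; correlation undefined")
  r <- stats::cor(x, y)
  if (permutations > 0) {
    n <- nrow(full_dm)
    null_r <- vapply(seq_len(permutations), function(k) {
      p <- sample.int(n)
      stats::cor(x, panel_dm[p, p][ut])
    }, numeric(1))
    attr(r, "p_value") <- (1 + sum(null_r >= r)) / (1 + permutations)
  }
  r
}

#' Per-locus reference allele frequency
#'
#' p = (2 * n_refhom + n_het) / (2 * n_nonmissing). Loci with no
#' non-missing call get `NA` with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @return named numeric vector (locus IDs), values in `[0, 1]` or `NA`.
#' @export
allele_frequencies <- function(gm) {
  stopifnot_gm(gm)
  n_obs <- colSums(!is.na(gm$calls))
  n_ref <- colSums(!is.na(gm$calls) & gm$calls == 0L)
  n_het <- colSums(!is.na(gm$calls) & gm$calls == 1L)
  if (any(n_obs == 0))
    warning(sum(n_obs == 0), " locus/loci with no non-missing call; NA")
  p <- ifelse(n_obs > 0, (2 * n_ref + n_het) / (2 * n_obs), NA_real_)
  names(p) <- gm$loci$id
  p
}

#' Polymorphism information content of a biallelic locus
#'
#' Standard biallelic PIC: `1 - (p^2 + q^2) - 2 p^2 q^2` with `q = 1 - p`.
#' Maximal value 0.375 at p = 0.5; 0 for a monomorphic locus; symmetric in
#' p and q. `NA` frequencies pass through as `NA`.
#'
#' @param p reference allele frequency (vectorized), each in `[0, 1]`.
#' @return PIC values in `[0, 0.375]`.
#' @export
pic <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("allele frequency outside [0, 1]")
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Panel locus counts per chromosome
#'
#' @param panel integer vector of locus indices.
#' @param loci locus metadata data.frame with a `chrom` column.
#' @return named integer vector (chromosome -> count); counts sum to
#'   `length(panel)`.
#' @export
per_chromosome_counts <- function(panel, loci) {
  if (length(panel) && (min(panel) < 1L || max(panel) > nrow(loci)))
    stop("panel indices out of range")
  counts <- table(factor(loci$chrom[panel], levels = unique(loci$chrom)))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Evaluate a chosen panel
#'
#' Bundles the panel-validation statistics into one report: discrimination
#' fraction (panel fitness), pairwise differing-locus counts, per-SNP and
#' mean PIC, per-chromosome locus counts, and the panel-versus-full
#' distance correlation.
#'
#' @param gm the full filtered [genotype_matrix()].
#' @param panel integer vector of locus indices into `gm`.
#' @return a `panel_eval_report` list.
#' @export
evaluate_panel <- function(gm, panel) {
  stopifnot_gm(gm)
  enc <- encode_genotypes(gm)
  p <- allele_frequencies(subset_loci(gm, panel))
  rep <- list(
    panel_size = length(panel),
    discrimination = fitness(enc, panel),
    differing_loci = pairwise_differing_loci(gm, panel),
    pic = pic(p),
    mean_pic = mean(pic(p), na.rm = TRUE),
    chrom_counts = per_chromosome_counts(panel, gm$loci),
    fit_correlation = panel_fit_correlation(
      mismatch_distance_matrix(gm),
      mismatch_distance_matrix(gm, panel))
  )
  class(rep) <- "panel_eval_report"
  rep
}

#' @export
print.panel_eval_report <- function(x, ...) {
  cat(sprintf(paste0("panel evaluation: %d loci\n",
                     "  discrimination: %.4f\n",
                     "  mean PIC:       %.4f\n",
                     "  distance fit r: %.4f\n"),
              x$panel_size, x$discrimination, x$mean_pic,
              x$fit_correlation))
  invisible(x)
}
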