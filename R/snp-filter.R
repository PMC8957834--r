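#' Candidate SNP filtering
#'
#' Three filters reduce a raw genotype matrix to the candidate set fed to
#' the genetic algorithm, applied in fixed order:
#' missingness -> homozygote counts -> adjacent-pair LD.
#'
#' @name snp_filter
NULL

new_filter_report <- function(stage, gm_in, keep, reason) {
  removed <- gm_in$loci[!keep, c("chrom", "pos", "id"), drop = FALSE]
  removed$reason <- if (nrow(removed)) reason else character(0)
  rownames(removed) <- NULL
  structure(list(stage = stage,
                 n_input = n_loci(gm_in),
                 n_removed = sum(!keep),
                 n_kept = sum(keep),
                 removed = removed),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter stage '%s': %d loci in, %d removed, %d kept\n",
              x$stage, x$n_input, x$n_removed, x$n_kept))
  invisible(x)
}

#' Remove loci with too many missing calls
#'
#' A locus survives iff its missing-call fraction is at most
#' `max_missing_fraction`; removal is strict-greater, so with 100 samples
#' and threshold 0.01 a locus with exactly one missing call is kept.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_fraction maximum tolerated fraction of missing calls,
#'   in `[0, 1]`. Default 0.01.
#' @return list with elements `gm` (filtered matrix) and `report`
#'   (a `filter_report`).
#' @export
filter_by_missing <- function(gm, max_missing_fraction = 0.01) {
  stopifnot_gm(gm)
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must be in [0, 1]")
  frac <- colMeans(is.na(gm$calls))
  keep <- frac <= max_missing_fraction
  list(gm = subset_loci(gm, which(keep)),
       report = new_filter_report("missing", gm, keep, "missing_fraction"))
}

#' Remove loci lacking both homozygote classes
#'
#' A locus survives iff it carries at least `min_homozygote_count` calls of
#' *each* homozygous genotype (0/0 and 1/1). An all-heterozygous locus is
#' always removed (for `min_homozygote_count` > 0).
#'
#' @param gm a [genotype_matrix()].
#' @param min_homozygote_count required count of each homozygote class.
#'   Default 2.
#' @return list with elements `gm` and `report`.
#' @export
filter_by_homozygote_count <- function(gm, min_homozygote_count = 2) {
  stopifnot_gm(gm)
  if (min_homozygote_count < 0) stop("min_homozygote_count must be >= 0")
  n_ref <- colSums(!is.na(gm$calls) & gm$calls == 0L)
  n_alt <- colSums(!is.na(gm$calls) & gm$calls == 2L)
  keep <- n_ref >= min_homozygote_count & n_alt >= min_homozygote_count
  list(gm = subset_loci(gm, which(keep)),
       report = new_filter_report("homozygote", gm, keep, "homozygote_count"))
}

# squared Pearson correlation of dosages over pairwise-complete samples;
# 0 by convention for <2 complete pairs or zero variance at either locus
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Squared correlation between adjacent loci
#'
#' For each pair of consecutive loci on the same chromosome, computes the
#' squared Pearson correlation of allele dosages (0/0 = 0, 0/1 = 1,
#' 1/1 = 2) over samples non-missing at both loci. Pairs with fewer than
#' two complete observations, or zero variance at either locus, get
#' r-squared 0 by convention.
#'
#' @param gm a [genotype_matrix()] (loci already (chrom, pos)-sorted by
#'   construction).
#' @return data.frame with columns `i`, `j` (column indices of the pair),
#'   `chrom` and `r2`; zero rows if no within-chromosome adjacency exists.
#' @export
adjacent_r2 <- function(gm) {
  stopifnot_gm(gm)
  m <- n_loci(gm)
  if (m < 2L)
    return(data.frame(i = integer(0), j = integer(0),
                      chrom = character(0), r2 = numeric(0)))
  i <- seq_len(m - 1L)
  same <- gm$loci$chrom[i] == gm$loci$chrom[i + 1L]
  i <- i[same]
  r2 <- vapply(i, function(k) pair_r2(gm$calls[, k], gm$calls[, k + 1L]),
               numeric(1))
  data.frame(i = i, j = i + 1L, chrom = gm$loci$chrom[i], r2 = r2)
}

#' Filter loci by adjacent-pair linkage disequilibrium
#'
#' Two modes:
#' * `"prune"` (default): standard LD pruning. Sweeping each chromosome
#'   left to right, a locus is removed when its dosage r-squared with the
#'   last *kept* locus exceeds `r2_threshold`, so runs of mutually
#'   redundant loci collapse to their first member.
#' * `"literal_retain"`: the source wording taken literally — only loci
#'   belonging to at least one adjacent pair with r-squared above the
#'   threshold are retained. Note this *inverts* standard pruning; it keeps
#'   redundant loci and drops independent ones.
#'
#' @param gm a [genotype_matrix()].
#' @param r2_threshold r-squared above which adjacent loci are considered
#'   redundant. Default 0.95.
#' @param ld_mode `"prune"` or `"literal_retain"`.
#' @return list with elements `gm` and `report`.
#' @export
ld_filter <- function(gm, r2_threshold = 0.95, ld_mode = c("prune", "literal_retain")) {
  stopifnot_gm(gm)
  if (r2_threshold < 0 || r2_threshold > 1)
    stop("r2_threshold must be in [0, 1]")
  ld_mode <- match.arg(ld_mode)
  m <- n_loci(gm)
  keep <- rep(TRUE, m)
  if (ld_mode == "prune") {
    for (chr in unique(gm$loci$chrom)) {
      idx <- which(gm$loci$chrom == chr)
      if (length(idx) < 2L) next
      last_kept <- idx[1L]
      for (k in idx[-1L]) {
        if (pair_r2(gm$calls[, last_kept], gm$calls[, k]) > r2_threshold)
          keep[k] <- FALSE
        else
          last_kept <- k
      }
    }
  } else {
    adj <- adjacent_r2(gm)
    hot <- adj[adj$r2 > r2_threshold, , drop = FALSE]
    keep <- seq_len(m) %in% c(hot$i, hot$j)
  }
  list(gm = subset_loci(gm, which(keep)),
       report = new_filter_report(paste0("ld_", ld_mode), gm, keep, "ld_r2"))
}

#' Filter configuration
#'
#' @param max_missing_fraction see [filter_by_missing()]. Default 0.01.
#' @param min_homozygote_count see [filter_by_homozygote_count()]. Default 2.
#' @param r2_threshold see [ld_filter()]. Default 0.95.
#' @param ld_mode see [ld_filter()]. Default `"prune"`.
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_missing_fraction = 0.01,
                          min_homozygote_count = 2,
                          r2_threshold = 0.95,
                          ld_mode = "prune") {
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must be in [0, 1]")
  if (min_homozygote_count < 0) stop("min_homozygote_count must be >= 0")
  if (r2_threshold < 0 || r2_threshold > 1)
    stop("r2_threshold must be in [0, 1]")
  if (!ld_mode %in% c("prune", "literal_retain"))
    stop("unknown ld_mode: ", ld_mode)
  structure(list(max_missing_fraction = max_missing_fraction,
                 min_homozygote_count = as.integer(min_homozygote_count),
                 r2_threshold = r2_threshold,
                 ld_mode = ld_mode),
            class = "filter_config")
}

#' Apply the full three-stage candidate SNP filter
#'
#' Stages compose in fixed order: missingness, then homozygote counts,
#' then adjacent-pair LD.
#'
#' @param gm a [genotype_matrix()].
#' @param config a [filter_config()].
#' @return list with elements `gm` (surviving loci) and `reports` (list of
#'   three `filter_report`s, in stage order).
#' @export
filter_snps <- function(gm, config = filter_config()) {
  s1 <- filter_by_missing(gm, config$max_missing_fraction)
  s2 <- filter_by_homozygote_count(s1$gm, config$min_homozygote_count)
  s3 <- ld_filter(s2$gm, config$r2_threshold, config$ld_mode)
  list(gm = s3$gm, reports = list(s1$report, s2$report, s3$report))
}

#' Serialize filter reports
#'
#' Writes a per-locus removal table (TSV: id, chrom, pos, stage, reason)
#' and a JSON per-stage summary.
#'
#' @param reports list of `filter_report`s from [filter_snps()].
#' @param tsv_path,json_path output paths; `NULL` skips that output.
#' @return the per-locus removal data.frame, invisibly.
#' @export
write_filter_report <- function(reports, tsv_path = NULL, json_path = NULL) {
  rows <- do.call(rbind, lapply(reports, function(r) {
    if (nrow(r$removed) == 0L)
      return(data.frame(id = character(0), chrom = character(0),
                        pos = integer(0), stage = character(0),
                        reason = character(0)))
    data.frame(id = r$removed$id, chrom = r$removed$chrom,
               pos = r$removed$pos, stage = r$stage,
               reason = r$removed$reason, stringsAsFactors = FALSE)
  }))
  if (!is.null(tsv_path))
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- lapply(reports, function(r)
      list(stage = r$stage, n_input = r$n_input,
           n_removed = r$n_removed, n_kept = r$n_kept))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(rows)
}
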