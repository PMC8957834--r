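#' Synthetic population configuration
#'
#' A stated world for testing the whole pipeline without external
#' accessions: a structured population of diploid biallelic genotypes with
#' subgroup-specific allele frequencies, configurable missingness and
#' duplicated adjacent loci (perfect LD) to exercise the LD filter.
#' Defaults mirror the end-to-end acceptance scenario: 200 samples, 1,000
#' loci on 12 chromosomes, 5 subgroups, Balding-Nichols divergence
#' F = 0.15, 1% missing calls, 10% duplicated adjacent pairs.
#'
#' @param n_samples number of samples. Default 200.
#' @param n_loci number of loci. Default 1000.
#' @param n_chromosomes loci are split evenly over this many chromosomes,
#'   positions 1000, 2000, ... within each. Default 12.
#' @param n_subgroups K, number of subpopulations (K <= n_samples).
#'   Default 5.
#' @param divergence Balding-Nichols F in `[0, 1)`: subgroup frequencies
#'   are Beta(p(1-F)/F, (1-p)(1-F)/F) draws around the ancestral
#'   frequency p; 0 means panmixia. Default 0.15.
#' @param missing_rate per-call missingness probability. Default 0.01.
#' @param dup_fraction fraction of loci duplicated into their right
#'   neighbour (`round(dup_fraction * n_loci)` adjacent perfect-LD pairs).
#'   Default 0.10.
#' @param rng_seed optional integer seed for reproducibility.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 200, n_loci = 1000, n_chromosomes = 12,
                       n_subgroups = 5, divergence = 0.15,
                       missing_rate = 0.01, dup_fraction = 0.10,
                       rng_seed = NULL) {
  if (n_samples < 1 || n_loci < 0) stop("invalid sizes")
  if (n_subgroups < 1 || n_subgroups > n_samples)
    stop("n_subgroups must be in [1, n_samples]")
  for (r in c(divergence, missing_rate, dup_fraction))
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 n_loci = as.integer(n_loci),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_subgroups = as.integer(n_subgroups),
                 divergence = divergence,
                 missing_rate = missing_rate,
                 dup_fraction = dup_fraction,
                 rng_seed = rng_seed),
            class = "sim_config")
}

#' Simulate a structured genotyped population
#'
#' Per locus, an ancestral reference-allele frequency is drawn uniformly
#' on `[0.05, 0.95]`; each subgroup's frequency is a Balding-Nichols
#' Beta perturbation controlled by `divergence`; genotypes are
#' binomial(2, 1 - p_subgroup) ALT-dosage draws. `round(dup_fraction *
#' n_loci)` loci are then copied into their right neighbour on the same
#' chromosome (adjacent perfect-LD pairs), and calls are masked missing
#' independently at `missing_rate`. Deterministic under `rng_seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] with attribute `"subgroup"` giving each
#'   sample's subpopulation label.
#' @export
simulate_population <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) stop("expected a `sim_config`")
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  n <- cfg$n_samples; m <- cfg$n_loci; K <- cfg$n_subgroups

  subgroup <- rep(seq_len(K), length.out = n)
  p_anc <- stats::runif(m, 0.05, 0.95)
  f <- cfg$divergence
  # subgroup frequencies: Balding-Nichols Beta around the ancestral p
  p_sub <- if (f > 0) {
    a <- p_anc * (1 - f) / f
    b <- (1 - p_anc) * (1 - f) / f
    vapply(seq_len(K), function(k) stats::rbeta(m, a, b), numeric(m))
  } else {
    matrix(p_anc, m, K)
  }
  if (m == 1L) p_sub <- matrix(p_sub, 1L, K)

  calls <- matrix(0L, n, m)
  for (i in seq_len(n))
    calls[i, ] <- stats::rbinom(m, 2L, 1 - p_sub[, subgroup[i]])

  # duplicated adjacent columns: perfect-LD pairs for the LD filter
  n_pairs <- as.integer(floor(cfg$dup_fraction * m + 0.5))
  per_chrom <- ceiling(m / cfg$n_chromosomes)
  chrom <- paste0("chr", ((seq_len(m) - 1L) %/% per_chrom) + 1L)
  pos <- (((seq_len(m) - 1L) %% per_chrom) + 1L) * 1000L
  if (n_pairs > 0L && m >= 2L) {
    eligible <- which(chrom[-m] == chrom[-1L])  # j, j+1 on one chromosome
    # disjoint pairs: take every other eligible index
    starts <- eligible[seq(1L, length(eligible), by = 2L)]
    starts <- starts[seq_len(min(n_pairs, length(starts)))]
    calls[, starts + 1L] <- calls[, starts, drop = FALSE]
  }

  if (cfg$missing_rate > 0)
    calls[matrix(stats::runif(n * m) < cfg$missing_rate, n, m)] <- NA_integer_

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  gm <- genotype_matrix(
    calls,
    samples = sprintf("S%03d", seq_len(n)),
    loci = data.frame(chrom = chrom, pos = pos,
                      id = paste0(chrom, "_", pos),
                      ref = ref, alt = alt, stringsAsFactors = FALSE))
  attr(gm, "subgroup") <- subgroup
  gm
}

#' Mask genotype calls as missing
#'
#' Each call is independently set missing with probability `rate`.
#'
#' @param gm a [genotype_matrix()].
#' @param rate missingness probability in `[0, 1]`.
#' @return the masked `genotype_matrix`.
#' @export
inject_missing <- function(gm, rate) {
  stopifnot_gm(gm)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (rate == 0) return(gm)
  mask <- matrix(stats::runif(length(gm$calls)) < rate,
                 nrow(gm$calls), ncol(gm$calls))
  gm$calls[mask] <- NA_integer_
  gm
}
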