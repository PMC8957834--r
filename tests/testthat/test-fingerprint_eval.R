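test_that("binary fingerprint uses the 1/2/0/- coding in panel order", {
  gm <- make_gm(c(0, 2, 1, NA))
  fp <- binary_fingerprint(gm, 1:4)
  expect_equal(fp$code, "120-")
  # panel order is respected, not genomic order
  expect_equal(binary_fingerprint(gm, c(3, 1))$code, "01")
  # empty panel -> empty string
  expect_equal(binary_fingerprint(gm, integer(0))$code, "")
})

test_that("fingerprints are pairwise distinct iff panel fitness is 1", {
  set.seed(21)
  for (rep in 1:10) {
    calls <- matrix(sample(c(0:2, NA), 5 * 6, replace = TRUE,
                           prob = c(.3, .3, .3, .1)), 5, 6)
    gm <- genotype_matrix(calls, paste0("S", 1:5),
                          data.frame(chrom = "chr1", pos = 1:6 * 10,
                                     id = paste0("L", 1:6)))
    enc <- encode_genotypes(gm)
    panel <- sort(sample(6, 3))
    codes <- binary_fingerprint(gm, panel)$code
    expect_equal(anyDuplicated(codes) == 0, fitness(enc, panel) == 1)
  }
})

test_that("pairwise differing-locus counts match per-position oracle", {
  gm <- make_gm(c(0, 1, 2), c(0, 2, NA))
  d <- pairwise_differing_loci(gm, 1:3)
  # positions: equal, differ, missing-excluded -> 1
  expect_equal(d[1, 2], 1L)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(S1 = 0L, S2 = 0L))
  # identical samples -> 0; all-different -> C
  gm2 <- make_gm(c(0, 1, 2), c(0, 1, 2), c(2, 0, 1))
  d2 <- pairwise_differing_loci(gm2, 1:3)
  expect_equal(d2[1, 2], 0L)
  expect_equal(d2[1, 3], 3L)
})

test_that("mismatch distance is differing / shared non-missing loci", {
  # 4 loci, one mismatch, one missing -> 1/3
  gm <- make_gm(c(0, 1, 2, 0), c(0, 1, 0, NA))
  d <- mismatch_distance_matrix(gm)
  expect_equal(d[1, 2], 1 / 3)
  expect_equal(diag(d), c(S1 = 0, S2 = 0))
  # identical -> 0; complementary homozygotes at all loci -> 1
  gm2 <- make_gm(c(0, 0, 2), c(0, 0, 2), c(2, 2, 0))
  d2 <- mismatch_distance_matrix(gm2)
  expect_equal(d2[1, 2], 0)
  expect_equal(d2[1, 3], 1)
  # no shared non-missing locus -> distance 1 with a warning
  gm3 <- make_gm(c(0, NA), c(NA, 1))
  expect_warning(d3 <- mismatch_distance_matrix(gm3), "no non-missing")
  expect_equal(d3[1, 2], 1)
  # symmetry / range on simulated data
  gm4 <- simulate_population(sim_config(30, 60, 2, 3, missing_rate = 0.05,
                                        dup_fraction = 0, rng_seed = 9))
  d4 <- mismatch_distance_matrix(gm4)
  expect_equal(d4, t(d4))
  expect_true(all(d4 >= 0 & d4 <= 1))
})

test_that("panel fit correlation is the upper-triangle Pearson statistic", {
  gm <- simulate_population(sim_config(25, 80, 2, 3, missing_rate = 0.02,
                                       dup_fraction = 0, rng_seed = 14))
  full <- mismatch_distance_matrix(gm)
  # full panel -> identical matrices -> exactly 1
  expect_equal(panel_fit_correlation(full, full), 1.0)
  panel <- sort(sample(80, 20))
  pdm <- mismatch_distance_matrix(gm, panel)
  r <- panel_fit_correlation(full, pdm)
  # independent oracle: vegan's Mantel statistic on the same matrices
  skip_if_not_installed("vegan")
  vr <- vegan::mantel(as.dist(full), as.dist(pdm), permutations = 0)
  expect_equal(as.numeric(r), as.numeric(vr$statistic), tolerance = 1e-12)
  # invariant to a common sample reordering
  p <- sample(25)
  expect_equal(panel_fit_correlation(full[p, p], pdm[p, p]), r)
  # degenerate constant triangle -> error
  con <- matrix(0.5, 4, 4); diag(con) <- 0
  expect_error(panel_fit_correlation(con, con), "degenerate")
})

test_that("shuffled panel distances decorrelate from the full matrix", {
  gm <- simulate_population(sim_config(25, 80, 2, 3, missing_rate = 0,
                                       dup_fraction = 0, rng_seed = 15))
  full <- mismatch_distance_matrix(gm)
  pdm <- mismatch_distance_matrix(gm, 1:20)
  set.seed(4)
  null_r <- replicate(50, {
    p <- sample(25)
    panel_fit_correlation(full, pdm[p, p])
  })
  expect_lt(abs(mean(null_r)), 0.1)
  r <- panel_fit_correlation(full, pdm, permutations = 99)
  expect_lt(attr(r, "p_value"), 0.05)
})

test_that("allele frequencies follow the diploid count formula", {
  gm <- do.call(make_gm, as.list(c(rep(0, 3), rep(1, 2), rep(2, 5))))
  expect_equal(unname(allele_frequencies(gm)), 8 / 20)
  expect_equal(unname(allele_frequencies(make_gm(c(0), c(0)))), 1)
  expect_equal(unname(allele_frequencies(make_gm(c(0), c(2)))), 0.5)
  expect_warning(p <- allele_frequencies(make_gm(c(NA), c(NA))), "no non-missing")
  expect_true(is.na(p))
})

test_that("PIC has the biallelic ceiling 0.375 at p = 0.5 and is symmetric", {
  expect_equal(pic(0.5), 0.375)
  expect_equal(pic(0), 0)
  expect_equal(pic(1), 0)
  p <- seq(0, 1, by = 0.01)
  expect_equal(pic(p), pic(1 - p))
  expect_true(all(pic(p) <= 0.375 + 1e-15))
  expect_equal(p[which.max(pic(p))], 0.5)
  expect_error(pic(1.2), "outside")
})

test_that("per-chromosome counts cover the panel and sum to C", {
  loci <- data.frame(chrom = rep(paste0("chr", 1:12), each = 10),
                     pos = rep(1:10, 12) * 100, id = paste0("L", 1:120))
  set.seed(6)
  panel <- sample(120, 100)
  counts <- per_chromosome_counts(panel, loci)
  expect_equal(sum(counts), 100L)
  expect_length(counts, 12L)
  one <- per_chromosome_counts(1:5, loci[1:10, ])
  expect_equal(sum(one), 5L)
  expect_equal(unname(one[1]), 5L)
})

test_that("evaluate_panel bundles the statistics coherently", {
  gm <- simulate_population(sim_config(20, 60, 3, 2, missing_rate = 0.02,
                                       dup_fraction = 0, rng_seed = 17))
  ev <- evaluate_panel(gm, 1:30)
  expect_equal(ev$panel_size, 30L)
  expect_true(ev$discrimination >= 0 && ev$discrimination <= 1)
  expect_equal(sum(ev$chrom_counts), 30L)
  expect_true(all(ev$pic <= 0.375 + 1e-15, na.rm = TRUE))
  expect_equal(mean(ev$pic, na.rm = TRUE), ev$mean_pic)
})
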