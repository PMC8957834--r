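test_that("initial population is P uniform random C-subsets, reproducible", {
  set.seed(99)
  pop <- init_population(50, 5, 10)
  expect_length(pop, 10L)
  for (p in pop) {
    expect_length(p, 5L)
    expect_false(anyDuplicated(p) > 0)
    expect_true(all(p >= 1 & p <= 50))
  }
  set.seed(99)
  expect_identical(pop, init_population(50, 5, 10))
  # C = m forces the full locus set
  expect_setequal(init_population(4, 4, 3)[[1]], 1:4)
  expect_error(init_population(4, 5, 3), "exceeds")
})

test_that("profiles are ordered tuples, not sums", {
  enc <- encode_genotypes(make_gm(c(0, 2), c(2, 0), c(0, 2)))
  # samples 1 and 3 share (97,98); sample 2 has (98,97): a sum would
  # collapse all three to 195
  prof <- assemble_profiles(enc, c(1, 2))
  expect_equal(prof[1], prof[3])
  expect_false(prof[1] == prof[2])
})

test_that("fitness counts uniquely identified samples", {
  # profiles (97),(97),(98): only the third is unique
  enc <- encode_genotypes(make_gm(c(0), c(0), c(2)))
  expect_equal(fitness(enc, 1), 1 / 3)
  # pairwise distinct -> 1; all identical -> 0
  enc2 <- encode_genotypes(make_gm(c(0), c(1), c(2)))
  expect_equal(fitness(enc2, 1), 1.0)
  enc3 <- encode_genotypes(make_gm(c(1), c(1), c(1)))
  expect_equal(fitness(enc3, 1), 0)
})

test_that("missing-wildcard fitness treats missing as compatible", {
  # samples differ only by missingness: distinguished by default,
  # not under the wildcard semantics
  enc <- encode_genotypes(make_gm(c(0, NA), c(0, 2)))
  expect_equal(fitness(enc, 1:2), 1.0)
  expect_equal(fitness(enc, 1:2, missing_wildcard = TRUE), 0)
})

test_that("linear ranking follows the stated line and sums to Nind", {
  expect_equal(rank_fitness_linear(5, 1), rep(1, 5))
  expect_equal(rank_fitness_linear(3, 2), c(0, 1, 2))
  for (sp in c(1, 1.3, 1.7, 2)) for (n in c(2, 7, 50))
    expect_equal(sum(rank_fitness_linear(n, sp)), n, tolerance = 1e-12)
  expect_error(rank_fitness_linear(5, 2.5), "sp")
})

test_that("nonlinear ranking is the normalized geometric weighting", {
  expect_equal(rank_fitness_nonlinear(5, 1), rep(1, 5))
  expect_equal(rank_fitness_nonlinear(3, 2), c(3 / 7, 6 / 7, 12 / 7))
  for (b in c(0.5, 2, 4)) for (n in c(2, 7, 50))
    expect_equal(sum(rank_fitness_nonlinear(n, b)), n, tolerance = 1e-12)
  expect_error(rank_fitness_nonlinear(5, 0), "base")
})

test_that("selection probabilities normalize fitness, uniform when all zero", {
  expect_equal(selection_probabilities(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(selection_probabilities(c(0, 0)), c(0.5, 0.5))
  set.seed(2)
  for (i in 1:20) {
    f <- runif(10)
    p <- selection_probabilities(f)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(order(p), order(f))  # monotone in raw fitness
  }
  expect_error(selection_probabilities(c(-1, 2)), "negative")
})

test_that("roulette pick lands in the cumulative interval", {
  expect_equal(roulette_pick(1, r = 0.7), 1L)
  expect_equal(roulette_pick(c(0.5, 0.5), r = 0.25), 1L)
  expect_equal(roulette_pick(c(0.5, 0.5), r = 0.75), 2L)
  # empirical frequencies within 3 binomial standard errors
  set.seed(31)
  probs <- c(0.2, 0.3, 0.5)
  draws <- replicate(10000, roulette_pick(probs))
  freq <- tabulate(draws, 3) / 10000
  se <- sqrt(probs * (1 - probs) / 10000)
  expect_true(all(abs(freq - probs) <= 3 * se))
})

test_that("crossover swaps tails and repairs duplicates from absent loci", {
  ch <- crossover(c(1L, 2L, 3L), c(4L, 5L, 6L), m_loci = 10, b1 = 2)
  expect_equal(ch, list(c(1L, 2L, 6L), c(4L, 5L, 3L)))
  # duplicate after the swap is replaced by the smallest absent locus
  ch <- crossover(c(1L, 2L, 3L), c(3L, 4L, 5L), m_loci = 6, b1 = 2)
  expect_equal(ch[[1]], c(1L, 2L, 5L))
  expect_equal(ch[[2]], c(3L, 4L, 1L))
  # probability 0 -> children are the parents
  set.seed(5)
  expect_equal(crossover(c(1L, 2L, 3L), c(4L, 5L, 6L), 10,
                         crossover_probability = 0),
               list(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  # C = 1: no valid crossover point
  expect_equal(crossover(2L, 5L, 10), list(2L, 5L))
})

test_that("mutation replaces round(0.3 C) positions with absent loci", {
  set.seed(8)
  p <- 1:10 * 2L  # evens over 1..25
  out <- mutate(p, m_loci = 25, mutation_probability = 1,
                mutation_fraction = 0.3)
  expect_equal(sum(out != p), 3L)  # exactly round(0.3*10) positions
  expect_false(anyDuplicated(out) > 0)
  expect_true(all(out[out != p] %% 2 == 1))  # replacements were absent

  # C=3, fraction 0.3 -> round(0.9) = 1 position
  out <- mutate(c(1L, 2L, 3L), 10, 1, 0.3, positions = 2)
  expect_equal(sum(out != c(1, 2, 3)), 1L)
  # position value indexes the ascending absent list: absent = 4..10
  expect_equal(out, c(1L, 5L, 3L))
  # probability 0 -> unchanged
  expect_equal(mutate(c(1L, 2L, 3L), 10, mutation_probability = 0), 1:3)
  # C close to M: only as many positions as absent loci
  out <- mutate(1:9, m_loci = 10, 1, 1)
  expect_equal(sum(out != 1:9), 1L)
  expect_true(10L %in% out)
})

test_that("merge keeps size P, dedups panel sets, never loses the best", {
  enc <- small_enc()
  parents <- list(members = list(c(1L, 2L), c(3L, 4L), c(2L, 1L)),
                  fitness = c(0.9, 0.5, 0.9))
  offspring <- list(members = list(c(1L, 2L), c(5L, 6L)),
                    fitness = c(0.9, 0.7))
  set.seed(1)
  merged <- merge_and_truncate(parents, offspring, P = 3, enc)
  expect_length(merged$members, 3L)
  expect_equal(max(merged$fitness), 0.9)
  keys <- sapply(merged$members, function(p) paste(sort(p), collapse = ","))
  expect_false(anyDuplicated(keys) > 0)  # {1,2} and {2,1} collapse
  expect_true(all(c("1,2", "3,4", "5,6") %in% keys))

  # all-duplicate pool refills with fresh random panels up to P
  dup <- list(members = list(c(1L, 2L), c(1L, 2L)), fitness = c(0.4, 0.4))
  merged <- merge_and_truncate(dup, dup, P = 4, enc)
  expect_length(merged$members, 4L)
})

test_that("GA invariants hold along a run and the result is deterministic", {
  enc <- small_enc()
  cfg <- ga_config(panel_size = 4, population_size = 12,
                   max_iterations = 30, stall_generations = Inf,
                   rng_seed = 77)
  res <- run_ga(enc, cfg)
  expect_equal(nrow(res$trace), 30L)
  expect_true(all(diff(res$trace$best) >= 0))  # elitist: non-decreasing
  expect_length(res$population, 12L)
  for (p in res$population) {
    expect_length(p, 4L)
    expect_false(anyDuplicated(p) > 0)
    expect_true(all(p >= 1 & p <= ncol(enc)))
  }
  expect_true(all(res$fitness >= 0 & res$fitness <= 1))
  expect_equal(res$fitness, sort(res$fitness, decreasing = TRUE))
  # bit-identical rerun under the same seed
  expect_identical(res, run_ga(enc, cfg))
})

test_that("a single separating locus is found at C = 1", {
  # locus 3 alone separates all samples
  enc <- encode_genotypes(make_gm(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2),
                                  c(0, 0, NA)))
  res <- run_ga(enc, ga_config(panel_size = 1, population_size = 4,
                               max_iterations = 20, stall_generations = 2,
                               rng_seed = 3))
  expect_equal(res$chosen_fitness, 1.0)
  expect_equal(res$chosen, 3L)
})

test_that("brute force agrees with fitness() and guards huge enumerations", {
  enc <- small_enc(n = 6, m = 8, seed = 13)
  bf <- brute_force_best_panel(enc, 2)
  fits <- apply(combn(8, 2), 2, function(p) fitness(enc, p))
  expect_equal(bf$fitness, max(fits))
  # lexicographically smallest argmax
  first <- which(fits == max(fits))[1]
  expect_equal(bf$panel, combn(8, 2)[, first])
  # M = C: the only panel
  expect_equal(brute_force_best_panel(enc, 8)$panel, 1:8)
  expect_error(brute_force_best_panel(enc, 4, guard = 10), "guard")
})

test_that("chromosome-spread tie-break prefers the most even panel", {
  loci <- data.frame(chrom = rep(c("chr1", "chr2"), each = 4),
                     pos = rep(1:4, 2) * 100,
                     id = paste0("L", 1:8))
  lump <- c(1L, 2L, 3L, 4L)      # per-chrom counts (4, 0)
  spread <- c(1L, 2L, 5L, 6L)    # per-chrom counts (2, 2)
  expect_equal(chromosome_spread_tiebreak(list(lump, spread), loci), spread)
  expect_equal(chromosome_spread_tiebreak(list(lump), loci), lump)
  # exact spread tie -> lexicographically smaller panel
  a <- c(1L, 2L, 5L, 6L); b <- c(1L, 3L, 5L, 6L)
  expect_equal(chromosome_spread_tiebreak(list(b, a), loci), a)
  expect_error(chromosome_spread_tiebreak(list(), loci), "empty")
})
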