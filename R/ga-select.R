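#' Genetic-algorithm configuration
#'
#' Parameters of the panel-selection GA. An individual ("panel") is an
#' ordered set of `panel_size` distinct locus indices; raw fitness is the
#' fraction of samples whose panel genotype profile is unique in the
#' population. Defaults follow the published method where it states them
#' (panel size 100, 0.3*C mutation bits, rank selection pressure in
#' [1.0, 2.0]) and classical GA practice where it is silent (crossover
#' probability 0.8, mutation probability 0.1).
#'
#' @param panel_size C, number of loci per panel. Default 100.
#' @param population_size P, number of panels per generation. Default 100.
#' @param max_iterations X, number of generations. Default 500.
#' @param crossover_probability per-pair probability of single-point
#'   crossover. Default 0.8.
#' @param mutation_probability per-offspring probability that mutation is
#'   applied. Default 0.1.
#' @param mutation_fraction fraction of panel positions mutated when
#'   mutation fires (rounded half away from zero). Default 0.3.
#' @param ranking fitness transform before roulette selection: `"none"`
#'   (raw fitness, default), `"linear"` or `"nonlinear"` rank-based values.
#' @param sp selection pressure for linear ranking, in `[1.0, 2.0]`.
#' @param nonlinear_base base of the geometric weights for nonlinear
#'   ranking, > 0.
#' @param stall_generations early stop: terminate once best fitness has sat
#'   at 1.0 for this many consecutive generations. Default 50. `Inf`
#'   disables early stopping.
#' @param rng_seed optional integer seed; fixing it makes [run_ga()]
#'   bit-reproducible.
#' @return a `ga_config` list.
#' @export
ga_config <- function(panel_size = 100,
                      population_size = 100,
                      max_iterations = 500,
                      crossover_probability = 0.8,
                      mutation_probability = 0.1,
                      mutation_fraction = 0.3,
                      ranking = c("none", "linear", "nonlinear"),
                      sp = 2,
                      nonlinear_base = 2,
                      stall_generations = 50,
                      rng_seed = NULL) {
  ranking <- match.arg(ranking)
  if (panel_size < 1) stop("panel_size must be >= 1")
  if (population_size < 2) stop("population_size must be >= 2")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  for (p in c(crossover_probability, mutation_probability, mutation_fraction))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  if (sp < 1 || sp > 2) stop("sp must be in [1.0, 2.0]")
  if (nonlinear_base <= 0) stop("nonlinear_base must be > 0")
  structure(list(panel_size = as.integer(panel_size),
                 population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 crossover_probability = crossover_probability,
                 mutation_probability = mutation_probability,
                 mutation_fraction = mutation_fraction,
                 ranking = ranking, sp = sp,
                 nonlinear_base = nonlinear_base,
                 stall_generations = stall_generations,
                 rng_seed = rng_seed),
            class = "ga_config")
}

check_panel <- function(panel, m_loci, C = length(panel)) {
  panel <- as.integer(panel)
  if (length(panel) != C || anyDuplicated(panel) ||
      (length(panel) && (min(panel) < 1L || max(panel) > m_loci)))
    stop("invalid panel: need ", C, " distinct indices in [1, ", m_loci, "]")
  panel
}

#' Initial GA population
#'
#' Each panel is a uniform random `C`-subset of the locus indices, drawn
#' without replacement.
#'
#' @param m_loci number of candidate loci.
#' @param C panel size.
#' @param P population size.
#' @return list of `P` integer vectors of length `C`.
#' @export
init_population <- function(m_loci, C, P) {
  if (C > m_loci) stop("panel_size C exceeds number of loci")
  lapply(seq_len(P), function(i) sample.int(m_loci, C))
}

#' Per-sample panel genotype profiles
#'
#' The profile of a sample is the *ordered tuple* of its encoded genotype
#' codes at the panel loci, realized as a collapsed key string. Tuples, not
#' sums: summing codes would collapse distinct profiles (97 + 104 and
#' 98 + 103 and permutations become indistinguishable), defeating the
#' uniqueness count the fitness is built on.
#'
#' @param enc an `encoded_matrix` from [encode_genotypes()].
#' @param panel integer vector of locus indices.
#' @return character vector of profile keys, one per sample.
#' @export
assemble_profiles <- function(enc, panel) {
  panel <- check_panel(panel, ncol(enc))
  sub <- unclass(enc)[, panel, drop = FALSE]
  if (ncol(sub) == 0L) return(rep("", nrow(sub)))
  do.call(paste, c(as.data.frame(sub), sep = ","))
}

#' Panel fitness: fraction of uniquely identified samples
#'
#' F = U / N where U counts samples whose panel profile occurs exactly once
#' among all N samples. F = 1 iff the panel separates every sample.
#' Missing genotypes are ordinary profile symbols unless
#' `missing_wildcard = TRUE`, in which case a sample only counts as unique
#' if no other sample is compatible with it at every panel locus (missing
#' matches anything).
#'
#' @param enc an `encoded_matrix`.
#' @param panel integer vector of locus indices.
#' @param missing_wildcard treat missing calls as matching any genotype.
#'   Default `FALSE`.
#' @return fitness in `[0, 1]`.
#' @export
fitness <- function(enc, panel, missing_wildcard = FALSE) {
  if (!missing_wildcard) {
    prof <- assemble_profiles(enc, panel)
    counts <- table(prof)
    return(sum(counts[prof] == 1L) / length(prof))
  }
  panel <- check_panel(panel, ncol(enc))
  sub <- unclass(enc)[, panel, drop = FALSE]
  n <- nrow(sub)
  unique_flags <- vapply(seq_len(n), function(i) {
    for (j in seq_len(n)) {
      if (j == i) next
      diff <- sub[i, ] != sub[j, ] & sub[i, ] != 45L & sub[j, ] != 45L
      if (!any(diff)) return(FALSE)
    }
    TRUE
  }, logical(1))
  mean(unique_flags)
}

#' Linear ranking fitness values
#'
#' Rank-based fitness for a population sorted ascending by raw fitness
#' (position `n_ind` is the best):
#' `FitnV(pos) = 2 - sp + 2 (sp - 1) (pos - 1) / (Nind - 1)`.
#' The values always sum to `n_ind`; `sp = 1` gives uniform values,
#' `sp = 2` maximal selection pressure.
#'
#' @param n_ind population size, >= 2.
#' @param sp selection pressure, in `[1.0, 2.0]`.
#' @return numeric vector of length `n_ind`, ascending.
#' @export
rank_fitness_linear <- function(n_ind, sp) {
  if (sp < 1 || sp > 2) stop("sp must be in [1.0, 2.0]")
  if (n_ind < 2) stop("n_ind must be >= 2")
  pos <- seq_len(n_ind)
  2 - sp + 2 * (sp - 1) * (pos - 1) / (n_ind - 1)
}

#' Nonlinear (geometric) ranking fitness values
#'
#' `FintV(pos) = Nind * base^(pos-1) / sum_i base^(i-1)`; values sum to
#' `n_ind` by construction. `base = 1` gives uniform values, larger bases
#' steeper selection pressure.
#'
#' @param n_ind population size, >= 2.
#' @param base geometric base, > 0.
#' @return numeric vector of length `n_ind`, ascending when `base > 1`.
#' @export
rank_fitness_nonlinear <- function(n_ind, base) {
  if (base <= 0) stop("base must be > 0")
  if (n_ind < 2) stop("n_ind must be >= 2")
  w <- base^(seq_len(n_ind) - 1)
  n_ind * w / sum(w)
}

#' Selection probabilities from fitness values
#'
#' `O(i) = F(i) / sum(F)`; an all-zero fitness vector yields uniform
#' probabilities so selection still proceeds.
#'
#' @param fitness_values non-negative numeric vector.
#' @return probability vector summing to 1.
#' @export
selection_probabilities <- function(fitness_values) {
  if (any(fitness_values < 0)) stop("negative fitness")
  s <- sum(fitness_values)
  if (s == 0) return(rep(1 / length(fitness_values), length(fitness_values)))
  fitness_values / s
}

#' Roulette-wheel pick
#'
#' Draws R uniform on (0, 1) and returns the index whose cumulative
#' probability interval contains R.
#'
#' @param probabilities probability vector summing to 1.
#' @param r optional pre-drawn uniform deviate (used by tests to inject a
#'   fixed R); default draws from the session RNG.
#' @return a member index in `1..length(probabilities)`.
#' @export
roulette_pick <- function(probabilities, r = stats::runif(1)) {
  cum <- cumsum(probabilities)
  idx <- findInterval(r, cum, left.open = TRUE) + 1L
  min(idx, length(probabilities))
}

# replace second-and-later occurrences of any locus by the smallest absent
# loci, in ascending order
repair_duplicates <- function(panel, m_loci) {
  dup <- which(duplicated(panel))
  if (length(dup) == 0L) return(panel)
  absent <- setdiff(seq_len(m_loci), panel)
  panel[dup] <- absent[seq_along(dup)]
  panel
}

#' Single-point crossover of two panels
#'
#' With probability `crossover_probability`, a crossover bit B1 is drawn
#' uniformly from `[1, C-1]` and the tails (positions B1+1..C) of the two
#' parents are swapped. A locus duplicated within a child by the swap is
#' replaced by the smallest-index locus absent from that child, in
#' ascending order, so children always hold C distinct loci. Otherwise the
#' children are the unchanged parents. `C = 1` has no valid crossover
#' point; children are the parents.
#'
#' @param a,b parent panels (integer vectors of equal length C over
#'   `1..m_loci`).
#' @param m_loci size of the locus universe (replacement pool for repair).
#' @param crossover_probability probability the crossover fires. Default 0.8.
#' @param b1 optional injected crossover bit (tests); drawn uniformly from
#'   `1..C-1` when `NULL`.
#' @return list of two child panels.
#' @export
crossover <- function(a, b, m_loci, crossover_probability = 0.8, b1 = NULL) {
  C <- length(a)
  a <- check_panel(a, m_loci)
  b <- check_panel(b, m_loci, C)
  if (C < 2L) return(list(a, b))
  fire <- is.null(b1)  # injected b1 forces the crossover (deterministic test path)
  if (fire && stats::runif(1) >= crossover_probability) return(list(a, b))
  if (is.null(b1)) b1 <- sample.int(C - 1L, 1L)
  if (b1 < 1L || b1 > C - 1L) stop("crossover bit out of [1, C-1]")
  tail_idx <- (b1 + 1L):C
  c1 <- a; c2 <- b
  c1[tail_idx] <- b[tail_idx]
  c2[tail_idx] <- a[tail_idx]
  list(repair_duplicates(c1, m_loci), repair_duplicates(c2, m_loci))
}

#' Mutate a panel
#'
#' With probability `mutation_probability`, `round(mutation_fraction * C)`
#' distinct positions (rounding half away from zero) are drawn uniformly
#' from `[1, C]` and emptied; each emptied position `p` is refilled with
#' the `p`-th entry of the ascending list of loci absent from the panel
#' (its position value indexes the absent list). When fewer absent loci
#' exist than mutation bits (C close to M), only as many positions as
#' available absent loci are mutated, refilled with the smallest absent
#' loci in ascending order.
#'
#' @param panel integer vector of length C over `1..m_loci`.
#' @param m_loci size of the locus universe.
#' @param mutation_probability probability mutation fires. Default 0.1.
#' @param mutation_fraction fraction of positions mutated. Default 0.3.
#' @param positions optional injected mutation positions (tests); drawn
#'   when `NULL`.
#' @return mutated panel (C distinct in-range loci).
#' @export
mutate <- function(panel, m_loci, mutation_probability = 0.1,
                   mutation_fraction = 0.3, positions = NULL) {
  C <- length(panel)
  panel <- check_panel(panel, m_loci)
  fire <- is.null(positions)
  if (fire && stats::runif(1) >= mutation_probability) return(panel)
  n_mut <- as.integer(floor(mutation_fraction * C + 0.5))  # half away from zero
  if (n_mut == 0L) return(panel)
  if (is.null(positions)) positions <- sort(sample.int(C, n_mut))
  positions <- sort(unique(as.integer(positions)))
  absent <- setdiff(seq_len(m_loci), panel)  # already ascending
  if (length(absent) == 0L) return(panel)
  if (length(absent) >= C) {
    panel[positions] <- absent[positions]
  } else {
    k <- min(length(absent), length(positions))
    panel[positions[seq_len(k)]] <- absent[seq_len(k)]
  }
  panel
}

panel_key <- function(panel) paste(sort.int(panel), collapse = ",")

#' Merge parents and offspring, deduplicate, truncate to P
#'
#' Elitist replacement: parents and offspring are pooled, duplicate panels
#' (identical locus *sets*) are discarded, the pool is sorted by fitness
#' descending (stable) and the top P survive. If deduplication leaves
#' fewer than P panels, fresh random panels are drawn (and evaluated) to
#' refill, so population size is exactly P after every generation.
#'
#' @param parents,offspring lists with elements `members` (list of panels)
#'   and `fitness` (numeric vector).
#' @param P target population size.
#' @param enc `encoded_matrix`, needed to evaluate refill panels.
#' @param missing_wildcard passed to [fitness()] for refills.
#' @return list with `members` and `fitness`, both of length exactly P.
#' @export
merge_and_truncate <- function(parents, offspring, P, enc,
                               missing_wildcard = FALSE) {
  members <- c(parents$members, offspring$members)
  fit <- c(parents$fitness, offspring$fitness)
  ord <- order(-fit)  # stable: ties keep pool order (parents first)
  members <- members[ord]; fit <- fit[ord]
  keys <- vapply(members, panel_key, character(1))
  keep <- !duplicated(keys)
  members <- members[keep]; fit <- fit[keep]; keys <- keys[keep]
  if (length(members) > P) {
    members <- members[seq_len(P)]
    fit <- fit[seq_len(P)]
  }
  C <- length(members[[1L]])
  m_loci <- ncol(enc)
  guard <- 0L
  while (length(members) < P && guard < 50L * P) {
    cand <- sample.int(m_loci, C)
    k <- panel_key(cand)
    if (!k %in% keys) {
      members <- c(members, list(cand))
      fit <- c(fit, fitness(enc, cand, missing_wildcard))
      keys <- c(keys, k)
    }
    guard <- guard + 1L
  }
  # distinct-panel space exhausted (choose(m, C) < P): pad with duplicates
  # of random members so the population size stays exactly P
  while (length(members) < P) {
    i <- sample.int(length(members), 1L)
    members <- c(members, members[i])
    fit <- c(fit, fit[i])
  }
  list(members = members, fitness = fit)
}

#' Run the panel-selection genetic algorithm
#'
#' Searches for a panel of `C` loci maximizing the fraction of uniquely
#' identifiable samples. Per generation: selection probabilities are
#' computed from (optionally rank-transformed) fitness, P offspring are
#' bred by roulette parent picks, single-point crossover and mutation,
#' then parents and offspring are pooled, deduplicated and truncated back
#' to P by fitness (elitism), so the best fitness never decreases. Stops
#' after `max_iterations` generations, or earlier once best fitness has
#' held at 1.0 for `stall_generations` generations.
#'
#' @param enc `encoded_matrix` of the filtered candidate loci.
#' @param config a [ga_config()].
#' @param missing_wildcard passed to [fitness()]. Default `FALSE`.
#' @return a `ga_result` list: `population` (panels ranked by fitness
#'   descending), `fitness` (matching vector), `trace` (data.frame
#'   generation / best / mean), `best_panels` (per-generation best panel),
#'   `chosen` (best-fitness panel after the chromosome-spread tie-break),
#'   `chosen_fitness`, `config`.
#' @export
run_ga <- function(enc, config = ga_config(), missing_wildcard = FALSE) {
  if (!inherits(enc, "encoded_matrix")) stop("expected an `encoded_matrix`")
  cfg <- config
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  m_loci <- ncol(enc)
  C <- cfg$panel_size
  P <- cfg$population_size
  if (C > m_loci) stop("panel_size C exceeds number of candidate loci")

  members <- init_population(m_loci, C, P)
  fit <- vapply(members, function(p) fitness(enc, p, missing_wildcard),
                numeric(1))
  pop <- list(members = members, fitness = fit)

  trace_best <- numeric(0)
  trace_mean <- numeric(0)
  best_panels <- list()
  stall <- 0L

  for (gen in seq_len(cfg$max_iterations)) {
    sel_fit <- pop$fitness
    if (cfg$ranking != "none") {
      # rank transform: population sorted ascending by raw fitness,
      # position Nind (the best) receives the largest ranked value
      ord <- order(sel_fit)
      ranked <- if (cfg$ranking == "linear")
        rank_fitness_linear(P, cfg$sp)
      else
        rank_fitness_nonlinear(P, cfg$nonlinear_base)
      sel_fit <- numeric(P)
      sel_fit[ord] <- ranked
    }
    probs <- selection_probabilities(sel_fit)

    kids <- vector("list", P)
    k <- 0L
    while (k < P) {
      i <- roulette_pick(probs)
      j <- roulette_pick(probs)
      ch <- crossover(pop$members[[i]], pop$members[[j]], m_loci,
                      cfg$crossover_probability)
      ch[[1L]] <- mutate(ch[[1L]], m_loci, cfg$mutation_probability,
                         cfg$mutation_fraction)
      kids[[k + 1L]] <- ch[[1L]]
      if (k + 2L <= P) {
        ch[[2L]] <- mutate(ch[[2L]], m_loci, cfg$mutation_probability,
                           cfg$mutation_fraction)
        kids[[k + 2L]] <- ch[[2L]]
      }
      k <- k + 2L
    }
    kid_fit <- vapply(kids, function(p) fitness(enc, p, missing_wildcard),
                      numeric(1))
    pop <- merge_and_truncate(pop, list(members = kids, fitness = kid_fit),
                              P, enc, missing_wildcard)

    best_i <- which.max(pop$fitness)
    trace_best <- c(trace_best, pop$fitness[best_i])
    trace_mean <- c(trace_mean, mean(pop$fitness))
    best_panels[[gen]] <- pop$members[[best_i]]

    stall <- if (pop$fitness[best_i] >= 1) stall + 1L else 0L
    if (stall >= cfg$stall_generations) break
  }

  ord <- order(-pop$fitness)
  population <- pop$members[ord]
  fit <- pop$fitness[ord]
  top <- which(fit == fit[1L])
  chosen <- chromosome_spread_tiebreak(population[top], attr(enc, "loci"))

  structure(list(population = population,
                 fitness = fit,
                 trace = data.frame(generation = seq_along(trace_best),
                                    best = trace_best, mean = trace_mean),
                 best_panels = best_panels,
                 chosen = chosen,
                 chosen_fitness = fit[1L],
                 config = cfg),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result: %d generations, best fitness %.4f, panel size %d\n",
              nrow(x$trace), x$chosen_fitness, length(x$chosen)))
  invisible(x)
}

#' Exhaustive best panel (test oracle)
#'
#' Enumerates every C-subset of the loci and returns the
#' lexicographically-smallest subset attaining maximal fitness. Refuses
#' instances with more than `guard` subsets.
#'
#' @param enc `encoded_matrix`.
#' @param C panel size.
#' @param missing_wildcard passed to [fitness()].
#' @param guard maximum number of subsets to enumerate. Default 1e6.
#' @return list with `panel` and `fitness`.
#' @export
brute_force_best_panel <- function(enc, C, missing_wildcard = FALSE,
                                   guard = 1e6) {
  m <- ncol(enc)
  if (choose(m, C) > guard)
    stop("choose(", m, ", ", C, ") exceeds enumeration guard ", guard)
  best_fit <- -1
  best_panel <- NULL
  apply(utils::combn(m, C), 2, function(panel) {
    f <- fitness(enc, panel, missing_wildcard)
    if (f > best_fit) {  # first max in combn order = lexicographically smallest
      best_fit <<- f
      best_panel <<- panel
    }
    invisible(NULL)
  })
  list(panel = as.integer(best_panel), fitness = best_fit)
}

#' Chromosome-spread tie-break among equally fit panels
#'
#' Among candidate panels sharing maximal fitness, prefers the one whose
#' loci spread most evenly over chromosomes: minimal maximum
#' per-chromosome locus count, remaining ties broken by lexicographic
#' order of the sorted locus indices.
#'
#' @param candidates non-empty list of panels.
#' @param loci locus metadata data.frame with a `chrom` column (as stored
#'   in a `genotype_matrix` / attached to an `encoded_matrix`).
#' @return the winning panel.
#' @export
chromosome_spread_tiebreak <- function(candidates, loci) {
  if (length(candidates) == 0L) stop("empty candidate list")
  if (length(candidates) == 1L) return(candidates[[1L]])
  score <- vapply(candidates, function(p)
    max(table(loci$chrom[p])), numeric(1))
  best <- which(score == min(score))
  if (length(best) == 1L) return(candidates[[best]])
  keys <- vapply(candidates[best], function(p)
    paste(formatC(sort.int(p), width = 12, flag = "0"), collapse = ","),
    character(1))
  candidates[[best[order(keys)[1L]]]]
}
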