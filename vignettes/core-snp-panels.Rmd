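---
title: "Selecting core SNP panels for DNA fingerprinting with a genetic algorithm"
author: "corepanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting core SNP panels for DNA fingerprinting with a genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corepanel)
```

## The problem

Variety identification in crops and livestock needs a *small*, assayable
set of markers whose joint genotypes distinguish every accession in a
collection. Genome-wide resequencing yields millions of SNPs — far too
many to genotype routinely — but the discriminating information is highly
redundant. The task is combinatorial: among M filtered candidate SNPs,
find a panel of C loci (C = 100 by default) such that no two samples share
the same C-locus genotype profile. Exhaustive search over
$\binom{M}{C}$ subsets is hopeless at realistic sizes, so the package
searches with a genetic algorithm (GA) over locus subsets.

## The model and procedure

**Genotype states.** Calls are diploid biallelic: 0/0, 0/1, 1/1 or
missing (./.), stored as ALT dosage 0/1/2/NA. Inside the GA the four
states are mapped to the integer alphabet
$\{./.\!\to\!45,\ 0/0\!\to\!97,\ 1/1\!\to\!98,\ 0/1\!\to\!104\}$
(`encode_genotypes()`), a bijection whose inverse is
`decode_genotypes()`.

**Candidate filtering** (`filter_snps()`), in fixed order:

1. *Missingness*: a locus is removed iff its missing-call fraction
   strictly exceeds `max_missing_fraction` (default 0.01).
2. *Homozygote counts*: a locus must carry at least
   `min_homozygote_count` (default 2) calls of **each** homozygote class
   (0/0 and 1/1); near-monomorphic and all-heterozygous loci are removed.
3. *Adjacent-pair LD*: dosage $r^2$ is computed for consecutive loci
   within each chromosome over pairwise-complete samples. The default
   mode `"prune"` removes the downstream member of each pair with
   $r^2 > 0.95$, sweeping left to right so runs of redundant loci
   collapse to their first member. The alternative `"literal_retain"`
   mode keeps *only* loci belonging to a high-$r^2$ pair — the source
   method's wording taken literally, which inverts standard pruning; it
   is preserved as an option but not the default, since retaining
   redundant loci and discarding independent ones runs against the goal
   of an informative panel.

**Fitness.** A panel's raw fitness is $F = U/N$, where $U$ counts samples
whose panel genotype profile occurs exactly once among the $N$ samples.
Profiles are *ordered tuples* of encoded codes, never their sum: a sum
such as $\sum_k S(G(i,k),j)$ collapses distinct profiles (97 + 104 =
104 + 97 across positions, and different code multisets can tie), which
would silently overstate uniqueness. $F = 1$ exactly when the panel
separates every sample.

**Selection.** Either raw fitness or a rank transform feeds
roulette-wheel selection ($O_i = F_i/\sum F$, cumulative intervals on
$(0,1)$). Two transforms are available: linear ranking
$FitnV(pos) = 2 - sp + 2(sp-1)\frac{pos-1}{N_{ind}-1}$ with selection
pressure $sp \in [1, 2]$, and nonlinear (geometric) ranking
$FintV(pos) = N_{ind}\,X^{pos-1} / \sum_i X^{i-1}$ with base $X > 0$;
both sum to $N_{ind}$ by construction. The source method presents raw
fitness selection and the ranking transforms without stating which the
published runs used, so ranking is exposed as a configuration choice
(`ranking = "none"` by default) rather than guessed.

**Crossover.** With probability `crossover_probability` (default 0.8; the
source does not state a value, this is classical GA practice), a cut
point $B_1$ is drawn uniformly from $[1, C-1]$ and the two parents swap
tails. A locus duplicated within a child is repaired by substituting the
smallest-index locus absent from that child, ascending — a deterministic
repair given the cut, so runs are reproducible.

**Mutation.** With probability `mutation_probability` (default 0.1,
again classical practice), $\mathrm{round}(0.3\,C)$ distinct positions
(rounding half away from zero; base R's banker's rounding is *not* used)
are drawn and refilled from the ascending list of loci absent from the
panel, each position's value indexing that list. When fewer absent loci
exist than mutation bits (C close to M), only as many positions as
available loci mutate.

**Replacement.** Parents and offspring are pooled, duplicate panels —
identical locus *sets*, the only reading of "discarding repeated
genotypes" consistent with a constant population size — are dropped, and
the top P by fitness survive (elitism), refilled with fresh random
panels if deduplication leaves fewer than P. Best fitness is therefore
non-decreasing across generations, which the result trace records and
tests assert.

**Termination and tie-break.** The GA runs `max_iterations` generations
(default 500), stopping early once best fitness has held at 1.0 for
`stall_generations` (default 50) generations. Among final panels sharing
maximal fitness, `chromosome_spread_tiebreak()` prefers the most even
chromosome distribution (minimal maximum per-chromosome locus count),
then lexicographic order — mirroring the practice of choosing the
combination best spread over the genome.

**Fingerprint codes.** The chosen panel converts to per-sample code
strings over $\{0,1,2,-\}$: 0/0 → `1`, 1/1 → `2`, 0/1 → `0`, missing →
`-`, concatenated in panel order (`binary_fingerprint()`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `panel_size` (C) | 100 | loci per panel; the published core-panel size |
| `population_size` (P) | 100 | panels per generation |
| `max_iterations` (X) | 500 | generation budget |
| `crossover_probability` | 0.8 | per-pair single-point crossover rate |
| `mutation_probability` | 0.1 | per-offspring mutation rate |
| `mutation_fraction` | 0.3 | fraction of positions mutated when firing |
| `max_missing_fraction` | 0.01 | strict-greater missingness removal |
| `min_homozygote_count` | 2 | per-class homozygote requirement |
| `r2_threshold` | 0.95 | adjacent-pair dosage $r^2$ cutoff |

Missing genotypes are ordinary profile symbols by default, so two
samples differing only in missingness count as distinguished;
`fitness(..., missing_wildcard = TRUE)` provides the conservative
alternative where missing matches anything.

## The synthetic population

`simulate_population()` replaces external accession data with a stated
world: N samples in K subgroups, per-locus ancestral reference-allele
frequency uniform on [0.05, 0.95], subgroup frequencies drawn from the
Balding–Nichols beta model with divergence F, genotypes binomial(2, p),
plus independent missingness and a fraction of duplicated adjacent
columns (perfect LD) to exercise the pruning filter. Defaults — 200
samples, 1,000 loci on 12 chromosomes, 5 subgroups, F = 0.15, 1%
missing, 10% duplicated pairs — mirror the end-to-end test scenario;
F = 0.15 is a moderate, realistic crop-panel differentiation (typical
subpopulation F\_ST for structured germplasm collections sits roughly
between 0.05 and 0.25), chosen once and not tuned.

What the generator does *not* emulate: recombination-map LD decay (only
adjacent duplicates), genotyping-error structure, polyploid dosage
uncertainty, pedigree relatedness. A green end-to-end test therefore
establishes that the machinery — filters, GA, fingerprinting — composes
correctly on structured diploid data of realistic shape, not that the
default thresholds are optimal for any particular real crop.

## Numerical choices and degenerate inputs

- Adjacent $r^2$ uses genotype dosages over pairwise-complete samples;
  pairs with fewer than two complete observations or a monomorphic
  member get $r^2 = 0$ by convention (the exact estimator of the
  original VCFtools computation is not documented; dosage $r^2$ is fixed
  and stated).
- Distance between samples is the mismatch proportion over shared
  non-missing loci; a pair sharing no locus gets distance 1 with a
  warning.
- Panel-versus-full "matrix correlation" is implemented as the
  Mantel-style Pearson correlation of the strictly-upper-triangle
  entries of the two distance matrices (an interpretation — the source
  does not define correlation between matrices of different widths);
  constant triangles raise an error rather than returning NaN.
- `C = 1` panels have no crossover point: children equal parents.
- An all-zero fitness vector yields uniform selection probabilities.
- When the distinct-panel space is smaller than P, the population is
  padded with duplicate members after refill attempts are exhausted.

## Limitations

The GA is single-objective and offers no guarantee of optimality; the
test suite checks it against exhaustive enumeration only on small
instances (8 samples × 15 loci, C = 3), where it attains the optimum in
at least 19 of 20 seeds. Filter survivor counts reported for real
species data depend on upstream variant calling and are not reproducible
here; the package reproduces the *rules*, verified on constructed
boundary fixtures. QR rendering of fingerprint codes, tree building and
population-structure modeling are out of scope — codes export as TSV.
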