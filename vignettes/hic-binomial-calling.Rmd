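---
title: "Calling significant Hi-C interactions with a coverage-product binomial null"
author: "HiCbinom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling significant Hi-C interactions with a coverage-product binomial null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HiCbinom)
```

## The problem

A Hi-C library is a collection of proximity-ligated DNA fragment pairs, each
sequenced read pair nominally reporting a spatial contact between two genomic
loci. Two obstacles stand between the raw read pairs and a list of genuine
interactions. First, coverage varies strongly along the genome — GC content,
restriction-site density, fragment-length effects, mappability and
amplification biases all modulate how often a locus appears in the library —
so raw counts between two loci mostly reflect how visible those loci are, not
how often they touch. Second, a substantial fraction of ligations happen
between fragments that were never crosslinked together ("random ligations"),
producing read pairs indistinguishable from real contacts.

HiCbinom addresses both with a single idea: whatever the biases are, known or
unknown, they are captured in the observed coverage of each locus, and they
act on the two ends of a read pair independently.

## The model

Reads are aggregated into fixed-width bins (the *loci*, typically 1 Mb,
500 kb or 100 kb). With $reads_j$ the number of read ends mapped to bin $j$
and $N$ the total number of read pairs after filtering, the relative coverage
of bin $j$ is

$$r_j = \frac{reads_j}{2N}, \qquad \sum_j r_j = 1 .$$

Under end-independence, the probability that a single random-ligation pair
links distinct bins $j$ and $h$ is

$$p_{j,h} = 2\, r_j\, r_h\, f_{random},$$

where the factor 2 counts the two end assignments of an unordered pair, and
$f_{random}$ is the fraction of the library arising from spurious ligation.
$f_{random}$ is hard to estimate, and setting $f_{random} = 1$ (the package
default) gives a conservative upper bound on $p_{j,h}$, hence conservative
p-values.

Each bin pair is then a binomial experiment over the $N$ pairs of the
library. The p-value of an observed count $n_{j,h}$ is the upper tail

$$\mathrm{pval}_{j,h} = P(X \ge n_{j,h}), \qquad X \sim \mathrm{Binom}(N, p_{j,h}),$$

and significance is controlled with Benjamini–Hochberg over the full universe
of $m = L(L-1)/2$ bin pairs, $L$ the number of loci. The effect size is the
log observed-over-expected ratio $R_{j,h} = \log_2\!\big(n_{j,h} / (p_{j,h} N)\big)$,
analogous to a log fold-change, and like it noisy where expectations are
small.

Two deliberate stances follow from the model. Self pairs ($j = h$) are never
tested; their null mass $\sum_j r_j^2$ is exactly the probability excluded
from the off-diagonal universe (`nullNormalization()` reports the split), and
the off-diagonal null is left sub-normalized rather than rescaled. And there
is *no genomic-distance correction*: distance-corrected callers assume
functional interactions outcompete structural ones at equal distance, which
penalises short-range contacts of real regulatory interest. The output is
therefore a comprehensive list of contacts not explained by experimental
noise, structural and regulatory alike.

## Artefact filtering

Before binning, read pairs are cleaned in two deterministic steps:

* **Duplicate removal** (on by default): at most one pair is kept per exact
  (chrom, pos, strand) × 2 key. Hi-C libraries are PCR-amplified, so exact
  ditag copies are overwhelmingly amplification artefacts.
* **Artefact filter**: a pair is discarded when both ends map to the same
  restriction fragment (self-ligations — at *any* separation), or when the
  ends are on one chromosome closer than `minDistance` (default 10 kb;
  dangling ends, re-ligations, incomplete digestion). The comparison is
  strict (`< minDistance`): a pair at exactly 10 kb survives. Distance is
  measured between the 0-based leftmost mapped positions and strand plays no
  role in this rule. Trans pairs are never touched.

The categories partition the input exactly
(`duplicates + sameFragment + proximity + retained = input`), which the
`FilterStats` class enforces on construction. The fragment map comes from
in-silico digestion (`digestGenome()`): forward-strand, non-overlapping motif
matching, correct for palindromic sites such as HindIII `AAGCTT` and NcoI
`CCATGG`; non-palindromic enzymes would need reverse-strand search and are a
stated limitation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `binSize` | 1e6 bp | width of the tested loci; 1 Mb, 500 kb and 100 kb are the intended working points |
| `minDistance` | 10000 bp | cis separation below which a pair is an artefact (strict `<`) |
| `dedupe` | TRUE | drop exact duplicate ditags |
| `fRandom` | 1 | spurious-ligation fraction; 1 = conservative upper bound |
| `fdr` | 0.05 | q-value threshold (strict `<`) for the `significant` flag |
| `removeAdjacent` | FALSE | drop same-chromosome neighbour bins before testing (for comparisons with callers that do) |
| `LPolicy` | "all" | bins counted in $L$: all bins of the map, or only non-zero-coverage bins |
| `mapq` | 0 | minimum mapping quality when reading alignments |

`LPolicy = "all"` is the default because the test universe the q-values refer
to is all locus pairs — the many untested pairs carry p-value 1 implicitly
and belong in $m$. Switching to `"nonzero"` shrinks $m$ and makes q-values
slightly less conservative.

## Numerical choices

* The binomial upper tail is computed through the upper-tail cumulative
  distribution (the regularized incomplete beta), never as `1 - CDF` in
  floating point; it keeps full relative precision for $N \sim 10^8$ and
  $p \sim 10^{-12}$, where the naive form collapses to 0.
* BH over $m$ tests with only $s \le m$ materialized p-values is computed by
  running the step-up rule on the $s$ supplied values with denominator $m$:
  a padded p-value of 1 at rank $k$ contributes the candidate $m/k \ge 1$,
  which the final cap at 1 enforces anyway, so the shortcut is exact. At
  100 kb resolution genome-wide this avoids enumerating $\sim 3\times10^8$
  pairs.
* $R$ is `NA` when $n = 0$; a positive count on a zero-coverage pair is
  impossible by construction and raises an error rather than `Inf`.
* Output tables are sorted by (qvalue, pvalue, bin1, bin2), making runs
  byte-reproducible; all randomness in the package flows through explicit
  `seed` arguments.
* Coordinates are handled as `GRanges` (1-based, closed) inside the package
  and emitted 0-based half-open in every text format (BED, pairs, interaction
  tables); bin and fragment indices are dense `1..L` in (chromosome order,
  start) order.
* The random-ligation simulator draws two consecutive uniform deviates per
  pair, so its output is identical for any chunk size at fixed seed.

## What the simulator emulates — and what it does not

`simulateBiasProfile()` draws per-bin weights i.i.d. from a gamma
distribution and normalizes them. The gamma family gives the right-skewed
heterogeneity seen in real coverage tracks with a single interpretable knob:
CV $= 1/\sqrt{shape}$. The default `shape = 1` (exponential weights, CV 1)
is a deliberately harsh setting — heavier than typical real 1 Mb coverage
variation — so that calibration claims are stress-tested rather than
flattered. `simulateRandomLigation()` then draws both ends of every pair
independently from those weights: exactly the null the caller assumes.
`simulateWithSpikeins()` multiplies chosen pair weights by an enrichment
factor and renormalizes, providing a truth set for sensitivity.

The simulator deliberately omits what the model deliberately ignores:
distance decay, TADs, compartments, and fragment-level ligation chemistry.
Passing the simulation suite therefore shows that the implementation is
faithful to its own model and calibrated under it — it does not show that
end-independence holds in real nuclei, nor how the caller behaves on
distance-structured contact maps. The cis/trans composition of a simulated
random library follows the chromosome weights ($\mathrm{trans} = 1 - \sum_c W_c^2$,
about 94–95% for a mouse karyotype with length-proportional coverage),
mirroring the behaviour of experimental random-ligation controls, whereas
real Hi-C libraries are cis-dominated — a useful library-quality flag that
`qcReport()` surfaces.

## Validation scales used by the package

The shipped validation suite runs, in a few minutes on one core: five
random-ligation simulations of 35 million pairs on a mouse karyotype binned
at 1 Mb (2,665 loci, gamma(1) weights) expecting zero significant calls at
FDR 5%; a 500-bin spike-in study (50 pairs at 20-fold enrichment, 5 million
pairs, five seeds) expecting sensitivity ≥ 0.9; the trans-fraction law within
Monte-Carlo error; brute-force oracles for the binomial tail (relative error
≤ 1e-10) and padded BH (exact); and an exactly-tallied 20-pair filtering
fixture. `scripts/acceptance.R` recomputes all of these from scratch.

## Known limitations

* **Observed-rank coverage diagnostic.** `coverageIndependence()` ranks the
  *observed* interactions. Conditioning on $n \ge 1$ is itself
  coverage-dependent under a correct null: a low-expectation pair that is
  observed at all tends to carry a small p-value, so the lowest-coverage
  quartile is mildly enriched among top ranks. Under the harsh gamma(1)
  weights this residual deviation reaches ~8 percentage points in the extreme
  quartiles even though the *calls* are perfectly specific (zero significant
  calls on the same data). It is a property of the diagnostic's conditioning,
  not a miscalibration; milder, more realistic heterogeneity shrinks it.
* **False discoveries are licensed by FDR.** At FDR 5% with ~50 true
  discoveries, BH admits ~2–3 false discoveries per run *by design*; the
  spike-in study observes 0–3 per seed (empirical FDR ≈ 3%, under the nominal
  5%). Expecting literally zero false positives at a 5% FDR misreads the
  guarantee.
* Low-coverage bins produce noisy $R$ values (small expectations, integer
  counts) — the usual caveat of fold-change-like measures.
* Enzymes with degenerate or non-palindromic motifs, chimeric-read rescue,
  and distance-aware backgrounds are out of scope.

## A compact worked example

```{r example, eval = FALSE}
library(HiCbinom)
lm   <- makeBins(c(chr1 = 80e6, chr2 = 60e6), 1e6)      # 140 bins
prof <- simulateBiasProfile(lm, shape = 1, seed = 5)
sp   <- sampleSpikeins(lm, 8, enrichment = 30, seed = 5)
sim  <- simulateWithSpikeins(prof, 3e5, sp, seed = 6)
res  <- callInteractions(sim$contacts, fdr = 0.05)
head(res[res$significant, ])
coverageIndependence(res, sim$contacts)
```
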