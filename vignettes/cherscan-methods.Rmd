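---
title: "Methods: tiling-array ChIP analysis with cherscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiling-array ChIP analysis with cherscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherscan)
```

## The experimental design this package models

ChIP-chip measures transcription-factor occupancy by hybridizing
immunoprecipitated chromatin (Cy5) against input DNA (Cy3) on a tiling
microarray. The design `cherscan` targets is a promoter array: ~50–75-mer
reporters every ~100 bp across a window of about −7 kb to +3 kb around
each annotated TSS. Pooled tissue samples (one disease pool, one control
pool per antibody) mean there are no replicates; all inference rests on
the spatial coherence of enrichment along the genome, not on
between-array variance. Sonication leaves fragments of roughly 0.2–1 kb,
so true binding shows up as a *plateau* of elevated log ratios several
probes wide — which is why every step below is built around runs of
consecutive probes rather than single-probe outliers.

## Preprocessing

**Probe filtering.** Reporters mapping to more than one genomic location
are removed outright (`filter_unique_probes()`); cross-hybridizing probes
otherwise seed spurious enrichment. Probes missing either channel are
dropped, not imputed — the smoothing step tolerates gaps explicitly, and
imputation would manufacture spatial coherence where none was measured.

**Normalization.** Per-probe ratios $r_i = \log_2(\mathrm{IP}/
\mathrm{input})$ are centred on their one-step Tukey-biweight location
(`tukey_biweight_location()`): with $\tilde r$ the median and MAD the
unscaled median absolute deviation,
$u_i = (r_i-\tilde r)/(c\cdot\mathrm{MAD}+\varepsilon)$ and
$w_i = (1-u_i^2)^2$ for $|u_i|<1$, else 0. The tuning constant $c = 5$
and guard $\varepsilon = 10^{-4}$ are the conventional values of the
one-step array estimator; truly enriched probes are exactly the outliers
the biweight down-weights, so the centre tracks the unenriched bulk. With
a degenerate MAD (over half the values identical) all weights can vanish
and the median is returned. Centring makes 0 mean "no enrichment"; no
variance scaling is applied because the threshold below is a quantile of
the same distribution and is therefore scale-free.

**Smoothing.** `running_median()` replaces each probe's value by the
median over all probes within 450 bp (a centred 900-bp window). Windows
holding fewer than 7 probes give a missing value, so isolated probes and
sparse stretches can never form an enriched region. Two conventions are
fixed deliberately: the median of an even count is the mean of the two
central order statistics, and the 900-bp figure is interpreted as the
*total* window span (half-window 450 bp) — consistent with the 450-bp
region-separation scale used later — with the half-window exposed as a
parameter since the alternative reading (900 bp per side) is defensible.

## Calling ChIP-enriched regions (chers)

Three rules, applied in order by `call_chers()`:

1. maximal runs of consecutive probes with smoothed value **strictly
   above** the threshold $y_0$ ("exceeds" is read strictly; ties at
   exactly $y_0$ are not enriched);
2. runs shorter than 7 probes are discarded;
3. surviving runs on one chromosome closer than 450 bp (start of next
   minus end of previous) are merged — fragments this close derive from
   the same sonication-scale binding event.

Region start/end are the first/last probe positions. A merged region may
span sub-threshold probes between its runs; `n_probes` counts only
above-threshold probes, and the score sums $(s_i - y_0)$ over those
above-threshold probes. Restricting the sum this way (rather than over
all probes in the span) keeps the score non-negative and makes it exactly
the enrichment mass above the threshold; for unmerged regions the two
definitions coincide.

**The threshold.** $y_0$ is the top-1% point (99th percentile, linear
interpolation between order statistics) of the smoothed enrichment
distribution. Two readings of "the distribution" are implemented, because
the underlying rule — the 99th quantile of *potential* enriched regions —
does not pin down the candidate universe:

* **default**: the quantile of all non-missing smoothed values
  (`floor_quantile = NA`), i.e. the threshold probe-level convention of
  the smoothing/peak-calling tools this workflow descends from;
* **candidate-run mode** (`floor_quantile = 0.5`): enumerate maximal
  ≥7-probe runs above the median of the smoothed values and take the 99th
  percentile of the runs' maximum levels, falling back to the all-values
  quantile (with a logged message) when fewer than 10 candidate runs
  exist.

The all-values reading is the default for a structural reason: the
run-maxima distribution mixes noise runs with *true* enrichment runs, so
whenever genuine binding contributes more than 1% of candidate runs — 20
spiked promoters among a few hundred candidate runs at desk scale, and
plausibly thousands of bound promoters on a real genome-wide array — the
99th percentile of run maxima lands *inside* the distribution of true
peak heights, and the caller thresholds away the very signal it is meant
to find. The all-values quantile degrades gracefully instead (enriched
probes are a small fraction of all probes), satisfies the same top-1%
false-positive intent, and passes both calibration properties below.
Results carry the reading used in the threshold's `method` attribute.

## Gene assignment and site distances

A cher annotates a gene when it overlaps the strand-aware promoter
window — 10 kb 5′ of any TSS, excluding the TSS base itself — or the gene
body (`assign_chers_to_genes()`). All overlapping genes are reported (a
promoter array places one cher near several genes surprisingly often);
when both rules hold, `within_gene` is recorded. For site-to-TSS
distances the motif's absolute position is `cher_start + offset` and the
reported distance is $(\mathrm{TSS} - \mathrm{position}) \times
\mathrm{strand}$, positive when the site lies upstream on the coding
strand; the gene's most proximal TSS (ties toward the smaller coordinate)
is used. An additive alternative reading of the distance convention is
kept behind `literal = TRUE` for comparison. Offsets between predicted
sites and qPCR validation amplicons are `assay − site`
(`tfbs_assay_offset()`), the sign convention fixed by the published
validation table bundled as `qpcr_assays()`.

## Motif scanning

`scan_chers()` implements the information-weighted similarity scoring of
the classic Match-style scanners. Each PWM column carries information
$I(i) = \sum_B f(i,B)\ln(4 f(i,B))$ (natural log; $0\ln 0 = 0$; the log
base cancels in the score ratio except through the weighting, so it is
fixed for determinism). For a window with bases $b_i$,

$$\mathrm{MSS} = \frac{\sum_i I(i) f(i,b_i) - \sum_i I(i)\min_B f(i,B)}
{\sum_i I(i)\max_B f(i,B) - \sum_i I(i)\min_B f(i,B)} \in [0,1],$$

1 exactly on the consensus and 0 on the anti-consensus. CSS is the same
quantity over the core: the 5 consecutive positions of maximal summed
information (leftmost on ties). Hits must pass the core cutoff first,
then the matrix cutoff — the two-stage filter of the original tool. Both
strands are scanned (the minus strand by scoring the reverse complement)
and hits are reported at the plus-strand start of the footprint. Windows
containing ambiguous bases are skipped, not scored as zero. Proprietary
cutoff profiles are not bundled: cutoffs are user-supplied per matrix,
with defaults css 0.75 / mss 0.80; count matrices should be loaded with a
small pseudocount (0.01) so no base has frequency exactly zero.

## Over-representation analysis

`enrich()` tests each ontology term by the upper-tail hypergeometric
probability $P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, where the
universe $N$ and sample $n$ count only genes carrying at least one
*propagated* annotation (the true-path rule: a gene annotated to a term
is annotated to all its ancestors). Terms need $K \ge 1$ and
$k \ge$ `min_k` (default 2 — singleton overlaps are noise) to be tested;
BH adjustment runs across all tested terms jointly, before any level
filter. Term *level* is the shortest-path depth below a root, roots at
level 1, so "level 6" selects terms five edges down; shortest-path depth
is the choice here (longest-path is the other convention some tools use,
and the level definition is a config point, not a statistical one). Flat
pathway collections reuse the same machinery with an edgeless graph and
undefined levels. Up- and down-regulated target sets are analysed as
separate calls against the same reference.

## The synthetic experiment

`simulate_experiment()` generates the full input set from one seed
(byte-identical outputs under a fixed seed; a single stream consumed in
fixed order genome → genes → probes → intensities, with the annotation
stream of `simulate_annotations()` seeded at `seed + 1` so either half is
reproducible alone). Default conditions: 200 genes on 2 chromosomes in
non-overlapping promoter slots, windows −7 kb/+3 kb tiled at 100 bp with
60-mer probes, lognormal input baseline (meanlog log 500, sdlog 0.5), 3%
of probes flagged multi-mapping, and 20 spiked promoters with **boxcar**
enrichment — constant +1.5 log2 units over an 800-bp region placed
200–4000 bp upstream of the TSS — plus N(0, 0.3²) log-ratio noise on
every probe. The boxcar matches the sonication-fragment logic (binding
lifts whole fragments, not single probes) and makes in-spike expectations
analytic; 1.5 log2 units (~2.8-fold) with σ = 0.3 mirrors a clean ChIP on
a robust antibody. One consensus copy of an ETS-like 9-mer
(`default_motif()`) is written into the genome at each spike centre.

The annotation generator builds a random DAG (each level-$k$ term takes
parents only from level $k-1$, so construction depth equals
shortest-path level), samples term memberships uniformly within a size
range, and inflates the planted term's membership probability by a
configurable fold inside a designated target set, compensating the
background rate so the expected term size is preserved. Default sizes
(terms of 10–60 genes, planted 40, in a 200-gene universe) are scaled to
the default array; power analyses at reference scale (7,400 genes, term
of 250, 400-gene target, 3× fold) pass those values explicitly.

**What the simulation does not capture:** dye bias, spatial artifacts,
GC/melting-temperature probe effects, copy-number background, peaked
(non-boxcar) enrichment shapes, and correlated annotation structure.
Passing the recovery and calibration suites therefore validates the
*algorithmic chain*, not field performance on real arrays.

## Calibration and power properties

The test suite holds the pipeline to these properties (all on the
default conditions above):

* exact equivalence of the cher caller, the running median and the PWM
  scanner with brute-force oracles on hundreds of random instances;
* spike recovery: mean sensitivity and precision ≥ 0.9 over seeds 1–10
  (observed: ~0.97 and 1.0);
* null calibration: on spike-free tracks the 99th-quantile threshold
  promotes ≤ 2% of median-floor candidate runs (observed ~0.4%), and the
  null rank of a designated equal-size term in the enrichment test is
  uniform (KS p > 0.01 over 1,000 replicates; ranks are made continuous
  with a uniform dither because hypergeometric p-values are discrete);
* power: the 3× planted term is top-ranked by FDR in ≥ 95 of 100 seeds.

Problem sizes (20,000 probes per simulated array, 1,000 null replicates,
100 power seeds) are chosen so the full suite runs in a couple of minutes
while keeping the binomial/KS assertions well-powered.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive throughout; BED/bedGraph exports
  convert to 0-based half-open, and BED scores are clamped integers while
  TSV exports keep full precision.
* Percentiles use linear interpolation between order statistics
  (`stats::quantile` type 7).
* Empty inputs fail loudly (empty intensity vectors, empty TSS lists,
  all-missing tracks), except where the empty result is meaningful: zero
  called chers is a valid outcome, and recovery precision with zero calls
  is reported as missing rather than zero.
* Degenerate PWMs (identical min and max column scores) are an error, as
  is any frequency column summing to zero.
* Known limitation: hg18→hg19-style probe realignment is out of scope;
  an optional two-column coordinate map applied at load stands in, with
  unmapped probes dropped and counted.
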