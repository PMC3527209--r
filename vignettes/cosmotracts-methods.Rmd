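---
title: "Detecting cosmopolitan admixture tracts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cosmopolitan admixture tracts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sub-Saharan *Drosophila melanogaster* populations harbour the species'
ancestral diversity, but many African samples carry chromosomal segments
recently inherited from cosmopolitan (out-of-Africa) ancestors. These
admixture tracts depress local divergence from cosmopolitan reference
genomes and, left unmasked, distort nearly every downstream
population-genetic summary. `cosmotracts` detects such tracts in haploid
consensus sequences using a two-state hidden Markov model whose emission
distributions are estimated empirically from the data, and masks them for
downstream analysis.

The package also implements the machinery such an analysis sits inside:
identity-by-descent (IBD) masking of related genome pairs, SNP-count
windowing, windowed diversity and differentiation statistics (π, relative
π, D~xy~, Hudson's F~ST~), a bootstrap divergence-to-diversity ratio test,
folded site-frequency spectra with their neutral expectation, directional
linkage disequilibrium (r² and the signed r~ω~), outlier-region scanning
with GO permutation enrichment, and a simulation harness that generates
admixed genomes with known tract locations to validate the detector.

## The admixture HMM

For one chromosome arm, windows are built to contain a fixed number `K`
of *non-singleton* SNPs of the African reference panel (minor allele
count ≥ 2 among called panel genomes). SNP-count windows equalize the
information content per window; with empirical Rwanda-like diversity,
`K = 1000` gives a median window near 50 kb, and the simulated validation
runs use windows near 10 kb.

Within each window `w`, every African panel haplotype `i` is scored by
its mean pairwise divergence per comparable site from the cosmopolitan
panel, `d_iw`. The per-window moments (mean, SD over panel members; SD
with the n−1 denominator) standardize these values,
`z = (d − mean_w) / sd_w`, removing local diversity structure. The
**non-admixed** emission distribution pools the standardized African
values over all windows of the arm in histogram bins of 0.1 SD,
normalized to sum to one. The **admixed** emission distribution pools
each cosmopolitan panel member's leave-one-out divergence from the rest
of its panel, standardized by the *same* African-panel window moments
(standardizing by the cosmopolitan panel's own moments is slightly less
accurate on simulated data).

Decoding a query haplotype evaluates its (optionally depth-corrected)
`d` in each window, looks up the two histogram masses, and applies a
likelihood floor of 0.005 to the admixed state so that no single unusual
window dominates. Three numerical conventions matter here:

* the floor is applied to the **admixed state only** (the default).
  Flooring both states caps the per-window likelihood ratio near
  `max(L_adm)/floor` and makes two-to-three-window tracts undetectable
  under a sticky transition prior; leaving the non-admixed state
  unfloored lets windows falling in bins never occupied by any panel
  member carry decisive evidence. `floor_admixed_only = FALSE` restores
  symmetric flooring.
* bins never occupied by *either* pooled distribution (e.g. z far above
  the African range) emit `(1, 1)`: such windows carry no information
  rather than spurious evidence for the admixed state.
* `z` beyond ±5 SD clamps into the terminal bins; windows with missing
  divergence or degenerate moments (SD 0, or fewer than two panel
  values) also emit `(1, 1)`.

Posteriors come from the exact forward–backward algorithm on the
two-state chain with symmetric per-window switch probability `τ` and
initial admixed prior `p0` (defaults 0.005 and 0.1), scaled per window
against underflow. Windows with posterior > 0.5 form core tracts; one
buffer window on each side is added for masking (buffers are excluded
from centiMorgan tract lengths, which are interpolated from the
arm-adjusted genetic map: map distances × ½ on autosomes, ⅔ on the X).

`τ` is not identified by the data in this design, so it is exposed in
`hmm_config()`. When the admixture age of interest is roughly known,
`tau_from_age(g, window_morgans, p0)` supplies the switch probability
implied by tract structure of age `g` (ancestry breakpoints accrue at
rate `g` per Morgan, so adjacent windows differ in state with
probability ≈ `2 p0 (1−p0) (1−exp(−g·w))`). The validation harness uses
this age-matched `τ`; the empirical default stays at 0.005, which favours
long tracts of the kind recent admixture leaves.

### Iterative panel refinement

The African panel itself may contain admixture. `refine_panel()` runs the
full cycle three times: emissions from the (IBD-masked) panel, decoding
of every panel member over the full arm, masking of called buffered
tracts from the panel copy used for emissions, and re-estimation. The
third-round model generates the final calls for all query genomes. An
admixture-free panel is a fixed point: no tracts are called, so all three
rounds produce identical models.

### Depth correction

Sequencing depth depresses observed divergence. As a proxy for a
genome's quality effects, its mean divergence from the rest of the
African panel is compared with the panel average on the same arm, and
its divergence from the cosmopolitan panel is multiplied by
`panel_mean / d_self` before standardization. The ratio form restores
depressed divergence in low-depth genomes (factor > 1) and is exact for
multiplicative depth effects.

## IBD masking

Relatedness between sampled genomes violates population-genetic sampling
assumptions. For every genome pair, 500-kb windows advanced in 100-kb
steps are scored by pairwise divergence per comparable site; windows
below 0.0005 are flagged and merged into maximal segments. A
within-population pair is treated as related when more than 5 Mb of
summed genome-wide IBD lies outside user-supplied "recurrent IBD"
regions, or when a single segment over 5 Mb overlaps one. For each
flagged pair, all segments (+100 kb buffers) are masked to `N` in one
genome only — the lower-depth genome, ties broken lexicographically.
Windows with under 10% comparable sites are skipped in the scan.

## The synthetic-data generator

`simulate_panels()` draws the two-population sample under an ms-style
epoch model (all times in units of 4·N₀ generations, sizes relative to
N₀): an African population of constant size, a cosmopolitan population at
0.183 that crashed to 0.000377 at time 0.0037281 (the out-of-Africa
bottleneck) and rejoins the African lineage at 0.00381, with the
ancestral population at 0.2 from time 0.0145; θ = 0.0376/site,
ρ = 0.171/site, gene conversion at 5× the crossover rate with 86.5-bp
tracts. The engine is msprime via a bundled helper script; the epoch
model, not the engine, is what the generator fixes. Because the samples
are haploid, population sizes are passed as 2·N₀·(relative size) so
that the pair-coalescence timescale matches the ms convention — an easy
factor of two to lose, which the tests pin down against the analytic
expectation E[π] = 2θ·E[T] (≈ 0.0084 for the African sample; most
coalescence happens in the 0.2·N₀ ancestral epoch, which is why realized
diversity sits near the empirical ~0.8% rather than at θ).

Samples are 27 African and 36 cosmopolitan haplotypes plus one *donor*
cosmopolitan haplotype per African haplotype; donors provide the
sequence spliced into African haplotypes inside migrant tracts.
Mutations fall on a monomorphic `A` background with a random alternative
base per site. Gene conversion is disabled by default for arms ≤ 1 Mb
(the validation scale) for speed.

`simulate_migrant_tracts()` is a forward Wright–Fisher simulation (in
C++) of haploid chromosomes as breakpoint lists: each generation every
one of N offspring recombines two uniform parents with Poisson(map
length) crossovers at uniform genetic positions. Migration is either a
single pulse `g` generations before sampling (fraction `m` of founders)
or continuous (each offspring is an unrecombined migrant with
probability `m` per generation). The pulse model yields the classical
tract-length law — interior migrant tracts approximately
Exp(g·(1−m)) in Morgans, mean ≈ 1/g for small m — and is the default;
the validation harness uses continuous migration at `m = 0.1/g`, which
approximates a 10% total admixture proportion while replenishing
migrant lineages against drift (N = 5000 keeps the realized proportion
usefully close to target across ages up to g = 10000).

Two cautions the tests respect: sampled haplotypes from one finite
population share drift history, so tract samples are not i.i.d. —
Monte-Carlo error is therefore estimated across independent replicate
runs, and the distributional check bounds the KS *distance* (≤ 0.035)
rather than a p-value, absorbing the ~1–3% distortion that tract merging
and relatedness leave even at modest sampling fractions.

### What the generator does and does not emulate

It emulates the divergence contrast that powers the HMM (bottlenecked
cosmopolitan panel, deeper African diversity), realistic SNP densities,
tract-length structure across admixture ages, and in-panel admixture at
the stated 10%. It does not emulate depth or quality heterogeneity
(simulated depth is uniform, so the depth correction is exercised on
fixtures instead), reference bias, alignment error, selection, or
inversions. Passing validation therefore demonstrates correctness of the
statistical machinery under the stated demographic model, not robustness
to every artefact of real resequencing data.

## Windowed statistics

π, D~xy~ and Hudson's F~ST~ use per-site pairwise deletion: each site
with enough called genomes contributes its fraction of differing pairs,
and windows average sites, weighted by usable-site counts for arm-level
values. Hudson's F~ST~ is `1 − Hw/Hb` with `Hw` the unweighted mean of
the two within-population diversities (the per-site pair-counting form is
automatically sample-size corrected) and negative estimates are reported
as computed. Relative π weights window ratios by the *reference*
coverage, making it robust to masked blocks in diverse regions;
genome-wide values average the five major arms unweighted. The bootstrap
ratio test resamples 100-kb windows with replacement (667 per replicate,
matching the mid-chromosomal window count; 10⁴ replicates by default,
10⁶ in full-scale mode) and reports the fraction of replicates with
ratio < 1.

The folded SFS uses fixed-n filtering (all panel genomes called); the
neutral expectation for minor count `i` is proportional to
`1/i + 1/(n−i)`, halved at `i = n/2` — 0.3078 for singletons at n = 18.
r~ω~ is the signed correlation of minor-allele indicators over
haplotypes complete at both sites, positive when minor alleles couple;
sites at exactly 50/50 frequency make the sign convention-dependent,
which the tests acknowledge by comparing magnitudes there.

## Outlier scanning

Scans use windows of 100 panel SNPs (offset 20 for differentiation
scans, non-overlapping otherwise). Windows strictly above the arm-wise
97.5% (or 95%) quantile are outliers; outliers separated by at most two
non-outlier windows — counted in non-overlapping window equivalents,
`K/offset` index steps — merge into regions centred on the midpoint of
their most extreme window. Nearest-exon assignment ties break to the
lexicographically smaller gene id. GO enrichment permutes region centres
uniformly over analysis windows (10⁴ times by default), which prices in
gene length via the number of windows each gene is nearest to.

## Problem sizes and runtime choices

The validation suite runs the full pipeline at L = 1 Mb (the design
scales from 10 Mb), 27 + 36 haplotypes, three admixture ages
(g = 100, 1000, 10000), with ~100 windows of ~10 kb; the bootstrap
calibration uses 200 runs at 2000 replicates; the tract-length law uses
35 replicate forward runs (~9000 tracts). These sizes keep a complete
run within a few minutes on one CPU while leaving the Monte-Carlo error
well inside the acceptance margins.

## Known limitations

* `τ` and `p0` are design constants, not estimates; posterior
  probabilities are calibrated only to the extent the emission
  histograms are.
* Emission histograms are pooled per arm; arms with strong systematic
  divergence gradients are handled only through the window moments.
* The depth correction is a single multiplicative factor per genome per
  arm; it cannot fix site-level quality artefacts.
* Very old admixture (g ≈ 10⁴; tract scale below one window) is
  detected above chance but far from completely — consistent with the
  validation design's expectations.
* `simulate_panels()` shells out to a Python coalescent engine; it
  requires `python` with msprime on the PATH.
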