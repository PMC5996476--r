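---
title: "Methods: windowed scans for domestication signals and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed scans for domestication signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the statistical models behind `popgenscan`, the
parameter choices that matter, what the synthetic cohort generator does
and does not emulate, and the numerical conventions a maintainer should
know. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The scientific setting

The package reimplements the population-genomic toolchain of a
domestication study of a perennial, self-incompatible fruit crop sampled
across two continental gene pools (an Asian-like and a European-like
lineage, each with wild and cultivated accessions). Three biological
signals drive the design:

* **Selective sweeps** in cultivated material: artificial selection
  locally erases diversity in the domesticated lineage, producing high
  F_ST against the wild relatives, a high reduction-of-diversity (ROD)
  value, and an excess of rare variants (negative Tajima's D).
* **Balancing selection** at the self-incompatibility S-locus: many
  S-haplotypes are maintained at intermediate frequency in *all* groups,
  producing locally elevated θπ, strongly positive D, and near-zero
  F_ST between groups.
* **Identity by descent and admixture**: clonal propagation, shared
  ancestry and historical hybridization leave long stretches of
  near-identical genotypes between accession pairs, detectable as
  windowed similarity and usable to paint an admixed accession's genome
  by donor pool.

## Windowed statistics

For a group of samples and a window of span `L` bp:

* Per site with `C` called allele copies and `c` alternate copies, the
  pairwise diversity is `2c(C−c)/(C(C−1))`; missing genotypes are
  handled by pairwise deletion (the per-site `C` is exact). The window
  `theta_pi_count` is the sum over sites, and `theta_pi` divides by `L`.
* `S` counts segregating sites; `theta_w = S/(a₁ L)`.
* Tajima's D uses the standard constants with `n` set to the rounded
  harmonic mean of per-site `C` across the window — the constants assume
  one fixed sample size, so under missingness this is a documented
  approximation (exact when data are complete). `S = 0` yields `D = NA`.
* The default `L` is the window span; a per-window callable-site vector
  can be supplied instead when an alignability mask exists. Real
  resequencing panels report diversity against effective (callable)
  sites; the simulator has no unalignable sequence, so the span is the
  honest default here.
* Hudson's F_ST is computed per site as numerator
  `(p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1)` and denominator
  `p₁(1−p₂) + p₂(1−p₁)`, and the window estimate is the ratio of sums
  ("ratio of averages"), which is the stable form for small windows.
  Sites monomorphic across both groups together are skipped; fixed
  differences count (and give F_ST = 1). Negative estimates are
  reported, not clamped — clamping is a presentation choice and would
  bias genome-wide percentile cuts. Weir–Cockerham is deliberately not
  offered as an alternative here: one estimator keeps percentile
  thresholds comparable across runs.
* `ROD = 1 − θπ_cul/θπ_wild` per window, `NA` when the wild window has
  no diversity.

Under label permutation the ratio-of-sums F_ST has a small `O(1/sites)`
negative bias (a ratio-estimator effect), which the test suite accounts
for by asserting a small absolute bound rather than a shrinking
standard-error band.

## Selection scans

A window is a sweep candidate when jointly: F_ST at or above the
genome-wide top-5% cut, ROD > 0.5, and the *cultivated* group's D at or
below the bottom-10% cut. Balancing candidates are the mirror image:
bottom-5% F_ST, top-5% D, top-10% θπ. Conventions:

* Quantile cuts are computed genome-wide (not per chromosome), with the
  qualifying set sized `⌈qN⌉` over non-missing values and ties at the
  cut included.
* The cultivated member of the compared pair is the group whose D is
  screened — sweeps of interest act on the domesticated lineage. This is
  configurable.
* A window missing any one statistic never qualifies (conservative).
* Adjacent qualifying grid windows are merged; no gap bridging.
* Gene annotation lists any gene overlapping ≥ 1 bp of a region
  (half-open arithmetic: a gene starting exactly at a region's open end
  does not count), once per region.

## Windowed IBD, AverIBD and painting

The p-distance between unphased diploid genotypes is the allele-content
distance `|g_i − g_j|/2` averaged over co-called sites; two
heterozygotes are distance 0 under this metric, which is the natural
reading of "p-distance" for unphased dosage data. Windows are anchored
at position 1 of each chromosome, non-overlapping, 10 kb; a window is
evaluable with strictly more than 10 co-called SNPs and IBD when
similarity strictly exceeds 0.95. `P_ij` is the percentage of IBD
windows among *evaluable* windows (windows with too few SNPs carry no
evidence either way, so they are excluded from the denominator).
`AverIBD` averages `P_ij` over group x reference pairs, excluding
self-pairs when the sets overlap.

Painting assigns each evaluable window of a target accession to the
donor group whose best-matching member passes the IBD criterion with the
higher maximum similarity; ties and windows passing for neither group
stay unassigned. This window-vote rule is intentionally simple — no HMM
smoothing — so its failure modes are transparent: isolated windows can
flip near mosaic breakpoints, which is why recovered proportions are
checked to ±5 percentage points rather than exactly.

## LD from unphased genotypes

Two-locus haplotype frequencies are estimated by EM: allele margins are
fixed by the observed genotypes, so the only unknown is `p_AB`;
double heterozygotes split their two phasings by the current odds
`p_AB·p_ab / (p_AB·p_ab + p_Ab·p_aB)`. The EM starts at linkage
equilibrium and stops at `|Δp_AB| < 1e-10` (≤ 1000 iterations), then
`r² = D²/(p_A(1−p_A)p_B(1−p_B))` and `D′` follow from the converged
frequencies. Sites are pre-filtered by MAF ≥ 0.05, genotyping rate
≥ 0.6 and exact Hardy–Weinberg p ≥ 0.01 (the conditional exact test,
summing configurations no more probable than the observed one); pair
distance is capped at 200 kb. These mirror the conventional Haploview
settings for resequencing panels.

Decay profiles use 100-bp bins to 2 kb and 1-kb bins beyond, because LD
in an outcrossing perennial decays within hundreds of base pairs; the
half-decay distance is the midpoint of the first bin (left to right)
whose mean r² falls to half the *global* maximum (the first bin is not
guaranteed to be the maximum at these scales). Genome-scale inputs make
all-pairs evaluation quadratic in site density, so `nAnchors` restricts
the computation to all pairs inside randomly placed anchor regions —
this preserves the short-range decay shape, which is the quantity of
interest, at bounded cost.

## Phylogeny

Distances are genotype p-distances; trees are standard neighbor joining
(exact on additive matrices), with negative branch lengths clamped to
zero. The bootstrap resamples SNP sites with replacement to the original
count — implemented as multinomial site weights, which is numerically
identical and lets one precomputation serve all replicates. Replicate
trees are merged by majority rule; each retained bipartition carries its
percent support. Branch lengths come from the full-data NJ tree when the
merged topology equals it (the common case); otherwise NJ lengths are
undefined for that topology and a least-squares fit of the consensus
topology to the full-data distances completes them. Rooting on an
outgroup is a display option; trees are unrooted internally.

## QTL colocalization

The observed statistic is the number of sweep windows intersecting any
QTL interval. The null re-places each chromosome's sweep windows
uniformly at random on that chromosome's 10-kb grid (counts preserved,
without replacement), leaving QTL positions fixed — QTLs are measured
biology, sweep windows are the inferred quantity, so they are the
natural thing to randomize. The reported p uses the +1 correction,
`(1 + #{null ≥ obs})/(1 + n)`, which is valid but conservative for a
discrete count. For calibration studies the package also exposes the
randomized tie-broken p (`randomizedPValue()`), which is exactly uniform
under exchangeability; the acceptance suite checks uniformity on that
form, while the reported p stays conservative.

## The synthetic cohort: what it emulates

`simulateCohort()` draws ancestral allele frequencies from
Beta(0.35, 0.35) — a folded spectrum rich in low-frequency variants, so
background Tajima's D sits modestly below its balanced-locus values as
in real panels — then derives regional frequencies by a
Balding–Nichols draw with drift `fRegion` (default 0.25, standing in for
a several-million-year divergence between gene pools) and cultivated
frequencies from the wild ones with `fStatus` (default 0.06, reflecting
the weak domestication bottleneck of an outcrossing, clonally propagated
perennial — wild and cultivated diversities stay close, as the
diversity-ordering test checks). Genotypes are two independent allele
copies per sample; a uniform 5% dropout exercises every
pairwise-deletion code path.

Planted features:

* **Sweeps** erase standing variation in the target group at rate
  `intensity` and sprinkle singleton heterozygotes (rate 0.15 per swept
  site). At intensity 1.0 this leaves `S > 0` with an all-rare spectrum,
  so all three sweep criteria fire together; a fully monomorphic window
  would have undefined D and could never satisfy the conjunctive rule.
* **The balanced locus** holds `n_classes` random haplotypes (default 6)
  at equal frequency in every group: high θπ, strongly positive D,
  F_ST ≈ 0 — the S-locus signature.
* **IBD segments** overwrite one sample's genotypes with its partner's;
  dropout is applied afterwards, so co-called sites remain identical and
  window similarity is exactly 1.
* **The admixed accession** is a block mosaic (500-kb blocks, random
  phase offset) copied from random donors of the two cultivated pools,
  with the block-to-pool allocation made at the exact 60/40 proportion
  so recovery checks compare against a stable target.
* **LD mode** (`ldPoolSize > 0`): sample haplotypes become mosaics of a
  small pool of group haplotypes with exponential segment lengths, which
  creates genuine r² decay on the `ldSegmentBp` scale. It is off by
  default because pool sharing also creates chance window-level IBD,
  which would blur the painting and IBD null properties of the default
  cohort; the LD demonstration uses a dedicated cohort.

Default scale: 2 chromosomes x 5 Mb, ~10 SNPs/kb, 12 accessions per
group plus one admixed sample. Two scale choices deserve a note. Twelve
per group (rather than a handful) keeps the Hudson window-F_ST noise
small enough that a true-F_ST≈0 balanced locus reliably lands in the
genome-wide bottom 5% — with six per group the bottom-5% cut sits below
zero and the conjunctive balancing rule cannot work; twelve is half the
per-group size of the motivating panel. Ten SNPs/kb (about a third of
the real panel's density) gives ~100 SNPs per 10-kb window, enough that
chance between-sample similarity essentially never crosses the 95% IBD
cutoff — at half that density, chance IBD windows appear and planted-IBD
precision degrades, which is a property of the rule at low marker
density, not of the implementation.

What the simulator does **not** emulate: recombination-explicit
coalescent genealogies (sites are exchangeable draws, so there is no
background LD in the default mode), selection acting through time,
mutation-rate heterogeneity, unalignable or repetitive sequence, and
read-level error. Passing recovery tests therefore demonstrates that the
statistics and calling rules do what they claim on data with the assumed
structure — not that the pipeline is robust to alignment artifacts or
demographic confounding in real resequencing data.

## Pipeline and reproducibility

`runPipeline()` derives one seed per stage from the global seed (so
adding a stage never shifts another stage's stream), writes only
plain-text artifacts, and records parameters and md5 checksums in
`manifest.json` (no timestamps — two runs with the same config and seed
are byte-identical, which the acceptance suite verifies). On a rerun
into an existing directory, stages recompute in memory but rewrite only
missing artifacts, so deleting one stage's files regenerates exactly
those. The tree stage thins to at most 20,000 evenly spaced sites —
p-distances from 20k SNPs are stable to the third decimal, and the
bootstrap cost is linear in sites — and the default study sizes keep the
whole run in the low minutes on one CPU.

## Numerical conventions and degenerate inputs

* Coordinates: 1-based inclusive in VCF/GFF3 and in `GRanges`
  internally; BED output is 0-based half-open. Overlap semantics are
  half-open-consistent throughout.
* Multi-allelic and indel records are skipped on read (never split),
  matching the biallelic-SNP analysis contract; half-calls count as
  missing. The missing-rate filter is strictly `<` its threshold.
* Site filters are idempotent; filtering an already-filtered cohort is a
  no-op.
* `quantileThreshold()` sizes the qualifying set as `⌈qN⌉` over
  non-missing values with ties included, so a constant vector qualifies
  entirely — conservative in the direction of calling more candidate
  windows, which the conjunction then prunes.
* NJ tie-breaks follow the deterministic lowest-index rule of the
  underlying implementation; trees, EM fits and permutations are all
  reproducible from their seeds.
* Known limitations: Tajima's constants under heavy, unevenly
  distributed missingness rely on the harmonic-mean `n` approximation;
  the painting rule has single-window resolution; the permutation null
  treats sweep windows as exchangeable units and ignores their spatial
  clustering (a circular-shift null would preserve it, at the cost of a
  much coarser null space).
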