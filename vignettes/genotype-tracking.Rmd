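---
title: "Tracking phage genotypes through longitudinal metagenomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking phage genotypes through longitudinal metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetrace)
```

This vignette explains the models behind phagetrace, the parameters that
matter and their defaults, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where more than one
reasonable option existed.

## The inference problem

Short reads cannot phase SNPs that lie kilobases apart, so the haplotype
structure of a phage population must be inferred from how allele
frequencies behave across samples and time. The package exploits four
signals, in increasing order of indirection:

1. **Near-clonality.** If every catalog SNP in a sample has frequency
   above `high_threshold` (default 0.97) or below `low_threshold`
   (default 0.03), the sample is a single genotype up to trace
   contamination and its haplotype is the indicator of the high set
   (`detect_clonal_samples()`). The thresholds are strict inequalities: a
   site at exactly 0.97 is not "near fixation". Samples with any missing
   frequency are never called clonal — absence of evidence is not a
   reference allele.
2. **Pigeonhole linking.** For k variants at frequencies `f` in one
   sample, the fraction of genomes carrying all k alt alleles is at least
   `max(0, Σf − (k − 1))` (`cooccurrence_lower_bound()`). When several
   variants each exceed `high_freq_linkage_threshold` (default 0.8) while
   everything else is near absent, a genotype carrying exactly the high
   set is proposed (`derive_genotypes()`). Two design details:
   * With the threshold above one half, every *pair* of high variants
     co-occurs in a positive fraction of genomes; the joint k-wise bound
     is recorded with the proposal but not used as a gate, because for
     large high sets (dozens of SNPs at 0.97–0.99) it is vacuously zero
     even though the linkage evidence is overwhelming.
   * The "everything else" condition uses a background ceiling of 0.10
     (the catalog frequency threshold), not the clonality floor of 0.03.
     Migration between communities maintains a low-level background of
     foreign genotypes above 0.03; requiring the floor would reject
     legitimately near-fixed samples, while the 0.10 ceiling still rejects
     genuine genotype mixtures, which sit at intermediate frequencies.
3. **Linkage groups.** `cluster_trajectories()` partitions the catalog by
   complete-linkage agglomeration on
   `d(u, v) = max over co-observed samples |f_u − f_v|`, cut at the
   coupling tolerance `delta` (default 0.10). The max-abs metric was
   chosen over a correlation because it is directly interpretable against
   the coupling tolerance: two variants are in one group iff their
   trajectories never separate by more than δ anywhere they are jointly
   observed. Complete linkage guarantees that property for whole groups.
   Pairs with fewer than two co-observed samples get a sentinel distance
   above any attainable value and are never merged — one shared sample is
   not evidence of linkage.
4. **Decoupling.** In a community where two genotypes coexist, their
   marker groups travel at their respective genotype frequencies. A
   recombinant breaking that linkage shows up as two previously coupled
   groups separating. `detect_recombination()` emits an event at the
   first sampled week where two group trajectories differ by more than
   `decoupling` (Δ, default 0.30), provided both groups sat inside
   `(δ, 1 − δ)` and within δ of each other at some earlier sampled week
   (the coexistence-and-coupling precondition). Δ = 0.30 is far above the
   binomial sampling noise of group means at the depths the package
   targets (≥ 100×), so a crossing is a population signal, not noise.
   The child haplotype is proposed by rounding the sample frequencies at
   the event week and matched against known genotypes.

## Decomposing mixtures

`decompose_sample()` estimates genotype abundances `a` from a frequency
vector `f` given the haplotype matrix `H` (genotypes × variants):

* **`marker_averaging`** follows the field's hand recipe: a genotype's
  abundance is the mean frequency of the markers exclusive to it. When
  every genotype has exclusive markers this is exact on noise-free input
  and equals the least-squares solution. When haplotypes share markers
  (nested or overlapping genotypes), the recipe first decides which
  genotypes are present — a genotype whose own exclusive markers average
  below `presence_delta` (default 0.10) is called absent — and
  recomputes exclusivity among the present set. If some present genotype
  still has no exclusive marker the recipe is ill-defined and the call
  falls back to least squares, flagged in the output.
* **`simplex_lsq`** solves `min ‖Hᵀa − f‖` subject to `a ≥ 0`,
  `Σa = 1`, via non-negative least squares with a sum-to-one penalty row
  (weight 100) followed by exact renormalisation. The penalty weight only
  needs to dominate the data rows; the subsequent normalisation makes the
  simplex constraint exact to machine precision, and on consistent input
  the solution is exact. The reference (all-zero) genotype absorbs the
  complement; if the supplied set lacks one, an implicit `REF` genotype
  is appended.

Every decomposition returns a simplex: non-negative fractions summing to
one within 1e−9.

## Novel mutation blocks

Variants that are effectively absent (< `low_threshold`) from every
founding (week-0) and closed-regime sample yet later reach the catalog
threshold are candidate novel mutations (`detect_novel_blocks()`). They
are clustered into blocks by the same trajectory metric, and each variant
is assigned a carrier genotype by comparing its trajectory — in the
community where it first appears, from first appearance onward — against
the genotype *abundance* trajectories obtained by decomposing the
non-candidate markers. Two deliberate choices:

* The comparison target is the decomposed abundance, not a raw marker
  trajectory. A genotype's only pre-existing markers may be shared with a
  parent (a recombinant inherits everything it has from its parents), in
  which case the raw marker trajectory contains the parent's contribution
  and diverges from the carrier's abundance exactly in the early window
  where assignment is decided. The decomposition removes that
  confounding.
* The distance is the *mean* absolute difference over co-observed weeks,
  not the max used for linkage clustering. Assignment is a per-variant
  decision against an averaged reference; a max statistic would let a
  single noisy time point veto an otherwise perfect match.

Variants within `delta` of a genotype's abundance trajectory are assigned
to it; the rest form a new genotype of provenance `"mutational"`.
Because novel blocks rise from zero frequency, they would otherwise
mimic decoupling; `run_pipeline()` therefore detects novel blocks first
and excludes their variants from the linkage groups used for
recombination detection.

## The variant filter

`filter_variants()` retains a variant iff, in at least one qualifying
sample, its frequency `alt/(ref+alt)` reaches `min_allele_freq` (default
0.10) **and** its alt depth is at least `min_alt_reads` (default 4); a
sample qualifies iff its breadth of coverage at `breadth_depth_threshold`
(default 10 reads) is at least `min_breadth_fraction` (default 0.30). All
boundaries are inclusive. Frequencies are computed per site from the two
recorded alleles; multiallelic records are split into biallelic
observations upstream by the VCF reader. Sites whose mean depth deviates
from the catalog-wide mean by more than `irregular_depth_factor` (default
5×) are flagged for review, never removed — coverage irregularity is
grounds for inspection, not automatic exclusion. The 10% rule is
evaluated only within qualifying samples, so a spurious frequency in a
low-coverage sample cannot seed the catalog.

## The serial-transfer simulator

`simulate_metacommunity()` provides ground-truthed data shaped like a
paired closed/open mesocosm experiment. Defaults describe the study
design the package targets: 10 mesocosms, four of community type A
(ids 1, 2, 5, 6) natively carrying the phage — one founding genotype per
mesocosm: the reference G1 in mesocosm 2, the nine-marker variant G2 in
1, 5 and 6 — and six of type B founded phage-free; biweekly 1/20-dilution
transfers for 48 weeks; sampling at weeks 0, 2, 4, 6, 8, 20, 32, 40, 48;
an open regime receiving, at every transfer, a 0.2-µm-filtered cocktail
pooling equal volumes of all open communities (virions migrate, cells do
not); a programmed recombination in mesocosm 6 (open) at transfer 4
creating a three-marker recombinant, a programmed recombination in
mesocosm 3 (open) at transfer 3, and a block of 61 novel SNPs arriving on
that recombinant at transfer 4 — the host-switch scenario.

Within each two-week cycle the update is deliberately coarse-grained:

1. dilution (×1/20) and, for open communities, cocktail addition;
2. programmed events scheduled at that transfer (a recombination event
   validates that both parents are present in the community and aborts
   with the event's name otherwise; a novel block instantly replaces the
   carrier population with the block-bearing genotype);
3. host regrowth to the community's host carrying capacity, with a
   fraction `resistance_reversion` (default 0.1) of the resistant pool
   reverting to sensitivity — phase-variable resistance, which lets
   resistance sweep during an outbreak (ending it) while preserving a
   susceptible minority that keeps the phage replicating and selection
   acting afterwards;
4. one round of infection: a saturating fraction
   `θ = P_eff/(P_eff + half_saturation)` of susceptibles is infected,
   partitioned among genotypes in proportion to fitness-weighted
   abundance `w_g P_g`, each infection yielding `burst_size` (default
   100) virions; unadsorbed free virions survive the cycle with
   probability `virion_survival` (default 0.2).

Genotype fitness is per community type (`c(A =, B =)`), which is the
mechanism by which different recombinants dominate different community
types under migration — the biological reading is host-switch adaptation
with a trade-off. Founders default to `c(A = 1, B = 0.02)`: the phage is
adapted to the hosts of its native community type and barely replicates
on the other type's hosts until the adapted recombinant arises.

Two parameters deserve justification because a naive accounting would
omit them:

* `cocktail_efficiency` (default 0.5): the fraction of pooled cocktail
  virions that successfully establish after filtration, storage and
  transfer. With the raw 1/20 volumetric dose, pooled migrants from ten
  communities would arithmetically swamp the small phage populations of
  the non-native community type every single transfer, making the locally
  adapted genotype's observed fixation impossible; real transfer
  protocols lose a large fraction of infectivity at exactly these steps.
* `virion_survival` (default 0.2): free phage decay appreciably over two
  weeks in a compost matrix; without decay, non-replicating migrant
  virions would accumulate and appear in the sequenced virion pool at
  frequencies they never reach in reality.

The observation model is the simplest one that supports the filter's
thresholds: per-sample mean depth scales linearly with the sample's true
phage read fraction, normalised so the peak sample gets
`mean_depth_at_peak` (default 2000×, a deliberately conservative fraction
of the coverage such outbreaks produce); per-site depth is Poisson; alt
counts are Binomial with success probability `f(1−ε) + (1−f)ε` at
sequencing error ε (default 0.001). Breadth summaries follow analytically
from the Poisson depth (`P(depth ≥ k)`), and `n_noise_positions`
monomorphic sites (default 20) flow through the observation model so the
filter has something to reject. The genus count table is
Dirichlet-multinomial around two type-specific mean profiles, with the
mesocosm-level draw shared between paired closed and open communities
(founder effect), sized so the two types separate along the first
principal axis of the CLR-transformed counts.

What the simulator does **not** emulate: within-host co-infection and
superinfection exclusion, lysis inhibition, sequence-level reads (no
mapping artifacts, no GC bias, no chimeras), host-side evolution beyond
the two-state sensitive/resistant toggle, and any calibrated outbreak
kinetics — the dynamical parameters are illustrative, chosen to reproduce
the qualitative regime structure (outbreak and decline, cross-invasion,
local fixation of adapted recombinants), not fitted to any particular
time series. Tests passing on these data therefore demonstrate the
correctness of the inference logic under a faithful observation model,
not robustness to mapping artifacts or model misspecification in real
sequencing data.

## Validation oracles and problem sizes

The test suite validates each stage against an independent oracle: the
variant filter against an exhaustive loop-based reimplementation on
random tables (up to 20 samples × 50 variants); decomposition against
forward-constructed mixtures (`f = Hᵀa`, recovery to 1e−6) and the
analytic equality of the two modes for exclusive-marker genotypes;
alignment identity against a dynamic-programming alignment oracle on
sequences ≤ 200 bp; Bray–Curtis against an established community-ecology
implementation; and the full inference chain against the simulator's
hidden truth at the default design (10 mesocosms × 2 regimes × 9 sampled
weeks, 70 catalog variants) across ten seeds.

One oracle deserves a note: recombination *timing*. The ground-truth
event log records the transfer at which a recombinant was mechanistically
seeded, but the observable signature — trajectory decoupling beyond Δ —
necessarily lags that moment by however long the recombinant takes to
rise, and is further quantised by the sampling grid. Judging the detector
against the mechanistic seeding time would measure the simulator's sweep
speed, not detection accuracy. The recovery tests therefore run the same
detector on the *noise-free* truth frequencies (abundance-weighted
genotype alleles) restricted to the same qualifying samples, and require
the week detected from noisy data to match the week implied by the truth
trajectories within one transfer. This isolates exactly the detector's
sensitivity to observation noise.

## Numerical choices and degenerate inputs

* Group labels are assigned by decreasing group size (ties by first
  member), so labels are stable under column permutations of the input.
* Genotype ids are assigned by increasing alternative-allele count, so
  the reference haplotype, when observed, is always `G1`.
* `hclust` complete linkage with `cutree(h = δ)` guarantees the
  within-group max-distance bound; the sentinel distance for
  under-observed pairs (2, above the attainable maximum of 1) can never
  be cut below.
* Empty observation sets yield empty catalogs, not errors; negative
  depths, all-zero abundance vectors, rank-0 CLR matrices, and zero read
  totals are errors with named messages.
* The DTR search caps repeat length at ⌊L/2⌋ so prefix and suffix stay
  disjoint, and uses exact matching only.
* Rotation-invariant identity uses a seeded rotation search (exact prefix
  seed of 15 bp against the doubled second sequence, plus evenly spaced
  fallback rotations, at most 50 candidates) rather than all L rotations;
  for genuinely circularly permuted sequences the seed match finds the
  exact rotation.
* The community-type split is the largest gap between consecutive
  mesocosm means along PC1, with the sign of PC1 fixed by its
  largest-magnitude loading; the partition is flagged unstable when the
  gap is below `min_gap_fraction` (default 0.25) of the PC1 range. A
  deterministic gap rule was preferred over a clustering algorithm
  because it is transparent and directly testable.
* The resilience comparison reports a rank sum and an exceedance
  probability descriptively; with windows drawn from the same series the
  independence assumptions of a formal rank test do not hold, so no
  p-value is attached.

## Known limitations

* Genotype derivation only proposes haplotypes visible in near-clonal or
  pigeonhole-linkable samples — the minimal-scenario assumption. Mixtures
  are explained by derived genotypes only; there is no latent-genotype
  search, so a genotype that never dominates any sample is invisible.
* Recombination detection requires the parents' coexistence to be
  *observed* inside `(δ, 1 − δ)` at a qualifying sampled week; sparse
  sampling or low coverage in the coexistence window suppresses the call.
* Carrier assignment for novel blocks assumes the block is fixed within
  its carrier (instantaneous-replacement model); a block polymorphic
  within its carrier would sit between trajectories.
* `pairwise_identity()` is a single global alignment — appropriate for
  near-identical genome copies, not a substitute for a genome aligner on
  diverged sequences.
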