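---
title: "Models and methods behind paleoquartet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleoquartet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoquartet)
```

paleoquartet implements the inference stack used to study the phylogeny,
introgression history and genetic diversity of a four-taxon system in which
some genomes are ancient, low-coverage and damaged: a blue antelope-like
focal species with two sister-group relatives (sable- and roan-like) and an
oryx-like outgroup, `(((blue, sable), roan), outgroup)`. Every stage
consumes pseudohaploid sequences — the single-allele representation that
avoids diploid genotype calling at 2–4x coverage — and every stage can be
validated end to end against a built-in simulator that knows the truth.

## The generative model

### Structured coalescent with an introgression pulse

`demographic_model()` describes the species tree with split times in
generations, a diploid effective size per branch, and an optional
unidirectional pulse. `simulate_gene_tree()` runs a piecewise-constant
structured coalescent backwards in time: within each population, each
lineage pair coalesces at rate $1/(2N_e)$; at a split time the daughter
populations merge; at the pulse time each recipient-population lineage
switches to the donor population independently with probability $f$ (the
standard instantaneous-pulse convention). Windows are simulated as freely
recombining loci — independent genealogies with no recombination within a
window — matching how non-overlapping genomic windows are treated as loci
downstream.

Default anchors: the blue–sable split at 1.67 Ma and the roan split at
2.86 Ma are converted to generations with a generation time of 8 years
(208,750 and 357,500 generations); the outgroup split uses the midpoint of
the 3.6–4.5 Ma calibration interval (506,250 generations). The generation
time and all $N_e$ values are stated modelling choices, not biological
claims. The default $N_e = 150{,}000$ for all branches puts the internal
branch at $T \approx 0.50$ coalescent units, which reproduces the
qualitative regime of the real system: roughly half of all window
genealogies discordant with the species tree.

The simulator is calibrated against the closed-form multispecies-coalescent
result: a quartet gene tree is discordant with probability
$\tfrac{2}{3}e^{-T}$, split equally between the two discordant resolutions
(`expected_discordance()`; the calibration is run by
`discordance_calibration()` on 10,000 windows, where the Monte-Carlo
standard error is about 0.004).

### Mutation

`simulate_window_genotypes()` drops mutations on each branch as a Poisson
process with rate $\mu \cdot \ell$ per site and applies a Kimura
two-parameter move: a transition with probability $\kappa/(\kappa+1)$,
otherwise one of the two transversions uniformly. Defaults
$\mu = 1.25\times10^{-8}$ per site per generation and $\kappa = 2$ are
typical mammalian values. Finite sites means multiple hits are possible;
the K2P closed form (via the eigendecomposition of the rate matrix) is the
test oracle for pairwise divergence.

### Ancient-DNA damage and coverage

`apply_damage_and_coverage()` models the observation layer: per-site depth
is Poisson(`coverage`); each read samples one haplotype and a fragment
position $p \sim \mathrm{Uniform}\{0, \dots, L_r - 1\}$ from the nearer
end; a true `C` is observed as `T` with probability
$\delta_{ss}e^{-\lambda p}$ — the single-stranded-library convention, where
cytosine deamination appears at *both* fragment ends — and a true `G` is
observed as `T` with probability $\delta_{ox}$, uniform along the read,
mimicking oxidative (8-oxo-guanine) damage; finally uniform sequencing
error $\varepsilon$. The two damage channels are exactly the two signals
this class of specimens shows: C-to-T enrichment at fragment ends, and a
uniform G-to-T excess in chemically stressed historical material.

What the generator does **not** emulate: mapping bias, reference bias,
indels, recombination within windows, selection, contamination and
library-specific error profiles. Tests passing against this generator
demonstrate the correctness of the estimators under the stated model, not
robustness to every artefact of real data.

## Pseudohaploid calling

Two modes, matching the two calling strategies used for this kind of data:

* **Consensify-style** (`call_consensify_site()`): mask sites with depth
  below `min_depth = 2` or above `max_depth` (by convention twice the
  individual's mean depth, `auto_max_depth()`); otherwise draw
  `min(3, depth)` reads *without replacement* and emit the base seen at
  least twice — a 3-draw either has such a majority or is all-distinct, so
  ties cannot occur. Sampling without replacement means isolated damaged
  reads are usually outvoted, which is why this caller feeds the
  damage-sensitive analyses.
* **Random read** (`call_random_site()`): one uniformly drawn read,
  the fast unbiased choice used for window trees.

Calls are exhaustively checked against a subset-enumeration oracle for all
depth-$\le 6$ count configurations.

## Site classes and filters

`classify_substitution()` partitions unordered base pairs into
transitions (`C/T`, `A/G` — confounded with deamination), damage-like
transversions (`G/T` and its complementary-strand twin `C/A` — confounded
with oxidation), and clean transversions (`A/T`, `C/G` — producible by no
damage channel). RY recoding (`ry_code()`) makes transitions invisible;
feeding already-recoded sequences back is rejected rather than silently
accepted. `filter_sites()` drops sites with any missing data and
monomorphic sites; the retained count is the shared normalization
denominator for all pairwise diversity values of a cohort. IUPAC ambiguity
codes other than `N` are treated as `N` on ingest.

## D statistics

`dstat()` is the transversions-only ABBA-BABA test: a site is used when no
taxon is `N`, exactly two alleles occur, the allele pair is not a
transition, and the outgroup carries one of the two alleles (it polarizes
the site — sites where the outgroup is `N` or carries a third state are
excluded, which standard practice requires for polarization).
$D = (n_{ABBA}-n_{BABA})/(n_{ABBA}+n_{BABA})$; positive $D$ means excess
sharing between positions 2 and 3 (blue and roan in the canonical
ordering). The standard error comes from a weighted block jackknife over
contiguous 1-Mb blocks (never spanning scaffolds; empty blocks dropped):
with block weights $m_j$ (informative sites), $h_j = n/m_j$ and
leave-one-out estimates $D_{-j}$,

$$\hat\theta_J = gD - \sum_j (1 - m_j/n) D_{-j}, \qquad
\widehat{\mathrm{var}} = \frac{1}{g}\sum_j
\frac{(\tau_j - \hat\theta_J)^2}{h_j - 1}, \qquad
\tau_j = h_j D - (h_j - 1) D_{-j},$$

which reduces *exactly* to the unweighted delete-1 jackknife when all
blocks are equal — the identity that pins the formula in the tests.
$Z = D/SE$ with $|Z| > 3$ conventionally significant.

## Window trees and concordance

`window_trees()` tiles each scaffold with non-overlapping windows (default
20 kb separated by 80 kb gaps, i.e., stride 100 kb from position 1; partial
terminal windows discarded), drops windows where any taxon exceeds 50%
missing data (the threshold is applied per taxon — the upstream convention
is ambiguous between per-taxon and joint, and per-taxon is the
conservative reading), computes transversion p-distances with pairwise
deletion, and builds a neighbor-joining tree per window.

NJ is implemented in-package (Saitou–Nei) with two determinism rules: Q-tie
breaking by smallest taxon-index pair, and clamping of negative branch
estimates to zero. For quartets the topology decision is
distance-dominated, so NJ stands in for per-window maximum likelihood; the
substitution is validated two ways — against a brute-force least-squares
enumeration of the three quartet topologies (1,000 random additive
matrices, 100% agreement required) and against an independent NJ
implementation on random matrices.

`classify_topology()` roots at the outgroup and reports the sister pair:
`BS` (species tree), `BR`, `RS`, with `other` reserved for trees whose
class-defining internal branch is not strictly positive (`tol = 0` by
default; the branch is measured on the tree as given, since rooting
redistributes edge lengths). With two roan individuals, blue attaching
outside the roan pair is `BR` and inside it `BR_nested` — the distinction
that dates the gene flow relative to the roan radiation
(`timing_classification()`). `topology_summary()` gives gene-concordance
proportions; `site_concordance()` gives the site-level analogue over
decisive (2+2 biallelic transversion) patterns.

## Gene-flow direction from branch lengths

The direction test compares roan–sable path lengths (as proportions of
tree length, `path_distance_proportion()`) between windows with the
species topology (BS) and windows where blue and roan are sisters (BR).
Under roan-to-blue gene flow the roan lineage is untouched, so roan–sable
distances in BR windows look like BS windows: unimodal, no shorter mode.
Under blue-to-roan gene flow, introgressed windows carry roan ancestry
that coalesces near the blue–sable divergence, producing a shorter mode.

Values outside $[0.0002, 0.9]$ are discarded (inclusive bounds: the
upstream rule excludes values strictly below/above the cut-offs, which
arise from windows with negligible information). The package
operationalizes the published visual assessment with two seeded tests at
$\alpha = 0.01$:

* a **one-sided permutation median test** (is the BR median *smaller* than
  the BS median?). One-sided is a deliberate design decision: conditioning
  on the discordant topology under pure lineage sorting makes roan–sable
  distances *deeper* on average, so a two-sided test fires on the wrong
  tail in exactly the scenario it should clear;
* a **dip-style unimodality test** on the BR distribution. The statistic
  is the sup-norm distance from the empirical CDF to its best unimodal
  fit, computed by minimizing over candidate modes the larger of the
  convex-minorant gap (left of the mode) and concave-majorant gap (right),
  halved. It is 1/(2n) for an evenly spaced sample and 1/4 for two
  well-separated equal atoms, and is calibrated by Monte Carlo against
  uniform samples of the same size, so no external null table is needed.

`blue_to_roan` is called when either test is significant; `roan_to_blue`
when neither is; `indeterminate` when a class has fewer than 30 windows
after filtering.

The recovery study (`direction_study()`) runs this on simulated pulses of
$f = 0.2$ with 300 windows of 10 kb and $N_e = 30{,}000$ (internal branch
$\approx 2.5$ coalescent units). The smaller $N_e$ is intentional: at the
discordance-anchored default ($T \approx 0.5$) only about a third of the
BR class is introgressed at $f = 0.2$ and no desk-scale test has power —
the study validates that the estimator recovers a present signal, not the
power of the high-ILS empirical regime, which would require genome-scale
window counts. The no-gene-flow null calibration runs at the anchored
default ($N_e = 150{,}000$), where lineage sorting alone populates the BR
class; because of the conditioning effect above, the one-sided test is at
most conservative there, and the calibration check is for the absence of
excess small p-values rather than exact uniformity.

## Damage-aware diversity

`diversity_table()` applies the joint filter once per cohort and counts,
for every within-species pair, sites whose two alleles form a *clean*
transversion, normalized by the shared denominator. This is a relative
diversity measure: robust to deamination and oxidation by construction,
comparable across species because the denominator is shared, but not an
absolute estimate of $\pi$ (pseudohaploids sample one allele per site).
The validation study (`diversity_study()`) simulates three species with
$N_e = 10^3, 10^4, 10^5$ (four diploids each, 50 windows of 20 kb,
coverage 5, Consensify calling with the 2x-coverage depth cap), and checks
that species means are strictly ordered and rank-correlated with
simulation-truth heterozygosity (`true_heterozygosity()`), which replaces
a genotype-likelihood heterozygosity estimate as the validation oracle.
The study's mutation rate is $10^{-7}$ — a deliberate scaling so the 1-Mb
desk genome carries the information of a ~10x larger genome at a mammalian
rate.

Damage robustness is tested by re-running the same seeds with the read
layer damaging the two blue specimens — both deaminated
($\delta_{ss} = 0.3$), one additionally oxidized ($\delta_{ox} = 0.1$) —
mirroring an ancient/historical pair among modern comparators, with
oxidation confined to one specimen as observed in such material. The
damage-aware statistic of an unaffected pair must move by less than 5%
(relative), while the unfiltered raw difference count of the damaged pair
inflates severalfold. Note the mechanism: damage can still perturb the
*denominator* (spurious polymorphic sites survive the joint filter), which
is why widespread oxidation across many individuals would eventually move
even the damage-aware statistic; the filter removes damage from the
numerator, not from the site list.

## Mitochondrial diversity

`mito_diversity()` is the alignment-level stage: drop every column with
any non-`ACGT` symbol (`strip_ambiguous_columns()`), then report filtered
length, segregating sites, and nucleotide diversity
$\pi = \overline{d_{ij}}/L$ over all unordered pairs with no sample-size
correction (the haplotype-network convention). Alignment construction is
upstream; `fetch_mito_accessions()` can download and align the real
mitogenome accessions when network access and `mafft` are available, and
`synthetic_mito_alignment()` provides a bundled-free synthetic stand-in: a
simulated low-diversity haploid cohort with a sprinkling of `N`s to
exercise the filter.

## Orchestration and reproducibility

`validate_config()` + `run_pipeline()` run the stages
(simulate, call, windows, dstat, direction, diversity, mito) in dependency
order from a YAML configuration, writing FASTA (70 bases per line), TSV
tables, newick tree files, a seed-stamped log and a checksum manifest.
One global seed fans out deterministically to per-stage seeds
(`seed + 1000003 * stage_index mod 2^31 - 1`), so reruns are
byte-identical and stages can be rerun independently.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in every output; conversions happen
  internally.
* NJ tie-breaks and negative-branch clamping as above; an all-equal
  distance matrix yields a zero-length internal branch, classified
  `other`.
* `D` is undefined (an error, not `NaN`) with no informative sites; the
  jackknife refuses fewer than two informative blocks or a single block
  holding every site.
* The dip statistic collapses tied values into single CDF jumps; the
  permutation and Monte-Carlo p-values use the add-one convention
  $(1 + \#\{\text{hits}\})/(1 + B)$ so they are never exactly zero.
* `ry_code()` on already-recoded input raises; `filter_sites()` and
  `strip_ambiguous_columns()` are idempotent.

## Problem sizes used in the validation studies

Calibration 10,000 windows; D recovery 2,000 windows x 5 kb (null: 50
replicates of 200 x 2 kb); NJ oracle 1,000 quartets; direction 20
simulations per scenario of 300 windows x 10 kb (null: 10); diversity 50
windows x 20 kb x 12 diploids at coverage 5. These sizes give the oracle
comparisons quoted above their stated Monte-Carlo precision while keeping
a full validation run in the tens of minutes on one core.

## Known limitations

Pseudohaploid diversity is relative, not absolute; the direction test
assumes the BS class is a valid null reference (violated under strong
gene flow into sable); the simulator's free recombination between and
none within windows brackets, but does not model, real linkage; and the
damage model's two channels do not span every post-mortem modification.
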