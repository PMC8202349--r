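---
title: "Methods: from amplicon reads and closed vials to methanotroph bioindicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from amplicon reads and closed vials to methanotroph bioindicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatmob)
```

peatmob implements the computational path used to study methane-oxidizing
bacteria (MOB) in peat soils: paired-end amplicon reads of the 16S rRNA
V3-V4 region and of *pmoA* transcripts are turned into OTU tables; the
tables are screened for treatment bioindicators and ordinated under a site
condition; *pmoA* OTUs are placed on a neighbor-joining tree; and
closed-vial incubation data are converted into potential CH~4~ oxidation
rates. This vignette explains each model, its assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## Read hygiene

**Merging.** `merge_pairs()` reverse-complements the reverse mate and scans
every candidate overlap of at least `min_overlap` nt (default 10),
selecting the overlap with the smallest mismatch fraction; ties go to the
longer overlap. A pair is merged only when that fraction is at most
`max_mismatch_density` (default 0.25). Both defaults are the customary
values for overlap-based mergers and are configurable. Within the overlap
the base with the higher phred score wins and keeps its own score; we do
not recalibrate the posterior quality of agreeing bases, a deliberate
simplification that only affects downstream quality *filtering*, never the
sequence itself. "Outie" overlaps (reads reading past each other into
adapter) are out of scope: amplicon fragments here always exceed the read
length.

**Windowed quality filter.** A merged read is discarded iff any contiguous
50-nt window (`window`) has a mean phred strictly below 20
(`min_mean_phred`). Reads shorter than the window are judged as a single
full-length window — the strictest reading of "any window". The filter is
monotone: raising the threshold can only shrink the kept set.

**Primer trimming.** Primers are matched under IUPAC degeneracy (bitmask
intersection, so `N` matches anything) with a per-primer mismatch budget
(default 0), *anchored* at the read ends: amplicon reads begin at the
primers by construction, and anchoring avoids spurious internal hits. Reads
lacking either site are rejected with a reason; every stage reports kept +
rejected = input, so read accounting is conservative end to end.

## OTU inference

**Dereplication** collapses identical primer-trimmed sequences into
amplicons with per-sample counts, ordered by decreasing total (ties broken
lexicographically so all downstream processing is deterministic).

**Chimera screening.** `detect_chimeras()` uses an explicit two-parent
crossover model rather than a full h-score: a query is flagged iff the best
single-crossover combination of two distinct candidate parents exceeds the
best *single*-parent identity by at least `min_improvement` (default 0.05,
identity fraction). De novo candidates are amplicons at least
`min_parent_skew` (default 2) times more abundant than the query,
reflecting the fact that chimeras arise late in PCR from already-amplified
templates; in reference mode every database entry is a candidate, and an
entry identical to the query is a legitimate single parent (identity 1), so
exact reference matches can never be flagged. Point errors give
improvements of about 1/L and are likewise immune. The model is
intentionally oracle-testable: the synthetic generator plants crossovers of
the same form, and recovery is measured against the truth table.

**Clustering.** `cluster_swarm()` grows clusters from unclustered seeds in
decreasing-abundance order, absorbing every amplicon within Levenshtein
distance `d` (default 1) of a current member. The resulting partition
equals the connected components of the distance-`d` graph (single linkage),
which the tests verify against a brute-force component search on hundreds
of random instances. The representative is the most abundant member, ties
again lexicographic. The "fastidious" refinement of the original
agglomerator and abundance-weighted greedy variants at d > 1 are
non-goals.

**Reading-frame validation.** Protein-coding *pmoA* amplicons trimmed at
the standard primers are expected to begin with the serine codon TCG
(gene positions 188-190) and end with TAT (tyrosine; mb661R amplicons,
positions 658-660) or TCG (A682R amplicons, positions 679-681).
`validate_reading_frame()` requires length divisible by three, the first
and last codons as expected, and no in-frame stop codon; any 1-nt indel
therefore fails deterministically via the length rule. The printed gene
coordinates are not mutually in frame (the 188-660 span is 473 nt), so the
frame is anchored at the first base of the trimmed amplicon and the gene
coordinates are carried as metadata only. Validation runs per dereplicated
amplicon (equivalent to per read, cheaper), before clustering; 16S V3-V4
amplicons skip the frame check entirely, as 16S is not protein-coding.

**OTU-level filters.** After taxonomic assignment, OTUs are retained iff
the representative length falls in the closed class window (mb661:
465-474 nt; A682: 492-495 nt; V3-V4: 370-435 nt) and the taxonomy path
contains none of Archaea, chloroplast, mitochondria (case-insensitive).

## Reference databases and taxonomy

Reference collections are trimmed to the amplified region (leftmost forward
site, rightmost reverse site; entries missing a site are dropped and
logged) and dereplicated; when identical sequences disagree on taxonomy the
kept path is their lowest common ancestor — a documented choice, since the
behavior of the original curation script on conflicts is unknowable.
Assignment uses end-to-end (global:global) affine-gap alignment of each OTU
representative against every entry, +5/−4 with gap open −10 and extend −1
— common nucleotide defaults for this aligner family, configurable through
`alignment_params()`. Percent identity is matches over alignment columns.
Tied best scores resolve to the LCA of the tied taxonomies, which removes
input-order dependence. No identity floor is applied by default
(`min_identity` exists but is off), matching the permissive best-hit
design.

## Community statistics

Counts are converted to relative abundances per sample; an OTU is treated
as absent from a sample when its relative abundance is strictly below
0.001 (`threshold_relative_abundance()`, no renormalization afterwards).
Matrices are then log-normalized as x → log~b~(x) + 1 for x > 0 with
b = 2 by default; a non-integer matrix is first divided by its smallest
positive entry so the smallest observed abundance maps to 1 and the
transform stays non-negative. This mirrors the reference implementation of
the transformation (the tests cross-check against `vegan::decostand`); the
log base is exposed because published analyses rarely state it.

`partial_rda()` centers the community matrix, residualizes the community
and the constraint design (e.g. `~ treatment * date + ch4_rate`) on the
conditioning variables (`~ site`), fits by least squares, and takes the
constrained axes from the SVD of the fitted values. The decomposition
conditioned + constrained + unconstrained = total inertia (variance scale,
SS/(n−1)) is exact to numerical tolerance, and the implementation
reproduces `vegan::rda(Y ~ X + Condition(Z))` eigenvalue-for-eigenvalue.
Constraint columns absorbed by the condition contribute zero and are
dropped; genuine collinearity among the remaining columns is an error
naming the aliased term.

`rda_permutation_test()` computes pseudo-F statistics from inertia ratios
and permutes rows of the *reduced-model residuals* (condition preserved,
re-residualized each draw) — the standard scheme for partial ordination
tests, chosen explicitly since published analyses typically name only the
testing function. Terms are tested sequentially in formula order;
p = (1 + #(F\* ≥ F))/(1 + m), so p is bounded below by 1/(m+1). Axis
tests compare each constrained eigenvalue against the condition-only null
(a simplification of the sequential axis conditioning some implementations
use; interpret axis p-values accordingly). Type-I error of the term test is
verified by simulation to sit inside the 99% binomial envelope of the
nominal 0.05.

`indval()` computes, per OTU and group, specificity A (share of the
between-group mean abundance) and fidelity B (occurrence frequency within
the group); the indicator value is A·B maximized over groups, and
significance is the probability of a *strictly higher* value under random
relabeling with an add-one correction, so ties favor non-significance. An
OTU whose statistic is invariant under relabeling (all-zero or constant
columns) carries no evidence and reports p = 1. The bioindicator cutoff is
the raw p < 0.001 at m = 10 000 — no multiple-testing correction by
default, as that is how the cutoff is conventionally applied;
`p_adjust = "BH"` is available. Grouping is by treatment only; a
treatment-by-season grouping is possible by pasting factors but is not the
default. Kruskal-Wallis comparisons of individual taxa delegate to
`stats::kruskal.test` (with an explicit H = 0 convention when every
observation is tied).

## Phylogeny

`jc_distance()` computes mismatch proportions with pairwise deletion
(columns where either sequence has a gap or ambiguity are skipped for that
pair — standard practice, since the tree-building literature is usually
silent here) and applies the Jukes-Cantor correction
d = −(3/4)·ln(1 − 4p/3), erroring with the offending pair when p ≥ 0.75.
`nj_tree()` delegates the agglomeration to `ape::nj` and clamps negative
branch lengths to zero with a warning, the presentation convention of
common tree software. `bootstrap_support()` resamples columns with
replacement (default 500 replicates), rebuilds JC + NJ per replicate, and
reports bipartition frequencies as percentages. Multiple sequence alignment
itself is out of scope — the module consumes aligned input (e.g. a fixed
440-column window chosen with `select_window()`; the window start is a
user parameter because published coordinates are rarely reported). On
additive distances NJ recovers the generating tree exactly; on star-like
data with effectively zero internal edges, tie-breaking (and hence
supports) can legitimately depend on input order.

## Gas physics

Headspace CH~4~ mass follows the ideal gas law,
n = f·p·V/(R·T), reported in µg with M = 16.04 g/mol and
R = 0.082057 L·atm·mol⁻¹·K⁻¹. Pore-water concentration from an
N~2~-flushed equilibration vial (20 mL, 5 mL pore water, 21 °C) adds the
dissolved term via Henry's law, f·p·K~H~·V~water~, and divides the total
by the injected pore-water volume. K~H~ defaults to
1.4×10⁻³ mol·L⁻¹·atm⁻¹ at 21 °C — a standard compilation value, exposed
in `gas_constants()` because only the law, not the constant, is usually
cited. Vial and bottle pressures default to 1 atm; incubations are run
slightly overpressured in practice but the overpressure is rarely
quantified, so it is configurable and the default is documented rather
than guessed.

`oxidation_rate()` converts each timepoint to µg (at the 8 °C incubation
temperature), fits an ordinary least-squares line, and reports
−slope·24/dry mass in µg CH~4~ g⁻¹ dry soil d⁻¹. A zero-order (linear)
model is used deliberately: the dosing (~0.5-0.6% CH~4~, far above
ambient) keeps the MOB community substrate-saturated over the ≤45 h
incubation, so first-order fitting is a non-goal. Dry mass comes from the
gravimetric water content, (wet − dry)/wet; soil organic matter is loss on
ignition, (dry − ash)/dry. The default bottle geometry (175 mL bottle,
~15 g wet peat at 1 g/mL displacement, 34 mL added air, 1 mL pure CH~4~)
yields a dosing fraction of 1/195 ≈ 0.513%, inside the intended 0.5-0.6%
band.

## The synthetic-data generators

The generators define the study conditions for every recovery test; they
are first-class, tested code, not fixtures.

* `sim_reference_db()` emulates a curated functional-gene collection:
  genus-level consensus amplicons drawn codon-by-codon to satisfy the frame
  class exactly, strain variants produced by substituting third codon
  positions only (so frame validity is preserved by construction), full
  records with concrete primer sites and random flanks, and
  `domain;class;order;genus;strain` taxonomy paths.
* `sim_community_counts()` uses log-normal baseline abundances (sdlog 1, a
  standard rank-abundance shape), per-sample log-normal noise
  (`overdispersion`, default 0.5), and a multinomial draw at fixed depth.
  Planted bioindicators multiply their expected abundance by a fold-change
  (> 1) in their favored treatment only. CH~4~ rates attached to the
  metadata are log-normal around 50 µg g⁻¹ d⁻¹, a mid-range field value.
* `sim_paired_reads()` builds each fragment as concrete forward primer +
  amplicon + reverse-complemented reverse primer and reads both ends.
  Qualities follow a MiSeq-like per-position mean (38 decaying to ~28)
  with Gaussian jitter clamped to [2, 40]. Chimeras are single crossovers
  between two distinct parents; breakpoints are drawn uniformly over the
  central 10-90% of the amplicon because a crossover within a few bases of
  an end is operationally indistinguishable from a point-mutated single
  parent — it is not a chimera in any detectable (or meaningful) sense.
  Frameshifts are single 1-nt indels at uniform internal positions.
  Substitution errors are applied per read base. A truth table labels every
  read, so every downstream test is label-aware.
* `sim_gas_series()` is linear consumption plus Gaussian noise, clipped at
  zero mass.

All generators are seed-deterministic: identical spec + seed gives
byte-identical output.

**What passing tests do and do not show.** The generators emulate planted,
well-separated effects under a clean factorial design: multinomial
sampling, independent substitution errors, single-indel frameshifts,
two-parent chimeras. Real data add PCR bias, quality miscalibration,
indel-rich error tails, cross-genus similarity gradients, and unbalanced
designs — all explicit non-goals. Recovery results therefore demonstrate
the *correctness* of the algorithms under their stated models, not field
performance.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately compact
problem sizes chosen to exercise every code path while keeping the whole
suite quick to run on a laptop: 200 random clustering instances of up to
100 amplicons against the brute-force oracle; 40 alignment pairs of up to
30 nt against exhaustive dynamic programming; a planted-bioindicator
design with 10 samples per treatment, 40 background OTUs, fold-change 8
and m = 10 000 permutations; 15 reference genera with 5% planted chimeras
and frameshifts over ~900 reads; and 1000 null simulations at m = 199 for
the type-I calibration. Degenerate inputs are handled explicitly rather
than by accident: empty constraint designs give zero constrained inertia,
all-tied Kruskal-Wallis data give H = 0, permutation-invariant IndVal
statistics give p = 1, constant gas series give slope 0 with an undefined
R², and the JC correction refuses p ≥ 0.75 by naming the offending pair.

## Known limitations

* The chimera detector is a transparent two-parent crossover model, not a
  reimplementation of the published h-score; chimeras between very similar
  parents (improvement below `min_improvement`) are undetectable by
  design, as they are for the field tools at comparable thresholds.
* Axis permutation tests use the condition-only null rather than
  sequential axis conditioning.
* The merger does not model quality-dependent posterior recalibration or
  outie overlaps.
* NJ tie-breaking on star-like (near-zero internal edge) regions is
  input-order dependent, as for any NJ implementation.
* Gas calculations assume ideal behavior and a user-supplied, temperature-
  fixed Henry constant.
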