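# peatmob

Amplicon bioinformatics and methane-oxidation analysis for peat
methanotroph communities.

Grazing by large herbivores restructures high-latitude peatlands, and with
them the methane-oxidizing bacteria (MOB) that consume CH₄ before it
reaches the atmosphere. Studies of this system combine two very different
data streams: paired-end MiSeq amplicons — 16S rRNA V3-V4 for the whole
bacterial community and *pmoA* transcripts (the functional marker of
particulate methane monooxygenase) for the active MOB — and closed-vial
soil incubations whose headspace CH₄ decline gives the potential oxidation
rate. peatmob implements the full computational path between raw reads /
gas measurements and the quantities such studies report, as a
tidyverse-native R package: every user-facing function takes a data frame
and returns a tibble, fitted objects have `tidy()`/`glance()`/`autoplot()`
methods, and a seeded synthetic-data module generates every input with
known ground truth so the whole pipeline is testable by parameter
recovery.

## What it computes

**Reads → OTU table.** Overlap merging (best overlap by mismatch
fraction, higher-phred base wins), the windowed quality filter (discard if
any 50-nt window has mean phred < 20), anchored IUPAC primer trimming,
dereplication, de novo + reference chimera screening (two-parent crossover
model with abundance skew), swarm-style single-linkage clustering at edit
distance d = 1, reading-frame validation of *pmoA* amplicons (length
divisible by 3, first codon TCG, last codon TAT/TCG, no in-frame stop),
best-global-alignment taxonomy against a primer-trimmed dereplicated
reference, and the OTU length windows (mb661 465–474 nt, A682 492–495 nt,
V3-V4 370–435 nt) plus the Archaea/chloroplast/mitochondria exclusion.

**OTU table → statistics.** Relative abundances with the < 0.001 absence
threshold; log normalization x → log₂(x) + 1; site-conditioned partial
redundancy analysis (RDA) with sequential permutation tests
(pseudo-F on reduced-model residuals); IndVal indicator-species analysis
(specificity × fidelity, bioindicator iff the permutation probability of a
higher value is < 0.001 on 10 000 permutations); Kruskal-Wallis
comparisons.

**Sequences → tree.** Jukes-Cantor distances with pairwise deletion,
d = −¾ ln(1 − 4p/3); neighbor joining; bootstrap support over resampled
columns (default 500 replicates) on a fixed alignment window (default
440 columns).

**Gas series → rates.** Ideal-gas headspace CH₄ mass n = f·p·V/(R·T);
Henry's-law pore-water CH₄ from equilibration vials; ordinary
least-squares oxidation rate in µg CH₄ g⁻¹ dry soil d⁻¹; gravimetric
water content and loss-on-ignition soil organic matter.

## Worked example

Simulate a small *pmoA* study — 6 reference genera, 2 sites × 2
treatments × 3 replicates, two planted bioindicators at fold-change 8 —
then run the full path:

```r
library(peatmob)
library(dplyr)

db <- sim_reference_db(n_genera = 6, n_per_genus = 1, seed = 20)
design <- community_design(
  sites = c("SV1", "SV2"), treatments = c("grazed", "exclosed"),
  dates = "summer2015", replicates_per_cell = 3,
  n_background_otus = 4,
  planted = tibble::tibble(favored_treatment = c("grazed", "exclosed"),
                           fold_change = c(8, 8)),
  sequencing_depth = 300, seed = 21
)
community <- sim_community_counts(design)
reads <- sim_paired_reads(community$counts, db,
                          read_sim_params(substitution_rate = 0.001, seed = 22))

result <- run_amplicon_pipeline(
  reads$reads, db[, c("id", "taxonomy", "seq")],
  fwd = primer_a189f(), rev = primer_mb661r(), frame = frame_spec("mb661")
)
result$log
#> # A tibble: 6 × 3
#>   stage           kept rejected
#>   <chr>          <int>    <int>
#> 1 merge           3600        0
#> 2 quality_filter  3600        0
#> 3 primer_trim     3489      111
#> 4 chimera_filter  3489        0
#> 5 frame_filter    3410       79
#> 6 otu_filter      3410        0
```

Every stage accounts for its input (kept + rejected), so the 111 reads
with a sequencing error inside a primer and the 79 singleton artifacts
failing the reading-frame rules are reported, not silently dropped. The
six abundant OTUs are the six reference strains at 100% identity; the
remaining low-count OTUs are isolated error reads.

```r
iv <- indval(relative_abundance(result$otu_table),
             community$metadata$treatment, permutations = 9999, seed = 23)
arrange(iv, p_value)
#> # A tibble: 179 × 7
#>   otu     group        A     B indval p_value bioindicator
#>   <chr>   <chr>    <dbl> <dbl>  <dbl>   <dbl> <lgl>
#> 1 OTU_001 exclosed 0.729     1  0.729  0.0001 TRUE
#> 2 OTU_002 grazed   0.920     1  0.920  0.0001 TRUE
#> 3 OTU_004 grazed   0.693     1  0.693  0.0086 FALSE
#> 4 OTU_006 exclosed 0.497     1  0.497  0.658  FALSE
#> 5 OTU_003 grazed   0.541     1  0.541  0.686  FALSE
```

Exactly the two planted OTUs are called bioindicators, each for its
planted treatment: `A` is specificity (how concentrated the abundance is
in that treatment), `B` fidelity (how consistently it occurs there), and
the permutation p-value is the probability of a higher indicator value
under random relabeling.

```r
comm <- relative_abundance(result$otu_table) |>
  threshold_relative_abundance() |>
  log_normalize()
fit <- partial_rda(comm, community$metadata, ~ treatment + ch4_rate, ~ site)
fit
#> Partial redundancy analysis (12 samples)
#>   Inertia: total 25.2219 = conditioned 1.9432 + constrained 7.7300 + unconstrained 15.5487
#>   Constrained eigenvalues:
#>   RDA1   RDA2
#> 6.3857 1.3443
rda_permutation_test(fit, permutations = 999, seed = 24)
#> # A tibble: 2 × 5
#>   term         df variance statistic p_value
#>   <chr>     <int>    <dbl>     <dbl>   <dbl>
#> 1 treatment     1     6.38     3.28    0.003
#> 2 ch4_rate      1     1.35     0.693   0.876
```

After removing the site effect, treatment explains a significant share of
the community variance (pseudo-F = 3.28, p = 0.003) while the unstructured
CH₄-rate covariate does not — as planted. `autoplot(fit, metadata,
colour = treatment)` draws the ordination biplot.

```r
spec <- microcosm_spec(soil_wet_mass = 15, water_content = 0.9)
series <- sim_gas_series(660, 6, c(0, 11, 22, 34, 45), noise_sd = 4,
                         seed = 25, spec = spec)
oxidation_rate(series, spec)
#> CH4 oxidation: 96.656 ug g-1 dry soil d-1 (slope -6.0410 ug/h, R2 0.999, 5 timepoints)
```

A planted consumption of 6 µg/h in a 1.5 g dry-mass microcosm corresponds
to 6·24/1.5 = 96 µg g⁻¹ d⁻¹; with measurement noise the regression
recovers 96.7.

See `vignettes/peatmob-methods.Rmd` for the models, assumptions, defaults
and their rationale.

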