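# DiffCovBin

Differential-coverage genome binning and community profiling for
two-sample shotgun metagenomes.

## What it does, and for whom

When one metagenome co-assembly is sequenced under two conditions that
favour different organisms, every genome leaves a characteristic pair
of mean coverages on its scaffolds. `DiffCovBin` is for microbiome
researchers who want to turn such a two-condition assembly into
population genome bins and rank-level community profiles with a fully
scripted, deterministic workflow:

1. **Coverage** — per-scaffold mean depth per sample from BED-style
   per-base depth tables, normalized across samples by aligned-read
   counts (the sample with fewer aligned reads is the reference).
2. **Bin seeding** — density-based clustering of scaffolds in
   (log₁₀(c₁+0.1), log₁₀(c₂+0.1)) coverage space.
3. **Composition refinement** — canonical tetranucleotide frequencies
   (136 reverse-complement-collapsed 4-mers, each vector summing to 1)
   projected by within-cluster PCA; a secondary density clustering on
   the first 3 component scores splits genomes that share a coverage
   signature.
4. **Link recovery** — unbinned scaffolds join a bin when their summed
   paired-end link weight to it is ≥ 3 and uniquely maximal.
5. **Marker census** — completeness against a reference set of 105
   essential single-copy genes, `completeness(u) =
   round_half_up(100·u/105)`, plus two duplication summaries.
6. **Taxonomy** — mean nucleotide identity over essential genes with
   inclusive thresholds (≥95% species, ≥85% genus, ≥75% phylum) and a
   protein/placement consensus fallback below genus.
7. **Profiles & accounting** — clade tables
   (`k__Bacteria;p__...` lineages) rolled up to any rank and
   renormalized to 100% per sample; QC/host/annotation percentage
   reports with half-up rounding.

A seeded synthetic community generator (order-k Markov genomes with
exact GC targets, lognormal fragmentation, Poisson depth, planted
markers and links, full ground truth) ships as first-class,
tested code and drives the end-to-end validation.

## Worked example

Simulate a small two-genome, two-condition community and run the whole
pipeline:

```r
library(DiffCovBin)

spec <- CommunitySpec(data.frame(
    name = c("clostridium", "pantoea"), length = 4e5,
    gc = c(0.30, 0.55), markovOrder = 1L,
    cov_TW = c(120, 4), cov_AW = c(3, 90),
    nMarkers = c(105, 72), nDuplicated = 0L,
    fragMean = 8000, fragSigma = 0.5))

res <- runPipeline(runConfig(spec, seed = 1,
                             params = list(minSize = 1e5)))
res$binReport
#>   dataset   bin nScaffolds totalLength gcPercent essentialGenes completeness
#> 1      TW cov01         54       4e+05        30        105/105          100
#> 2      AW cov02         47       4e+05        55         72/105           69
#>   cov_TW cov_AW
#> 1     90      3
#> 2      3     90
res$evaluation$nRecovered
#> [1] 2
```

Reading the report: each genome came back as one bin on the correct
side of the coverage contrast (the `dataset` column names the sample
of maximal coverage). The genome carrying all 105 markers scores 100%
complete; the one planted with 72 markers scores 69% — the census
found 72 distinct markers and round-half-up(100·72/105) = 69. The
printed `cov_TW` of 90 (not 120) is the normalized value: the TW
sample had more aligned reads, so it is scaled by the aligned-read
ratio towards the AW reference. Both planted genomes were recovered at
purity 1.0 against the simulation's ground truth.

The packaged 13-genome community
(`witheringCommunitySpec()`) mirrors a published two-condition
grape-withering metagenome — scaffold counts, GC range 29–64%,
essential-gene counts and up to ~4000-fold coverage skew between
conditions — and is the fixture for the recovery tests.

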