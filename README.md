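# nichepack

Trait-based community assembly analysis with convex-hull null models.

`nichepack` is an R package for ecologists asking whether local communities
are assembled by **environmental filtering**, **limiting similarity**, or
neither, from two kinds of field data: specimen-level morphometric records
and site-by-species abundance matrices. It was built around a
small-mammal (shrew) metacommunity design — two ecoregions separated by a
dispersal barrier, ~30-species pool, 36 sites, per-site richness 4–12 — but
every stage is generic.

## What it computes

For each community (site) with richness *S*:

- **FRic** — functional richness: the volume of the convex hull of the
  community's species in a reduced trait space (PCoA of Gower distances on
  ten derived morphometric traits, up to 3 axes). Optionally standardized by
  the pool hull volume.
- **MNND** — mean nearest-neighbour distance: the mean over members of each
  species' smallest Gower distance to another member (niche packing).
- **SES** — standardized effect sizes against richness-preserving identity
  randomizations (default 1000), `SES = (obs − mean_null) / sd_null`, under
  four null variants: {total, regional} species pool × {unconstrained,
  hull-constrained} randomization (the constrained variant, which restricts
  candidate species to the community's own trait volume, applies to MNND).
- **Inference** — two-sided Wilcoxon signed-rank tests of SES against zero
  (exact for n ≤ 25, ties handled); type-II ANCOVA of metrics/SES on
  species richness × ecoregion; Pearson SES–richness correlations per
  ecoregion; Spearman correlation of functional peripherality (distance to
  the trait-space centroid) with average abundance.

A fully seeded **synthetic metacommunity generator** (`scenario_config()` /
`generate_metacommunity()`) emulates the study structure under neutral,
filtering and limiting-similarity assembly, so the entire pipeline is
testable without field data. Negative SES(FRic) is the filtering signature;
positive constrained SES(MNND) is the limiting-similarity signature (read it
against a neutral baseline — see the methods vignette for why).

## Worked example

```r
library(nichepack)

# a filtered metacommunity: 36 sites (15 CLF / 21 NLF), 30-species pool
meta <- generate_metacommunity(scenario_config(scenario = "filtering", seed = 7))
pipe <- run_pipeline(meta$records, meta$site_meta,
                     run_config(n_permutations = 999, seed = 3))
pipe$space
#> trait_space: 26 species on 3 axes (correction: sqrt, stress 0.272)

head(pipe$results[, c("site_id","metric","pool_definition","variant",
                      "richness","observed","ses")], 4)
#>   site_id metric pool_definition       variant richness  observed        ses
#> 1  CLF_01   FRic           total unconstrained        8 0.1132122 -1.2959368
#> 2  CLF_01   MNND           total unconstrained        8 0.1517569 -1.4576456
#> 3  CLF_01   MNND           total   constrained        8 0.1517569  0.4591794
#> 4  CLF_01   FRic        regional unconstrained        8 0.1132122 -1.0441326

summ <- inference_summary(pipe$results, meta$community$ecoregion)
subset(summ, test == "wilcoxon_ses" & metric == "FRic" & pool_definition == "total")
#>           test metric pool_definition       variant group  n statistic  p_value direction
#> 1 wilcoxon_ses   FRic           total unconstrained   CLF 15         2 1.83e-04        -1
#> 2 wilcoxon_ses   FRic           total unconstrained   NLF 21         0 9.54e-07        -1
```

Reading the output: observed FRic at `CLF_01` is 11% of the pool volume and
sits 1.30 null standard deviations *below* the identity-randomization
expectation (SES = −1.30); across sites the Wilcoxon tests reject SES = 0 in
both ecoregions with direction −1 — the generator's environmental filtering
is recovered as smaller-than-chance functional volumes. The same pipeline on
`scenario = "neutral"` data leaves these tests non-significant.

The species-level peripherality–abundance readout:

```r
centrality_abundance_correlation(pipe$space, meta$community)
#> Spearman rho = -0.364, p = 0.068, n = 26   (this run; sign as expected under
#>                                             filtering: peripheral species rarer)
```

## Command line

```sh
cli=$(Rscript -e 'cat(system.file("cli","nichepack",package="nichepack"))')
$cli synth --scenario filtering --seed 1 --out-dir data/
$cli nulls --specimens data/specimens.csv --sites data/sites.csv \
           --pool both --variant both --nperm 1000 --seed 42 --out results.csv
$cli stats --results results.csv --sites data/sites.csv --out stats.csv
```

## Documentation

The methods vignette
(`vignettes/community-assembly-methods.Rmd`) documents the models and their
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical conventions,
and known limitations (including the constrained null's positive bias under
neutral assembly).
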