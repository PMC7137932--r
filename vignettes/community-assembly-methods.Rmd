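---
title: "Trait-based community assembly: models, null models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based community assembly: models, null models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichepack)
```

## The scientific problem

When species richness varies among local communities, two non-exclusive
mechanisms can accommodate additional species: *niche expansion* (the
occupied volume of trait space grows) and *niche packing* (species pack more
densely into a fixed volume). Trait-based community ecology operationalizes
these with two statistics per community:

- **FRic** (functional richness): the Lebesgue measure of the convex hull of
  the community's species in a reduced trait space — the smallest convex
  volume containing all members.
- **MNND** (mean nearest-neighbour distance): the mean, over community
  members, of each species' smallest Gower distance to another member — an
  inverse measure of packing density.

Raw values of both statistics are confounded with species richness, so
inference runs through *null models*: species identities are randomized
against a species pool while holding each community's richness fixed, and
each observed value is expressed as a standardized effect size,

$$\mathrm{SES} = \frac{\mathrm{obs} - \overline{\mathrm{null}}}{\mathrm{SD}(\mathrm{null})},$$

with the sample (n−1) standard deviation. Negative SES(FRic) indicates a
smaller-than-chance trait volume (environmental filtering); positive
SES(MNND) indicates larger-than-chance spacing (limiting similarity).

The motivating system is a metacommunity of Congo Basin shrews: 36
pitfall-trapped communities in six localities, split between two ecoregions
(15 in central and 21 in northern lowland forests, CLF/NLF) separated by the
Congo River, with roughly 30 species in the combined pool and per-site
richness of about 4–12.

## From specimens to traits

Each captured individual carries ten measurements: five external (mass WT,
body length HB, tail T, hind foot HF, ear E) and five cranial
(condylo-incisive length CI, greatest skull width GW, interorbital width IW,
upper/lower tooth-row lengths UTR/LTR). Because most raw measurements scale
with body size, the analysis traits are WT, HB, CI plus seven ratios: T, HF
and E divided by HB; GW, IW, UTR and LTR divided by CI.

Within each species and trait, individual values outside the 1.5×IQR fences
(quartiles by linear interpolation, `quantile(type = 7)`) are discarded
before averaging — gross outliers are plausibly transcription errors or, for
mass, pregnancy. Three conventions here were genuinely open and are fixed as
follows:

- **Order of operations**: ratios are derived per individual first; outlier
  screening is applied to the derived traits, within species. Screening is
  *per trait*, so one aberrant measurement does not discard the whole
  specimen.
- **Species value**: arithmetic mean of surviving individuals, the
  functional-diversity-literature default; specimen counts are retained for
  audit.
- **Missing data**: carried through as `NA` (never zero) and handled by
  pairwise deletion in the Gower distance, rather than dropping specimens.

Fewer than four finite values make quartiles meaningless, so such groups are
never screened. The quartile convention matters: fences move under other
quantile types, which is why it is pinned and tested.

## Trait space, FRic and MNND

Pairwise species dissimilarity is the classic Gower distance:
range-normalized mean absolute difference over traits present in both
species, bounded in [0, 1]. Zero-range traits are uninformative and dropped
with a warning.

Convex hulls need Euclidean coordinates, so the Gower matrix is embedded by
classical PCoA. Gower matrices are usually not exactly embeddable; when
materially negative eigenvalues appear the square-root correction (PCoA of
$\sqrt{d}$) is applied, matching the behaviour of the standard
functional-diversity toolchain. A cleanly Euclidean input therefore embeds
exactly, with no correction. The embedding stress against the input
distances is reported on the `trait_space` object.

The number of retained axes follows `min(3, min community richness − 1)` by
default: a hull in m dimensions needs at least m + 1 affinely independent
points, and species-poor communities would otherwise lose FRic entirely.
FRic is optionally (default: yes) standardized by the pool hull volume,
giving values in (0, 1]; SES is invariant to this scaling. MNND is computed
on the raw Gower matrix, not the reduced coordinates, because it is defined
directly as a mean Gower distance; the reduction exists only for hulls and
hull membership.

Hull volumes and membership tests are computed in compiled code by
supporting-facet enumeration (dimensions 1–3; the default axis cap is 3, and
requesting FRic in higher dimensions is an error). Membership includes the
boundary — a community's own species must test inside their own hull — with
a small configurable slack (default `1e-9`, scaled by the coordinate range).
Degenerate (affinely dependent) point sets yield an undefined FRic rather
than an error, and degenerate hulls fall back to an affine-subspace
membership test.

## Null models

Four variants, crossed per community:

- **Pool definition** — *total* (all species in the study domain) or
  *regional* (the species recorded in the community's own ecoregion).
- **Randomization** — *unconstrained* (uniform richness-preserving draws
  from the pool, no abundance weighting) or *constrained* (draws restricted
  to pool species lying inside the focal community's empirical hull).

The constrained variant exists because a community whose volume is already
smaller than chance can hardly show larger-than-chance spacing against an
unconstrained pool; restricting candidates to the observed trait volume
isolates packing from volume effects. It is computed for MNND only: under
the constraint, every null community's hull is contained in the observed
hull, so null FRic can never exceed observed FRic and its SES is
uninformative (this bound is asserted in the test suite).

Permutations in which a null community's hull collapses are excluded from
the null mean/SD rather than redrawn (redrawing would bias the null toward
volume-rich configurations); the valid count is reported. A null SD of zero
(e.g. pool equal to community) leaves the SES undefined, flagged with a
reason, and per-site failures never abort a batch run.

Each (site × metric × pool × variant) cell derives its own RNG seed by
hashing the cell key into the base seed, so results are independent of
evaluation order and stable under site reordering; identical seed and
configuration give bit-identical output files.

### A caveat on the constrained null

The constrained null conditions on the observed community's hull. Because
the observed community always contains all of its own hull vertices, while
random draws from the constrained pool often replace a vertex with an
interior species (which necessarily has smaller nearest-neighbour
distances), the null MNND is systematically below the observed MNND *even
under neutral assembly*. At this study's pool sizes the effect is large
(median SES around +1.4 for neutral synthetic metacommunities in this
package's experiments). Two consequences, both visible in the test suite:

1. A positive constrained SES(MNND) alone does not demonstrate limiting
   similarity; only its magnitude relative to the neutral baseline does.
2. Calibration claims (mean SES ≈ 0, ~5% of |SES| > 1.96) hold for the
   unconstrained nulls — the distributions from which neutral communities
   are actually drawn — and are tested there.

Conversely, the empirical finding that motivates the constrained model —
observed constrained SES at or below zero — is strong evidence *against*
limiting similarity precisely because the statistic is biased upward.

## Inference

- **Wilcoxon signed-rank** (two-sided) tests whether SES distributions
  depart from zero. For n ≤ 25 the exact null distribution of the statistic
  is computed by the shift algorithm over doubled midranks — identical to
  enumerating all 2^n sign assignments, and exact under ties; beyond that, a
  normal approximation with continuity and tie corrections is used. Zero
  differences are dropped before ranking. Two-sided testing is the
  conservative reading of significance-star annotations whose direction is
  taken from the sign.
- **Type-II ANCOVA** fits the fully factorial least-squares model
  `response ~ richness * ecoregion`; each main effect is adjusted for the
  other main (interaction excluded), the interaction for both mains, with F
  against the full-model residual. Type II is appropriate for the unbalanced
  site design (15 vs 21). The implementation is verified against a
  nested-model refitting oracle to 1e-8.
- **Correlations**: Pearson r of SES against richness within each ecoregion;
  Spearman rank correlation between each species' distance to the pool
  centroid in trait space (functional peripherality) and its average
  abundance. "Average abundance" averages over all sites of the ecoregion(s)
  where the species occurs, zeros included — a regional mean-density proxy;
  an occupied-sites-only alternative is exposed as a flag. The Spearman p
  uses exact enumeration of rank permutations for n ≤ 10 (exact under ties)
  and the t approximation otherwise. No multiple-testing correction is
  applied anywhere; all p-values are reported raw.

## The synthetic generator: what it emulates, and what it does not

`generate_metacommunity()` reproduces the *structure* of the study system:
30-species pool; 36 sites as 15 CLF / 21 NLF across six localities (3 + 12
and 3 + 4 + 12 + 2); per-site richness uniform on [4, 12]; a dispersal
barrier sharing a configurable fraction (default 0.8) of the pool between
ecoregions; body-size allometry (log WT and log CI correlated ~0.8 with log
HB); ratio traits in plausible soricid ranges; ~5% multiplicative
measurement noise; a 2% rate of gross mass outliers (2.5×, the "pregnancy"
case); and log-series-like abundance variation with a floor of one capture
per occupied cell.

Assembly scenarios:

- *neutral* — uniform draws from the regional pool;
- *filtering* — draws weighted by
  $\exp(-d^2 / 2\sigma_f^2)$ toward the pool centroid (σ_f defaults to 0.1
  in range-normalized trait distance — strong filtering, chosen to emulate a
  clearly filtered metacommunity; the σ_f → 0 limit selects exactly the
  S most-central species);
- *limiting similarity* — greedy max-min spacing with a softmax temperature
  (default inverse temperature 30; the ∞ limit is strict farthest-point
  selection).

What the generator does **not** emulate: spatial structure within
ecoregions, phylogenetic signal in traits, trapping-effort variation,
observation error in identification, or refugial dynamics. A green
scenario-recovery test therefore establishes that the pipeline detects the
*designed* signatures at the configured strengths — not that the method
would detect weaker processes in real field data, and not anything about
shrew biology.

## Numerical conventions

- Hull tolerances: facet identification at `1e-9` × coordinate range;
  membership slack configurable (`hull_tolerance`, default `1e-9`).
- Session selection ties (two equally abundant single-season sessions) break
  to the lexicographically smallest session id, with a warning —
  reproducibility over arbitrariness.
- Results CSVs serialize numerics with 17 significant digits, so read-back
  is bit-exact.
- All randomness flows from explicit seeds; per-cell seeds are derived by a
  32-bit-safe polynomial hash of the cell key.

## Known limitations

- FRic (and hull-constrained pools) are limited to at most three embedding
  axes; this matches the default axis rule for species-poor communities but
  rules out high-dimensional hull analyses.
- The constrained null's neutral bias (above) means its SES should be read
  comparatively, not against zero.
- Communities below m + 1 species have no FRic; below 2, no MNND. They are
  flagged, not dropped silently.
- The generator's trait realism is deliberately loose; it exists to exercise
  the pipeline, not to model soricid evolution.
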