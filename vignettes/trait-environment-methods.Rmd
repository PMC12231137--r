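---
title: "Methods: community-weighted genomic traits, social niche breadth, and trait-environment models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community-weighted genomic traits, social niche breadth, and trait-environment models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`soiltraits` implements an analysis chain for soil 16S amplicon surveys that
links soil properties — pH above all — to genomic traits of the bacterial
and archaeal community: genome size, rRNA operon copy number, GC content,
and social niche breadth. This vignette is the package's account of the
methods: the models, their assumptions, the defaults and why they were
chosen, and what the synthetic validation does and does not demonstrate.

## Community preparation

Counts arrive as an ASV-by-sample integer matrix. Preparation is a fixed
order: organellar and non-prokaryotic taxa are removed first (`filter_taxa`:
any lineage containing Chloroplast or Mitochondria at any rank, or whose
domain is not Bacteria/Archaea; taxa missing from the taxonomy count as
unclassified domain and are removed); then samples under the read floor are
dropped (`filter_samples`, default 8000 reads); then every surviving sample
is rarefied to a common depth (`rarefy`, default 7555 reads). Rarefaction is
a single seed-controlled draw without replacement — standard single-
rarefaction practice; averaging over draws would shrink the sampling
variance the downstream models are supposed to see. Each column of the
rarefied table sums exactly to the depth, and per-taxon expectations follow
the hypergeometric mean, which the test suite checks against 500
independent draws.

Dissimilarity is Bray–Curtis, `1 - 2*sum(min(x,y))/(sum(x)+sum(y))`,
computed by the package and cross-checked in tests against both a
brute-force double loop and `vegan::vegdist`. Ordination is non-metric MDS
in 2 dimensions (the conventional choice for a single-panel ordination):
Kruskal stress-1 with monotone (isotonic) regression, best of 20 random
starts plus one metric-MDS-initialized start, ties handled by the primary
approach (tied dissimilarities receive averaged fitted values). The
`vegan::monoMDS` engine provides the stress machinery; the restart policy
and the argmin-over-starts contract are the package's.

Diversity is Gini–Simpson, `1 - sum(p_i^2)`. "Simpson's diversity" is
ambiguous between `sum(p^2)`, its complement and its inverse; the
complement is used because it increases with evenness, which matches the
direction in which diversity is discussed alongside pH in this literature.

The phylum-level screen regresses phylum relative abundances against every
numeric soil variable with Spearman's rho and applies Benjamini–Hochberg
adjustment across all (phylum, variable) pairs before assigning
significance stars at 0.05/0.01/0.001. Whether to adjust at all was an open
choice; BH across the full screen is the defensible default for a
many-hypothesis display, and stars are deliberately placed on the adjusted
values.

## Trait assignment by rank fallback

The trait reference is a table of (taxon name, rank, genome size, rRNA
copies, GC, coding density) rows, typically genus- and family-level
summaries of a genome database. `build_reference_index` collapses duplicate
rows for the same (name, rank) by the arithmetic mean (median available via
`stat`); when lineage columns are present, rows also aggregate upward, so a
genus genome contributes to its family's mean. The summary statistic at a
rank is not dictated by any external convention; the mean was chosen and
the median kept one keyword away.

`assign_traits` walks, per ASV and per trait independently, from the lowest
classified rank upward (genus, family, order, class, phylum, domain) and
takes the first rank at which the reference holds a value, recording that
rank as the trait's provenance. Per-trait independence (a genus may supply
GC while its family supplies genome size) maximizes annotation coverage
without inventing joint constraints. Exhausted walks leave the trait
missing with provenance `unassigned` — missing is a value, not an error.

Database and externally predicted rRNA copy numbers are merged by
`consensus_rrna` as their arithmetic mean, kept fractional, with provenance
`consensus`. A consensus rule had to be fixed; the mean is symmetric,
order-free and preserves information from both sources, and the choice is
surfaced here rather than buried. Non-positive predictions are rejected
with a warning.

Community-weighted means (`weighted_sample_traits`) renormalize weights
over the annotated taxa with positive count, rather than treating missing
traits as zeros, which would bias means toward zero exactly in the
poorly-annotated samples where caution is most needed. Per-sample read
coverage of each trait is recorded, and samples under a configurable floor
(default 50% of reads annotated) are set to missing so downstream models
refuse them. Every weighted mean is asserted, on every call, to lie within
the range of its contributing per-taxon values. Coding density is carried
through I/O but feeds no model.

## Social niche breadth

SNB scores generalism from co-occurrence: `SNB(a)` is the mean Bray–Curtis
dissimilarity between all unordered pairs of samples in which taxon `a` is
present. Profiles are ASV-level relative abundances with the focal taxon
included; the aggregation rank and the dissimilarity are configuration
knobs (`sample_profiles(rank=)`, `snb_scores(dissimilarity=)`) because the
choice is genuinely open — different profile resolutions emphasize
different co-occurrence structure — and the defaults are simply declared.
A taxon present in fewer than 2 samples has no pair to average and its
score is missing, not zero: zero would conflate rarity with extreme
specialism. No renormalization is applied beyond the natural [0, 1] range
of the dissimilarity. Sample-level `ave.snb` is the count-weighted mean
over score-carrying taxa.

## Phylogenetics

`neighbor_joining` is the classic Saitou–Nei agglomeration with the
Q-criterion. Negative branch lengths — an artifact the algorithm permits —
are clamped to zero with the deficit moved to the sister branch, preserving
the pair's summed length. On additive matrices the output reproduces the
input distances exactly (tested to 1e-9), and the topology is cross-checked
against `ape::nj`.

Phylofactorization greedily selects tree edges whose induced contrast best
explains a covariate. Candidate edges at each step are those whose tip
bipartition cuts exactly one current bin non-trivially; this guarantees the
successive contrasts form a sequential binary partition, i.e. mutually
orthogonal ILR sign vectors (asserted in tests). Two objectives are
implemented because the underlying regression direction — abundances
against a per-taxon score — does not map uniquely onto the standard
sample-covariate formulation:

* **taxon mode** (default): the covariate lives on taxa (e.g. SNB); the
  objective is the absolute pooled two-sample t statistic between the
  edge's two groups within the bin, with the two-sided t-test p-value.
* **sample mode**: the covariate lives on samples (e.g. pH); the objective
  is the F statistic of regressing the groups' ILR balance on the
  covariate.

Both are exposed; taxon mode is the default and is this package's
concretization, documented as such rather than asserted as anyone else's
exact computation. The default run extracts 15 factors at a significance
threshold of 0.01. Balances add a pseudocount of 1 before closure
(configurable); zero handling in log-ratio analysis has no canonical
answer, and 1 on rarefied counts of several thousand reads is a small
perturbation. For reporting, factor balances are stratified by high versus
low community niche breadth using the median of the per-sample weighted
mean SNB.

Blomberg's K and Pagel's λ need a covariance matrix of shared path lengths,
which requires a root; unrooted trees are midpoint rooted solely to define
that covariance (a convention, stated rather than hidden). K follows the
standard ratio-of-mean-squares form scaled by its Brownian expectation, so
K = 1 exactly on a star tree for any data (an algebraic identity the tests
assert); significance comes from tip-label permutations (default 999, the
observed labelling included in the numerator and denominator). λ scales the
off-diagonal covariance and is maximized over [0, 1] by bounded scalar
optimization at tolerance 1e-6 with both endpoints checked explicitly,
since the profile likelihood is frequently maximized at a boundary. PGLS
estimates λ the same way over the regression model when it is not supplied
and reports Wald t-tests on n − p degrees of freedom. All three are
cross-checked in tests against `picante` and `phytools`.

## Trait–environment models

`linear_fit` is ordinary least squares with the two-sided slope t-test,
reporting plain and adjusted R². `fit_additive_model` fits penalized
thin-plate regression splines with smoothing chosen by generalized
cross-validation (`mgcv::gam`, `method = "GCV.Cp"`), Gaussian family and
identity link — the responses (pH, ave.snb) are continuous and
unbounded-in-practice, and GCV is the classical criterion matching the
reported GCV scores. Basis dimension defaults to 10 per smooth. The
summary surface is the standard GAM one: per-term edf, reference df,
approximate F and p, intercept ± SE, adjusted R², % deviance explained,
GCV and n.

`model_battery` runs the two headline formulas —
`pH ~ s(Organic_Matter_LOI) + s(ave.gs) + s(ave.rrna) + s(ave.gc)` and
`ave.snb ~ s(Organic_Matter_LOI) + s(pH) + s(ave.gs) + s(ave.rrna) +
s(ave.gc)` — plus four simple regressions (pH on OM, genome size on rRNA
copies, Simpson diversity on pH, ave.snb on genome size). Within each
additive model, term p-values are additionally BH-adjusted across the
model's terms ("adjusted P" is interpreted as within-model BH; this is an
interpretation, flagged as such) and starred on the adjusted values.

## The synthetic generator

`generate_dataset` emulates a managed-soil survey with planted truth:

* ~245 samples with pH uniform on 5.6–8.7 and organic matter
  `om = 2.5 + 0.725*pH + N(0, 2.2^2)` — the slope chosen so the expected
  squared correlation with pH is ≈ 0.08, a weak positive coupling
  (tested to land in [0.02, 0.20]).
* 300 taxa with Gaussian pH niches: expected relative abundance of taxon
  *i* in sample *s* proportional to `exp(-(pH_s - opt_i)^2 / (2 sigma_i^2))`
  times lognormal noise (sdlog 0.6), integer counts multinomial at
  lognormal depths (mean 20 000), with at least two samples forced below
  8000 reads so the read filter always has work. Gaussian niches are the
  simplest unimodal response consistent with pH structuring; nothing
  downstream depends on the exact response shape.
* niche widths: generalists (fraction 0.3) around sigma 1.3 pH units,
  specialists around 0.45, both with lognormal spread, multiplied by
  `exp(-0.25*(opt_i - 7.15))` so niches widen toward acid optima — the
  configuration under which community niche breadth declines with pH.
* traits tied to the optimum: genome size `4.9 Mb - 350 kb/pH * (opt - 5.5)`
  plus 150 kb noise (spanning roughly 3.2–4.9 Mb), GC increasing at
  3 %/pH-unit, rRNA copies a clipped affine function of genome size
  (integer truth in [1, 15]).
* a Yule phylogeny with pH optima evolved as Brownian motion along it
  (affine rescaling preserves the Brownian covariance structure), so the
  phylofactor and signal stages have recoverable planted structure;
  `phylo_signal = FALSE` shuffles optima across tips for null testing, and
  `generalist_clade_fraction > 0` plants the generalists as a single clade.
* SILVA-style taxonomy (genera nested five per family, three ASVs per
  genus), a 25% chance per ASV of an unclassified genus, a reference
  covering 70% of genera at genus rank with family aggregates for the
  rest (so the fallback rank of every ASV is known by construction), a
  small archaeal fraction, and a handful of off-tree chloroplast /
  mitochondria / eukaryote contaminants for the taxon filter.

One consequence of this design shows up in the phylofactor report: under
the defaults, the per-taxon SNB distribution is left-skewed — most taxa sit
near the Bray–Curtis ceiling of the survey while specialists form a
distinctive low tail — so the strongest contrasts split off *low*-SNB
groups, and the high-SNB factor count reported by the acceptance script is
typically zero. A more symmetric generalist/specialist balance (or planting
the generalists as a clade) moves that count up; the statistic describes
the data's shape, not a fixed property of the method.

What the generator does **not** emulate: sequence-level error, chimeras,
compositional bias from copy-number variation in the 16S marker itself,
spatial or farm-level autocorrelation, covariance between soil nutrients
and community structure beyond pH, or realistic zero-inflation beyond what
Gaussian niches and multinomial sampling produce. Passing tests therefore
demonstrate that the pipeline's computations are correct and that planted
effects of realistic direction and magnitude are recovered — not that any
particular field dataset will show those effects.

## Calibration and a caution about nulls

The test suite calibrates each stage under its own model: mean Blomberg's K
within [0.85, 1.15] over 200 Brownian simulations on a 128-tip tree;
λ endpoint recovery at 200 tips; the additive model recovering edf ≈ 1 and
≥ 95% deviance on linear truth and staying quiet (≤ 10% of seeds with any
term at p < 0.01) on pure noise at n = 200 over 50 seeds.

One null deserves emphasis. Zeroing the generator's trait slopes does
**not** produce a null for the trait–pH models: as long as composition is
pH-structured, the community-weighted mean of *any* fixed per-taxon values
is a smooth function of pH, and the models correctly detect it. A true
null requires flattening the niches as well (all generalists with very
wide sigma), which is what the package's null-configuration test uses.
This is a property of community-weighted means worth remembering when
interpreting real data: a significant trait smooth is evidence of
pH-structured trait composition, not by itself of any particular
trait-assembly mechanism.

## Problem sizes and determinism

The default validation sizes — 300 taxa by 245 samples end-to-end, 128–200
tips for signal calibration, 40 tips for planted-clade recovery over five
seeds, 500 draws for the rarefaction expectation — keep the full suite
under a minute or two on a single core while leaving the stochastic
assertions comfortable margins. All randomness flows from explicit seeds;
`run_pipeline` writes a manifest of config, seeds and per-artifact md5
digests, and reruns with the same seed reproduce identical digests.

## Known limitations

* Trait assignment inherits every bias of the reference: taxa whose genus
  is absent get family-level averages, which compress true variation, and
  provenance should be inspected (`*_rank` columns) before interpreting
  fine differences in community means.
* SNB depends on the sample set: the same taxon scores differently in a
  survey spanning a broader environmental range. Scores are comparable
  within one dataset, not across datasets.
* Phylofactor p-values are per-edge test statistics reported at selection
  time and are not corrected for the edge search; with the default alpha
  of 0.01 they serve as a selection threshold, not inferential p-values.
* The midpoint-rooting convention for the signal covariance is one of
  several defensible choices; trees with strongly asymmetric depth may
  warrant an outgroup-rooted covariance instead.
* NMDS stress depends on the restart budget; pathological landscapes may
  need more than the default 20 restarts.
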