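# soiltraits

Soil pH is a dominant axis of variation for soil bacterial communities, and
it reaches past composition into the genomes themselves: communities in more
acidic soils tend to carry larger genomes (metabolic versatility), more rRNA
operon copies (growth-rate potential) and broader ecological niches, while
high-pH communities trend smaller, GC-richer and more specialized.
`soiltraits` is an R package for testing exactly these relationships in
16S amplicon surveys of soils. It is aimed at microbial ecologists who have
an ASV count table, a ranked taxonomy, soil chemistry measurements and
(optionally) a phylogeny, and who want per-sample community-weighted
genomic traits and niche-breadth scores, with the statistics to connect them
to soil properties.

## What it computes

**Community-weighted mean traits.** Each ASV is assigned a genome size, rRNA
copy number and GC content from a trait reference table by iterative
taxonomic-rank fallback: the genus value if the reference has one, else the
family, and so on up to domain, independently per trait. Database rRNA
values can be averaged with externally predicted per-ASV copies into a
consensus. Per sample, the community-weighted mean of trait *t* is

    ave.t(s) = sum_i n_is * t_i / sum_i n_is

over annotated taxa with positive rarefied count `n_is` (weights
renormalized over the annotated subset).

**Social niche breadth (SNB).** A per-taxon generalism score: the mean
Bray–Curtis dissimilarity among all pairs of samples in which the taxon
occurs. Taxa recurring across dissimilar communities score high
(generalists); taxa confined to similar communities score low (specialists).
Sample-level `ave.snb` is the abundance-weighted mean.

**Phylofactorization and phylogenetic signal.** Greedy selection of tree
edges whose isometric log-ratio contrast

    y_j = sqrt(rs/(r+s)) * ln( gm_R(j) / gm_S(j) )

best separates a covariate (per-taxon SNB by default), partitioning taxa
into bins; plus Blomberg's K (permutation-tested) and Pagel's λ (profile
ML) for the phylogenetic signal of tip traits, and PGLS regression.
Neighbor-joining tree construction from a distance matrix is included.

**Trait–environment models.** Simple linear regressions and penalized
additive models with GCV smoothing selection, reporting the standard GAM
summary surface (per-term edf, F, p; adjusted R²; % deviance explained;
GCV), e.g. `pH ~ s(Organic_Matter_LOI) + s(ave.gs) + s(ave.rrna) + s(ave.gc)`.

**Synthetic communities with known truth.** A generator of pH-structured
communities — Gaussian pH niches of heterogeneous width on a Yule phylogeny
with Brownian pH optima, trait gradients along the optimum, multinomial
reads, SILVA-style taxonomy with unclassified genera, and a partially
incomplete trait reference — so every stage can be validated against
planted ground truth.

## Worked example

```r
library(soiltraits)
options(soiltraits.log_level = "warn")

dat <- generate_dataset(generator_config(seed = 1))   # 300 taxa, 245 samples
counts <- filter_samples(filter_taxa(dat$counts, dat$taxonomy), 8000)
counts <- rarefy(counts, 7555, seed = 1)

idx  <- build_reference_index(dat$reference)
asgn <- consensus_rrna(assign_traits(dat$taxonomy, idx), dat$predicted_rrna)
snb  <- snb_scores(counts)
prof <- weighted_sample_traits(counts, asgn, snb = snb)

m <- model_battery(prof, dat$metadata)
print(m$gam_ph)
```

```
Additive model: pH ~ s(Organic_Matter_LOI) + s(ave.gs) + s(ave.rrna) + s(ave.gc)
(Intercept) 7.1844  (SE 0.00547)
Approximate significance of smooth terms:
                  term   edf ref_df       F  p_value stars
 s(Organic_Matter_LOI) 1.000  1.000   0.027 8.70e-01
             s(ave.gs) 3.638  4.670   8.802 6.52e-07   ***
           s(ave.rrna) 6.375  7.531 179.224 0.00e+00   ***
             s(ave.gc) 4.222  5.332   1.045 3.81e-01
R-sq.(adj) = 0.989; deviance explained = 99.0%
GCV = 0.007802; n = 243
```

Two of the 245 simulated samples fall below the 8000-read floor, leaving
n = 243. The community-weighted rRNA and genome-size smooths dominate the
pH model — the planted structure (larger genomes and more rRNA copies
toward acid soils) read back through the full annotation pipeline. On the
same run, `cor(pH, ave.gs) = -0.95`, `cor(ave.gs, ave.rrna) = 0.96` and
`cor(pH, ave.snb) = -0.45`: acid-soil communities are large-genomed,
rRNA-rich and broader-niched.

A one-command version of the whole analysis (with all artifacts and a
reproducibility manifest written to disk) is:

```r
res <- run_pipeline(default_pipeline_config(seed = 1), out_dir = "run1")
```

or, from a shell, `Rscript inst/scripts/soiltraits-pipeline.R --seed 1
--out-dir run1`.

## Vignette

`vignettes/trait-environment-methods.Rmd` documents the models and their
assumptions, the generator's design (what it emulates and what it leaves
out), numerical conventions, and known limitations.
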