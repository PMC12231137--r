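# Synthetic pH-structured soil communities with known ground truth.
#
# The generator emulates the statistical structure of a managed-soil survey:
# ~245 samples spanning pH 5.6-8.7 with organic matter weakly and positively
# coupled to pH (target squared Pearson correlation ~0.08); taxa with Gaussian
# pH niches of heterogeneous width (generalists vs specialists); genome size
# decreasing and GC increasing with a taxon's pH optimum; rRNA copy number an
# increasing (clipped affine) function of genome size; a Yule phylogeny with
# pH optima evolved as Brownian motion along it. Every stage of the pipeline
# is therefore testable against planted truth.

#' Generator configuration
#'
#' Returns the default configuration for [generate_dataset()], with any field
#' overridden by name. Defaults ARE the emulated study conditions; see the
#' methods vignette for the rationale behind each value.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `generator_config`.
#' @details Key fields:
#' \describe{
#'   \item{n_taxa, n_samples}{Community size (default 300 taxa, 245 samples).}
#'   \item{mean_depth, depth_sdlog}{Lognormal read-depth distribution
#'     (default mean 20000); `n_low_depth` samples (default 2) are forced
#'     below 8000 reads so the read filter is exercised.}
#'   \item{ph_range}{Uniform sample pH range, default `c(5.6, 8.7)`.}
#'   \item{om_ph_slope, om_noise_sd}{Organic-matter model
#'     `om = a + b*pH + N(0, sd)`; the default slope gives an expected
#'     squared correlation with pH of ~0.08.}
#'   \item{b_gs, b_gc, b_rrna}{Trait slopes: genome size (bp lost per pH unit
#'     of optimum), GC (percent gained per pH unit), rRNA copies per Mb of
#'     genome.}
#'   \item{generalist_fraction}{Probability a taxon is a generalist
#'     (wide niche), default 0.3.}
#'   \item{snb_ph_coupling}{Exponential widening of niches toward low pH
#'     optima (wider niches in acid soils), default 0.25 per pH unit.}
#'   \item{p_unclassified_genus}{Per-ASV probability the genus (and species)
#'     rank is unclassified, default 0.25.}
#'   \item{reference_coverage}{Fraction of genera with their own reference
#'     rows; remaining genera are covered only at family rank, default 0.7.}
#'   \item{n_contaminants}{Extra chloroplast/mitochondria/eukaryote ASVs
#'     appended so the taxon filter has work to do, default 6.}
#'   \item{archaea_fraction}{Fraction of taxa labelled Archaea
#'     (Crenarchaeota), default 0.05.}
#'   \item{phylo_signal}{If `FALSE`, pH optima are shuffled across tips,
#'     destroying phylogenetic signal (null configuration).}
#'   \item{generalist_clade_fraction}{If `> 0`, generalists are planted as a
#'     clade of roughly this tip fraction instead of at random, giving
#'     phylofactorization a recoverable target. Default 0 (random).}
#'   \item{seed}{Integer seed driving all randomness.}
#' }
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_taxa = 300L,
    n_samples = 245L,
    mean_depth = 20000,
    depth_sdlog = 0.25,
    n_low_depth = 2L,
    low_depth_range = c(4000, 7500),
    ph_range = c(5.6, 8.7),
    om_intercept = 2.5,
    om_ph_slope = 0.725,
    om_noise_sd = 2.2,
    gs_intercept = 4.9e6,
    b_gs = 3.5e5,
    gs_noise_sd = 1.5e5,
    gc_intercept = 50,
    b_gc = 3,
    gc_noise_sd = 1.5,
    b_rrna = 2.9,          # copies gained per Mb of genome
    rrna_noise_sd = 0.6,
    generalist_fraction = 0.3,
    sigma_generalist = 1.3,
    sigma_specialist = 0.45,
    sigma_sdlog = 0.15,
    snb_ph_coupling = 0.25,
    abundance_noise_sdlog = 0.6,
    genera_per_family = 5L,
    asvs_per_genus = 3L,
    p_unclassified_genus = 0.25,
    reference_coverage = 0.7,
    n_contaminants = 6L,
    archaea_fraction = 0.05,
    phylo_signal = TRUE,
    generalist_clade_fraction = 0,
    seed = 1L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown generator config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  validate_generator_config(structure(cfg, class = "generator_config"))
}

validate_generator_config <- function(cfg) {
  if (cfg$n_taxa < 2L || cfg$n_samples < 2L)
    stop("generator config: n_taxa and n_samples must be >= 2")
  fracs <- c(cfg$generalist_fraction, cfg$p_unclassified_genus,
             cfg$reference_coverage, cfg$archaea_fraction,
             cfg$generalist_clade_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("generator config: fractions must lie in [0, 1]")
  if (cfg$mean_depth < cfg$n_taxa)
    stop("generator config: mean depth below n_taxa is infeasible")
  cfg
}

#' Generate a synthetic soil community dataset with ground truth
#'
#' Draws sample pH and organic matter, taxon niches and genomic traits, a
#' Yule phylogeny with Brownian pH optima, multinomial read counts at
#' lognormal depths, a SILVA-style taxonomy with unclassified genera, and a
#' partially incomplete trait reference (genus rows for covered genera,
#' family aggregates for the rest). All randomness is driven by `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list with elements `counts` (taxa x samples integer matrix),
#'   `taxonomy`, `metadata`, `reference`, `predicted_rrna`, `tree`
#'   (tips = the `n_taxa` niche taxa; contaminants are not on the tree),
#'   and `truth` (list of per-taxon and per-sample truth tables).
#' @export
generate_dataset <- function(config = generator_config()) {
  cfg <- validate_generator_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_taxa; m <- cfg$n_samples

  ## --- samples: pH uniform, OM weakly positively coupled to pH ------------
  sample_id <- sprintf("S%03d", seq_len(m))
  ph <- stats::runif(m, cfg$ph_range[1L], cfg$ph_range[2L])
  om <- cfg$om_intercept + cfg$om_ph_slope * ph +
    stats::rnorm(m, 0, cfg$om_noise_sd)
  om <- pmax(om, 1.0)
  rotation <- sample(c("arable", "mixed", "grass"), m, replace = TRUE,
                     prob = c(0.87, 0.06, 0.07))
  sand <- stats::runif(m, 20, 70)
  clay <- stats::runif(m, 10, pmin(40, 95 - sand))
  silt <- 100 - sand - clay
  metadata <- data.frame(
    sample_id = sample_id, pH = round(ph, 3), om_loi = round(om, 3),
    phosphorus = round(stats::rlnorm(m, log(30), 0.4), 1),
    potassium = round(stats::rlnorm(m, log(150), 0.4), 1),
    magnesium = round(stats::rlnorm(m, log(80), 0.4), 1),
    sand = round(sand, 1), silt = round(silt, 1), clay = round(clay, 1),
    rotation = rotation, stringsAsFactors = FALSE)

  ## --- phylogeny and Brownian pH optima ------------------------------------
  taxon_id <- sprintf("ASV%04d", seq_len(n))
  tree <- ape::rphylo(n, birth = 1, death = 0)   # Yule
  tree$tip.label <- taxon_id[as.integer(sub("^t", "", tree$tip.label))]
  bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  bm <- bm[taxon_id]
  # affine map preserves the Brownian covariance structure
  mid <- mean(cfg$ph_range)
  opt <- mid + (bm - mean(bm)) / stats::sd(bm) * 0.85
  if (!cfg$phylo_signal) {
    names_save <- names(opt)
    opt <- sample(opt)
    names(opt) <- names_save
  }

  ## --- niche widths: generalists vs specialists ----------------------------
  if (cfg$generalist_clade_fraction > 0) {
    generalist <- plant_clade(tree, cfg$generalist_clade_fraction)[taxon_id]
  } else {
    generalist <- stats::runif(n) < cfg$generalist_fraction
    names(generalist) <- taxon_id
  }
  base_sigma <- ifelse(generalist, cfg$sigma_generalist, cfg$sigma_specialist)
  sigma <- base_sigma * stats::rlnorm(n, 0, cfg$sigma_sdlog) *
    exp(-cfg$snb_ph_coupling * (opt - mid))
  sigma <- pmax(sigma, 0.1)

  ## --- genomic traits tied to the pH optimum -------------------------------
  gs <- cfg$gs_intercept - cfg$b_gs * (opt - 5.5) +
    stats::rnorm(n, 0, cfg$gs_noise_sd)
  gs <- round(pmin(pmax(gs, 2.2e6), 5.6e6))
  gc <- cfg$gc_intercept + cfg$b_gc * (opt - mid) +
    stats::rnorm(n, 0, cfg$gc_noise_sd)
  gc <- pmin(pmax(gc, 25), 75)
  rrna <- 1 + cfg$b_rrna * (gs - 3.0e6) / 1e6 + stats::rnorm(n, 0, cfg$rrna_noise_sd)
  rrna <- as.integer(round(pmin(pmax(rrna, 1), 15)))

  ## --- taxonomy: genera nested in families, some genera unclassified -------
  n_genera <- ceiling(n / cfg$asvs_per_genus)
  genus_of <- rep(seq_len(n_genera), each = cfg$asvs_per_genus)[seq_len(n)]
  family_of_genus <- rep(seq_len(ceiling(n_genera / cfg$genera_per_family)),
                         each = cfg$genera_per_family)[seq_len(n_genera)]
  genus_names <- sprintf("Genus%03d", seq_len(n_genera))
  family_names <- sprintf("Family%03d", seq_len(max(family_of_genus)))
  n_arch <- round(cfg$archaea_fraction * n)
  is_arch <- seq_len(n) <= n_arch     # first taxa archaeal (arbitrary, fixed)
  phylum_pool_b <- c("Actinobacteriota", "Proteobacteria", "Acidobacteriota",
                     "Chloroflexi", "Verrucomicrobiota", "Firmicutes",
                     "Bacteroidota", "Planctomycetota", "Myxococcota",
                     "Nitrospirota")
  fam_phylum <- sample(phylum_pool_b, max(family_of_genus), replace = TRUE)
  phylum <- ifelse(is_arch, "Crenarchaeota", fam_phylum[family_of_genus[genus_of]])
  uncl_genus <- stats::runif(n) < cfg$p_unclassified_genus
  taxonomy <- data.frame(
    taxon_id = taxon_id,
    domain = ifelse(is_arch, "Archaea", "Bacteria"),
    phylum = phylum,
    class = paste0(phylum, "_c"),
    order = paste0(phylum, "_o"),
    family = family_names[family_of_genus[genus_of]],
    genus = ifelse(uncl_genus, "unclassified", genus_names[genus_of]),
    species = ifelse(uncl_genus, "unclassified",
                     paste0(genus_names[genus_of], "_sp")),
    stringsAsFactors = FALSE)

  ## --- trait reference: genus rows for covered genera, family aggregates ---
  covered <- stats::runif(n_genera) < cfg$reference_coverage
  # per-genus "database genome" values: mean of member truths + small noise
  agg <- function(v, idx, keep) {
    out <- tapply(v, idx, mean)
    out[as.character(which(keep))]
  }
  ref_rows <- list()
  if (any(covered)) {
    g_gs <- agg(gs, genus_of, covered); g_gc <- agg(gc, genus_of, covered)
    g_rr <- agg(rrna, genus_of, covered)
    ref_rows$genus <- data.frame(
      taxon_name = genus_names[covered], rank = "genus",
      genome_size = round(g_gs * stats::rlnorm(sum(covered), 0, 0.01)),
      rrna_copies = round(pmax(1, g_rr + stats::rnorm(sum(covered), 0, 0.1)), 2),
      gc = round(g_gc + stats::rnorm(sum(covered), 0, 0.2), 2),
      coding_density = round(stats::runif(sum(covered), 85, 92), 2),
      family = family_names[family_of_genus[covered]],
      stringsAsFactors = FALSE)
  }
  # family rows cover every family (fallback target for uncovered genera)
  f_of <- family_of_genus[genus_of]
  f_gs <- tapply(gs, f_of, mean); f_gc <- tapply(gc, f_of, mean)
  f_rr <- tapply(rrna, f_of, mean)
  fam_idx <- sort(unique(f_of))
  ref_rows$family <- data.frame(
    taxon_name = family_names[fam_idx], rank = "family",
    genome_size = round(as.numeric(f_gs)),
    rrna_copies = round(as.numeric(f_rr), 2),
    gc = round(as.numeric(f_gc), 2),
    coding_density = round(stats::runif(length(fam_idx), 85, 92), 2),
    family = family_names[fam_idx],
    stringsAsFactors = FALSE)
  reference <- do.call(rbind, ref_rows)
  rownames(reference) <- NULL

  predicted_rrna <- data.frame(
    taxon_id = taxon_id,
    rrna_predicted = round(pmax(1, rrna + stats::rnorm(n, 0, 0.5)), 2),
    stringsAsFactors = FALSE)

  ## --- counts: Gaussian pH niches, lognormal noise, multinomial reads ------
  depth <- round(stats::rlnorm(m, log(cfg$mean_depth), cfg$depth_sdlog))
  if (cfg$n_low_depth > 0L) {
    low <- sample.int(m, cfg$n_low_depth)
    depth[low] <- round(stats::runif(cfg$n_low_depth,
                                     cfg$low_depth_range[1L],
                                     cfg$low_depth_range[2L]))
  }
  lam <- exp(-outer(opt, ph, function(o, p) (p - o)^2) / (2 * sigma^2))
  lam <- lam * matrix(stats::rlnorm(n * m, 0, cfg$abundance_noise_sdlog), n, m)
  counts <- matrix(0L, n, m, dimnames = list(taxon_id, sample_id))
  for (j in seq_len(m)) {
    pj <- lam[, j] / sum(lam[, j])
    counts[, j] <- as.integer(stats::rmultinom(1L, depth[j], pj))
  }

  ## --- contaminants appended off-tree --------------------------------------
  if (cfg$n_contaminants > 0L) {
    nc <- cfg$n_contaminants
    kinds <- rep(c("chloroplast", "mitochondria", "eukaryote"), length.out = nc)
    cid <- sprintf("CONT%02d", seq_len(nc))
    ctax <- data.frame(
      taxon_id = cid,
      domain = ifelse(kinds == "eukaryote", "Eukaryota", "Bacteria"),
      phylum = ifelse(kinds == "eukaryote", "Eukaryota_p", "Cyanobacteria"),
      class = ifelse(kinds == "eukaryote", "Eukaryota_c", "Cyanobacteriia"),
      order = ifelse(kinds == "chloroplast", "Chloroplast", "Other_o"),
      family = ifelse(kinds == "mitochondria", "Mitochondria", "Other_f"),
      genus = "unclassified", species = "unclassified",
      stringsAsFactors = FALSE)
    ccounts <- matrix(stats::rpois(nc * m, 20), nc, m,
                      dimnames = list(cid, sample_id))
    storage.mode(ccounts) <- "integer"
    counts <- rbind(counts, ccounts)
    taxonomy <- rbind(taxonomy, ctax)
  }

  truth_taxa <- data.frame(
    taxon_id = taxon_id, pH_optimum = opt, niche_width = sigma,
    niche_class = ifelse(generalist, "generalist", "specialist"),
    genome_size = gs, rrna_copies = rrna, gc = round(gc, 3),
    genus = genus_names[genus_of], family = family_names[family_of_genus[genus_of]],
    genus_in_reference = covered[genus_of] & !uncl_genus,
    stringsAsFactors = FALSE)
  truth_samples <- data.frame(
    sample_id = sample_id, pH = ph, om_loi = om, depth = depth,
    stringsAsFactors = FALSE)

  list(counts = validate_count_table(counts), taxonomy = taxonomy,
       metadata = metadata, reference = reference,
       predicted_rrna = predicted_rrna, tree = tree,
       truth = list(taxa = truth_taxa, samples = truth_samples,
                    config = cfg))
}

# Pick the clade whose tip count is closest to `fraction` of all tips;
# returns a named logical over tip labels (TRUE inside the clade).
plant_clade <- function(tree, fraction) {
  n <- length(tree$tip.label)
  target <- fraction * n
  parts <- ape::prop.part(tree)
  sizes <- lengths(parts)
  keep <- which(sizes < n)                       # exclude the root "clade"
  best <- keep[which.min(abs(sizes[keep] - target))]
  inside <- tree$tip.label %in% tree$tip.label[parts[[best]]]
  names(inside) <- tree$tip.label
  inside
}

#' Export generator ground truth as TSV tables
#'
#' Writes per-taxon truth (pH optimum, niche width and class, genomic traits)
#' and per-sample truth (pH, organic matter, read depth) for recovery tests.
#'
#' @param truth The `truth` element of [generate_dataset()]'s result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths written.
#' @export
truth_report <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- file.path(dir, "truth_taxa.tsv")
  ps <- file.path(dir, "truth_samples.tsv")
  utils::write.table(truth$taxa, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$samples, ps, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pt, ps))
}
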