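# Community filtering, rarefaction, dissimilarity, ordination and screens.
#
# Pipeline order is filter_taxa -> filter_samples -> rarefy; rarefy() enforces
# the read floor and each step logs what it removed.

#' Remove organellar and non-prokaryotic taxa
#'
#' Drops taxa whose lineage contains "Chloroplast" or "Mitochondria" at any
#' rank, and taxa whose domain is neither Bacteria nor Archaea (taxa missing
#' from the taxonomy count as unclassified domain and are removed). Removal
#' counts are logged.
#'
#' @param counts Count matrix (taxa x samples).
#' @param taxonomy Taxonomy `data.frame` (taxon_id + 7 ranks).
#' @return Filtered count matrix.
#' @export
filter_taxa <- function(counts, taxonomy) {
  counts <- validate_count_table(counts)
  tax <- taxonomy[match(rownames(counts), taxonomy$taxon_id), , drop = FALSE]
  lineage <- as.matrix(tax[RANKS])
  lineage[is.na(lineage)] <- "unclassified"
  organellar <- apply(lineage, 1L, function(z)
    any(z %in% c("Chloroplast", "Mitochondria")))
  prokaryote <- lineage[, "domain"] %in% c("Bacteria", "Archaea")
  keep <- prokaryote & !organellar
  st_log("info", "filter_taxa: removed ", sum(!keep), " of ", nrow(counts),
         " taxa (", sum(organellar), " organellar, ",
         sum(!prokaryote), " non-prokaryotic); ",
         sum(counts[!keep, , drop = FALSE]), " reads dropped")
  if (!any(keep)) stop("filter_taxa removed every taxon")
  counts[keep, , drop = FALSE]
}

#' Remove low-depth samples
#'
#' Drops samples whose total read count is below `min_reads` (default 8000).
#'
#' @param counts Count matrix.
#' @param min_reads Minimum column sum to retain a sample.
#' @return Filtered count matrix.
#' @export
filter_samples <- function(counts, min_reads = 8000) {
  counts <- validate_count_table(counts)
  keep <- colSums(counts) >= min_reads
  st_log("info", "filter_samples: removed ", sum(!keep), " of ", ncol(counts),
         " samples below ", min_reads, " reads")
  if (!any(keep)) stop("filter_samples removed every sample")
  counts[, keep, drop = FALSE]
}

#' Rarefy each sample to a common depth
#'
#' Draws `depth` reads per sample without replacement (a single draw, not an
#' average over draws), so every retained column sums exactly to `depth`.
#' Samples below `depth` are an error naming the sample: run
#' [filter_samples()] first.
#'
#' @param counts Count matrix.
#' @param depth Target reads per sample (default 7555).
#' @param seed Optional integer seed for reproducibility.
#' @return Rarefied count matrix (taxa with all-zero rows are kept).
#' @export
rarefy <- function(counts, depth = 7555, seed = NULL) {
  counts <- validate_count_table(counts)
  tot <- colSums(counts)
  low <- which(tot < depth)
  if (length(low))
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(colnames(counts)[low], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- counts
  for (j in seq_len(ncol(counts))) {
    if (tot[j] == depth) next
    pool <- rep.int(seq_len(nrow(counts)), counts[, j])
    drawn <- pool[sample.int(length(pool), depth)]
    out[, j] <- tabulate(drawn, nbins = nrow(counts))
  }
  storage.mode(out) <- "integer"
  st_log("info", "rarefy: ", ncol(out), " samples subsampled to ", depth, " reads")
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, computed for every
#' pair of sample columns.
#'
#' @param counts Count (or abundance) matrix, taxa x samples; `>= 2` samples,
#'   no zero-sum sample.
#' @return Symmetric dissimilarity matrix in `[0, 1]` with sample dimnames.
#' @export
bray_curtis <- function(counts) {
  if (ncol(counts) < 2L) stop("bray_curtis needs >= 2 samples")
  tot <- colSums(counts)
  if (any(tot == 0)) stop("zero-sum sample(s): ",
                          paste(colnames(counts)[tot == 0], collapse = ", "))
  m <- ncol(counts)
  d <- matrix(0, m, m, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(m - 1L)) {
    x <- counts[, i]
    rest <- (i + 1L):m
    shared <- colSums(pmin(counts[, rest, drop = FALSE], x))
    d[i, rest] <- d[rest, i] <- 1 - 2 * shared / (tot[i] + tot[rest])
  }
  d
}

#' Non-metric multidimensional scaling
#'
#' Finds the lowest-stress `n_dim` configuration over `restarts` random starts
#' plus one metric-MDS-initialized start, using monotone (isotonic) regression
#' of configuration distances on the input dissimilarities (Kruskal stress-1;
#' engine: `vegan::monoMDS`). Coordinates are centered at the origin.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param n_dim Embedding dimension (default 2; must be `< n_samples`).
#' @param seed Optional integer seed.
#' @param restarts Number of random starts (default 20).
#' @return List of class `nmds_result`: `points` (n x n_dim), `stress`, and
#'   `all_stress` (stress of every start).
#' @export
nmds <- function(d, n_dim = 2, seed = NULL, restarts = 20) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("nmds needs >= 3 samples")
  if (n_dim >= n) stop("n_dim must be < number of samples")
  if (!is.null(seed)) set.seed(seed)
  dd <- stats::as.dist(d)
  inits <- vector("list", restarts + 1L)
  cm <- stats::cmdscale(dd, k = n_dim)
  if (ncol(cm) < n_dim) cm <- cbind(cm, matrix(0, n, n_dim - ncol(cm)))
  inits[[1L]] <- cm
  for (r in seq_len(restarts))
    inits[[r + 1L]] <- matrix(stats::rnorm(n * n_dim), n, n_dim)
  fits <- lapply(inits, function(y)
    vegan::monoMDS(dd, y = y, k = n_dim, model = "global"))
  all_stress <- vapply(fits, function(f) f$stress, numeric(1L))
  best <- fits[[which.min(all_stress)]]
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("NMDS", seq_len(n_dim))
  structure(list(points = pts, stress = best$stress, all_stress = all_stress),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$points), "samples,",
      ncol(x$points), "dimensions\n")
  cat("Kruskal stress-1:", format(x$stress, digits = 4),
      "(best of", length(x$all_stress), "starts)\n")
  invisible(x)
}

#' Gini-Simpson diversity per sample
#'
#' `D = 1 - sum(p_i^2)` with `p_i` the within-sample relative abundances;
#' increases with richness and evenness.
#'
#' @param counts Count matrix with positive column sums.
#' @return Named numeric vector of per-sample diversity.
#' @export
simpson_diversity <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0)) stop("zero-sum sample(s)")
  p <- sweep(counts, 2L, tot, "/")
  1 - colSums(p^2)
}

#' Phylum-level environment correlation screen
#'
#' Aggregates counts to phylum relative abundances and computes Spearman's
#' rho (with p-value) for every (phylum, environmental variable) pair, then
#' Benjamini-Hochberg adjusts p across all pairs and assigns significance
#' stars at 0.001/0.01/0.05 on the adjusted p. Constant variables or phyla
#' yield `NA` rho.
#'
#' @param counts Rarefied count matrix.
#' @param taxonomy Taxonomy `data.frame`.
#' @param meta Sample metadata; all numeric columns are screened.
#' @return `data.frame` with phylum, variable, rho, p_value, p_adjusted,
#'   stars.
#' @export
phylum_env_correlations <- function(counts, taxonomy, meta) {
  phy <- aggregate_rank(counts, taxonomy, "phylum")
  rel <- sweep(phy, 2L, colSums(phy), "/")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  vars <- names(meta)[vapply(meta, is.numeric, logical(1L))]
  grid <- expand.grid(phylum = rownames(rel), variable = vars,
                      stringsAsFactors = FALSE)
  res <- mapply(function(ph, v) {
    x <- rel[ph, ]; y <- meta[[v]]
    if (stats::sd(x) == 0 || stats::sd(y, na.rm = TRUE) == 0 ||
        all(is.na(y)))
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }, grid$phylum, grid$variable)
  grid$rho <- res[1L, ]
  grid$p_value <- res[2L, ]
  grid$p_adjusted <- stats::p.adjust(grid$p_value, method = "BH")
  grid$stars <- significance_stars(grid$p_adjusted)
  grid
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

# Sum counts to a taxonomic rank; unclassified names pool under
# "unclassified".
aggregate_rank <- function(counts, taxonomy, rank) {
  stopifnot(rank %in% RANKS)
  lab <- taxonomy[[rank]][match(rownames(counts), taxonomy$taxon_id)]
  lab[is.na(lab)] <- "unclassified"
  rowsum(counts, group = lab)
}

#' Archaea:bacteria read ratio per sample
#'
#' Ratio of archaeal to bacterial reads in each sample; samples with zero
#' bacterial reads get `NA` (0 archaea over positive bacteria is 0).
#'
#' @param counts Count matrix.
#' @param taxonomy Taxonomy `data.frame` with classified domains.
#' @return Named numeric vector of per-sample ratios.
#' @export
archaea_bacteria_ratio <- function(counts, taxonomy) {
  dom <- taxonomy$domain[match(rownames(counts), taxonomy$taxon_id)]
  arch <- colSums(counts[dom %in% "Archaea", , drop = FALSE])
  bact <- colSums(counts[dom %in% "Bacteria", , drop = FALSE])
  ifelse(bact == 0, NA_real_, arch / bact)
}
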