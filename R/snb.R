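# Social niche breadth (SNB): a per-taxon generalism score from
# co-occurrence. A taxon found only in similar communities is a specialist;
# one spanning dissimilar communities is a generalist. SNB(a) is the mean
# Bray-Curtis dissimilarity over all unordered pairs of samples in which
# taxon a occurs.

#' Per-sample relative-abundance profiles at a taxonomic rank
#'
#' Closes each sample's composition to sum 1, optionally after aggregating
#' counts to a taxonomic rank (`rank = "asv"` keeps ASV resolution).
#'
#' @param counts Rarefied count matrix.
#' @param rank `"asv"` or one of the seven ranks.
#' @param taxonomy Required when `rank != "asv"`.
#' @return Numeric matrix of relative abundances (rows = taxa at the chosen
#'   level, columns = samples; each column sums to 1).
#' @export
sample_profiles <- function(counts, rank = "asv", taxonomy = NULL) {
  if (rank != "asv") {
    if (is.null(taxonomy)) stop("taxonomy needed for rank aggregation")
    counts <- aggregate_rank(counts, taxonomy, rank)
  }
  tot <- colSums(counts)
  if (any(tot == 0)) stop("zero-sum sample(s): ",
                          paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(counts, 2L, tot, "/")
}

#' Social niche breadth scores per taxon
#'
#' `SNB(a)` is the mean dissimilarity (default Bray-Curtis, the focal taxon
#' included in profiles) over all unordered pairs of samples in which `a` is
#' present (count > 0 in both). Occupancy (number of samples present) is
#' recorded; taxa present in fewer than `min_occupancy` samples get a missing
#' score — a singleton has no pair to average, and zero would conflate rarity
#' with extreme specialism.
#'
#' @param counts Rarefied count matrix (`>= 2` samples).
#' @param profiles Optional per-sample profiles (defaults to ASV-level
#'   [sample_profiles()] of `counts`).
#' @param dissimilarity Function taking a profile matrix and returning a
#'   sample dissimilarity matrix; default [bray_curtis()].
#' @param min_occupancy Minimum occupancy for a defined score (default 2).
#' @return `data.frame` of class `snb_result`: `taxon_id`, `snb`, `occupancy`.
#' @export
snb_scores <- function(counts, profiles = NULL, dissimilarity = bray_curtis,
                       min_occupancy = 2L) {
  counts <- validate_count_table(counts)
  if (ncol(counts) < 2L) stop("snb_scores needs >= 2 samples")
  if (is.null(profiles)) profiles <- sample_profiles(counts)
  d <- dissimilarity(profiles)
  present <- counts > 0L
  occupancy <- rowSums(present)
  snb <- rep(NA_real_, nrow(counts))
  for (i in which(occupancy >= max(2L, min_occupancy))) {
    s <- which(present[i, ])
    sub <- d[s, s]
    snb[i] <- mean(sub[upper.tri(sub)])
  }
  out <- data.frame(taxon_id = rownames(counts), snb = snb,
                    occupancy = as.integer(occupancy),
                    stringsAsFactors = FALSE)
  class(out) <- c("snb_result", "data.frame")
  out
}

#' Abundance-weighted mean SNB per sample
#'
#' Per sample: `sum(n_is * SNB_i) / sum(n_is)` over taxa with a defined score
#' and positive count. Samples with no score-carrying taxa get `NA`.
#'
#' @param counts Rarefied count matrix (same table the scores came from).
#' @param snb An `snb_result` from [snb_scores()].
#' @return Named numeric vector of per-sample `ave.snb`.
#' @export
weighted_mean_snb <- function(counts, snb) {
  v <- snb$snb[match(rownames(counts), snb$taxon_id)]
  ok <- !is.na(v)
  num <- colSums(counts[ok, , drop = FALSE] * v[ok])
  den <- colSums(counts[ok, , drop = FALSE])
  ifelse(den > 0, num / den, NA_real_)
}
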