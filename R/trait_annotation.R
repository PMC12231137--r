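# Genomic trait assignment by iterative taxonomic-rank fallback, rRNA
# consensus, and abundance-weighted per-sample trait means.

TRAITS <- c("genome_size", "rrna_copies", "gc", "coding_density")

#' Build a rank-indexed trait lookup from a reference table
#'
#' For each rank and taxon name, each trait value is the summary (arithmetic
#' mean by default, median via `stat`) over all reference rows mapping to that
#' name at that rank. When the reference carries lineage columns (e.g. a
#' `family` column on genus rows), rows also aggregate upward into the named
#' higher-rank entries, so a genus genome contributes to its family's mean.
#'
#' @param ref Trait reference `data.frame` (see [read_trait_reference()]).
#' @param stat `"mean"` or `"median"` summary across genomes at a rank.
#' @return A list of class `trait_index`: per rank, a data.frame of summarized
#'   trait values keyed by taxon name.
#' @export
build_reference_index <- function(ref, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  ref <- validate_trait_reference(ref)
  traits <- intersect(TRAITS, names(ref))
  # long form: one contribution row per (rank, name) a reference row maps to
  contribs <- list(data.frame(rank = ref$rank, name = ref$taxon_name,
                              ref[traits], stringsAsFactors = FALSE))
  lineage_cols <- intersect(RANKS, names(ref))
  for (rc in lineage_cols) {
    up <- which(match(rc, RANKS) < match(ref$rank, RANKS) &
                  !is.na(ref[[rc]]) & ref[[rc]] != "" &
                  ref[[rc]] != "unclassified")
    if (length(up))
      contribs[[length(contribs) + 1L]] <-
        data.frame(rank = rc, name = ref[[rc]][up], ref[up, traits, drop = FALSE],
                   stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, contribs)
  fun <- if (stat == "mean") function(v) mean(v, na.rm = TRUE)
         else function(v) stats::median(v, na.rm = TRUE)
  idx <- lapply(split(long, long$rank), function(blk) {
    out <- do.call(rbind, lapply(split(blk, blk$name), function(g) {
      vals <- vapply(traits, function(tr) {
        v <- g[[tr]]
        if (all(is.na(v))) NA_real_ else fun(v)
      }, numeric(1L))
      as.data.frame(as.list(vals))
    }))
    out
  })
  structure(idx, class = "trait_index", traits = traits)
}

#' Assign traits to ASVs by taxonomic-rank fallback
#'
#' Per ASV and per trait independently: walk the ranks genus, family, order,
#' class, phylum, domain, starting at the ASV's lowest classified rank; the
#' first rank at which the reference index holds a value supplies the trait
#' and its provenance. If no rank hits, the trait is missing with provenance
#' `"unassigned"`. (Species is skipped: references are summarized at genus
#' and above.)
#'
#' @param taxonomy Taxonomy `data.frame`.
#' @param index A `trait_index` from [build_reference_index()].
#' @return `data.frame` of class `trait_assignment`: per taxon, each trait's
#'   value and a `<trait>_rank` provenance column.
#' @export
assign_traits <- function(taxonomy, index) {
  stopifnot(inherits(index, "trait_index"))
  traits <- attr(index, "traits")
  walk <- c("genus", "family", "order", "class", "phylum", "domain")
  out <- data.frame(taxon_id = taxonomy$taxon_id, stringsAsFactors = FALSE)
  for (tr in traits) {
    out[[tr]] <- NA_real_
    out[[paste0(tr, "_rank")]] <- "unassigned"
  }
  for (i in seq_len(nrow(taxonomy))) {
    for (tr in traits) {
      for (rk in walk) {
        nm <- taxonomy[[rk]][i]
        if (is.na(nm) || nm == "unclassified") next
        tab <- index[[rk]]
        if (is.null(tab) || !nm %in% rownames(tab)) next
        v <- tab[nm, tr]
        if (!is.na(v)) {
          out[[tr]][i] <- v
          out[[paste0(tr, "_rank")]][i] <- rk
          break
        }
      }
    }
  }
  class(out) <- c("trait_assignment", "data.frame")
  out
}

#' Merge database and predicted rRNA copy numbers into a consensus
#'
#' When both a database-derived and a predicted value exist for an ASV, the
#' consensus is their arithmetic mean (kept fractional) and the provenance is
#' annotated `"consensus"`; with one source, that source is used; with
#' neither, the value stays missing. Non-positive predicted values are
#' rejected with a warning and the database value kept.
#'
#' @param assigned A `trait_assignment`.
#' @param predicted Optional `data.frame` with `taxon_id`, `rrna_predicted`.
#' @return The updated `trait_assignment`.
#' @export
consensus_rrna <- function(assigned, predicted = NULL) {
  if (is.null(predicted)) return(assigned)
  pred <- predicted$rrna_predicted[match(assigned$taxon_id, predicted$taxon_id)]
  bad <- !is.na(pred) & pred <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive predicted rRNA value(s) rejected")
    st_log("warn", "consensus_rrna: rejected ", sum(bad),
           " non-positive predicted values")
    pred[bad] <- NA_real_
  }
  db <- assigned$rrna_copies
  both <- !is.na(db) & !is.na(pred)
  only_pred <- is.na(db) & !is.na(pred)
  assigned$rrna_copies[both] <- (db[both] + pred[both]) / 2
  assigned$rrna_copies_rank[both] <- "consensus"
  assigned$rrna_copies[only_pred] <- pred[only_pred]
  assigned$rrna_copies_rank[only_pred] <- "predicted"
  assigned
}

#' Abundance-weighted per-sample trait means
#'
#' For each sample and trait: `sum(n_is * t_i) / sum(n_is)` over taxa with the
#' trait defined and positive count — weights are renormalized over the
#' annotated subset rather than treating missing traits as zero. The same
#' weighting is applied to SNB scores when supplied, and Gini-Simpson
#' diversity is attached. Samples where fewer than `min_coverage` of reads
#' carry a trait get `NA` for that trait (with a warning): downstream models
#' refuse poorly annotated samples.
#'
#' @param counts Rarefied count matrix.
#' @param assigned A `trait_assignment` (after [consensus_rrna()]).
#' @param snb Optional `data.frame` from [snb_scores()] (`taxon_id`, `snb`).
#' @param min_coverage Minimum fraction of reads annotated per trait
#'   (default 0.5).
#' @return `data.frame` with `sample_id`, `ave.gs`, `ave.rrna`, `ave.gc`,
#'   `ave.snb` (if `snb` given), `simpson`, plus `coverage_*` columns.
#' @export
weighted_sample_traits <- function(counts, assigned, snb = NULL,
                                   min_coverage = 0.5) {
  counts <- validate_count_table(counts)
  ord <- match(rownames(counts), assigned$taxon_id)
  vals <- list(
    ave.gs = assigned$genome_size[ord],
    ave.rrna = assigned$rrna_copies[ord],
    ave.gc = assigned$gc[ord])
  if (!is.null(snb))
    vals$ave.snb <- snb$snb[match(rownames(counts), snb$taxon_id)]
  out <- data.frame(sample_id = colnames(counts), stringsAsFactors = FALSE)
  tot <- colSums(counts)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    ok <- !is.na(v)
    w <- colSums(counts[ok, , drop = FALSE] * v[ok])
    wsum <- colSums(counts[ok, , drop = FALSE])
    cov <- wsum / tot
    mean_v <- ifelse(wsum > 0, w / wsum, NA_real_)
    low <- cov < min_coverage
    if (any(low)) {
      warning("trait ", nm, ": ", sum(low),
              " sample(s) below ", round(100 * min_coverage),
              "% read annotation; set to NA")
      mean_v[low] <- NA_real_
    }
    out[[nm]] <- mean_v
    out[[paste0("coverage_", nm)]] <- cov
    st_log("debug", "weighted_sample_traits: ", nm, " mean read coverage ",
           round(mean(cov), 3))
  }
  out$simpson <- simpson_diversity(counts)
  # contract: each weighted mean lies within the contributing taxa's range
  for (nm in names(vals)) {
    v <- vals[[nm]]
    rng <- range(v, na.rm = TRUE)
    stopifnot(all(is.na(out[[nm]]) |
                    (out[[nm]] >= rng[1L] - 1e-9 & out[[nm]] <= rng[2L] + 1e-9)))
  }
  out
}
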