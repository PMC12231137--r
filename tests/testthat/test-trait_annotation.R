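ref_fixture <- function() {
  data.frame(
    taxon_name = c("GenA", "GenA", "GenB", "FamX"),
    rank = c("genus", "genus", "genus", "family"),
    genome_size = c(4.0e6, 5.0e6, NA, 4.2e6),
    rrna_copies = c(3, 5, 2, 4),
    gc = c(60, 62, NA, 55),
    coding_density = c(88, 90, 87, 89),
    family = c("FamX", "FamX", "FamY", NA),
    stringsAsFactors = FALSE)
}

test_that("reference index averages duplicate rows and aggregates upward", {
  idx <- build_reference_index(ref_fixture())
  # duplicate genus rows averaged
  expect_equal(idx$genus["GenA", "genome_size"], 4.5e6)
  # single row passes through
  expect_equal(idx$genus["GenB", "rrna_copies"], 2)
  # missing trait on the only row stays missing
  expect_true(is.na(idx$genus["GenB", "genome_size"]))
  # genus rows aggregate into their family via the lineage column:
  # FamX = mean(own row 4.2, GenA rows 4.0 and 5.0)
  expect_equal(idx$family["FamX", "genome_size"], mean(c(4.2e6, 4.0e6, 5.0e6)))
  # median summary available
  idx_med <- build_reference_index(ref_fixture(), stat = "median")
  expect_equal(idx_med$family["FamX", "genome_size"], 4.2e6)
  # degenerate: empty reference -> everything unassigned downstream
  empty <- ref_fixture()[0, ]
  tax <- toy_taxonomy("T1", genus = "GenA", family = "FamX")
  a0 <- assign_traits(tax, build_reference_index(empty))
  expect_true(is.na(a0$genome_size))
  expect_equal(a0$genome_size_rank, "unassigned")
})

test_that("trait fallback walks ranks independently per trait", {
  idx <- build_reference_index(ref_fixture())
  tax <- rbind(
    toy_taxonomy("hit_genus", genus = "GenA", family = "FamX"),
    toy_taxonomy("fall_family", genus = "unclassified", family = "FamX"),
    toy_taxonomy("partial", genus = "GenB", family = "FamY"),
    toy_taxonomy("nohit", genus = "unclassified", family = "ZZZ"))
  a <- assign_traits(tax, idx)
  # direct genus hit
  expect_equal(a$genome_size[1], 4.5e6)
  expect_equal(a$genome_size_rank[1], "genus")
  # unclassified genus falls back to the family value
  expect_equal(a$genome_size[2], mean(c(4.2e6, 4.0e6, 5.0e6)))
  expect_equal(a$genome_size_rank[2], "family")
  # per-trait independence: GenB supplies rrna at genus rank but its genome
  # size must fall through (FamY has no reference value)
  expect_equal(a$rrna_copies_rank[3], "genus")
  expect_equal(a$genome_size_rank[3], "unassigned")
  expect_true(is.na(a$genome_size[3]))
  # exhausted walk
  expect_equal(a$genome_size_rank[4], "unassigned")
})

test_that("rRNA consensus merges the two sources by arithmetic mean", {
  idx <- build_reference_index(ref_fixture())
  tax <- rbind(toy_taxonomy("A", genus = "GenB", family = "FamY"),
               toy_taxonomy("B", genus = "GenA", family = "FamX"),
               toy_taxonomy("C", genus = "unclassified", family = "ZZZ"))
  a <- assign_traits(tax, idx)
  # database 2 (GenB), predicted 5 -> arithmetic mean 3.5
  pred <- data.frame(taxon_id = c("A"), rrna_predicted = c(5))
  out <- consensus_rrna(a, pred)
  expect_equal(out$rrna_copies[1], (2 + 5) / 2)
  expect_equal(out$rrna_copies_rank[1], "consensus")
  # predicted absent: database value unchanged
  expect_equal(out$rrna_copies[2], 4)   # mean of GenA rows 3, 5
  expect_equal(out$rrna_copies_rank[2], "genus")
  # both absent stays missing
  expect_true(is.na(out$rrna_copies[3]))
  # non-positive predicted values rejected with warning, database kept
  badpred <- data.frame(taxon_id = "B", rrna_predicted = -1)
  expect_warning(out2 <- consensus_rrna(a, badpred), "non-positive")
  expect_equal(out2$rrna_copies[2], 4)
})

test_that("weighted sample traits renormalize over annotated taxa", {
  counts <- toy_counts(matrix(c(3L, 1L), 2, 1))
  assigned <- data.frame(taxon_id = c("T1", "T2"),
                         genome_size = c(4e6, 8e6),
                         genome_size_rank = "genus",
                         rrna_copies = c(2, 2), rrna_copies_rank = "genus",
                         gc = c(50, 60), gc_rank = "genus",
                         stringsAsFactors = FALSE)
  prof <- weighted_sample_traits(counts, assigned, min_coverage = 0)
  expect_equal(prof$ave.gs, 5e6)               # (3*4 + 1*8)/4
  expect_equal(prof$ave.rrna, 2)               # constant trait -> constant mean
  # equal counts -> simple mean
  eq <- toy_counts(matrix(c(2L, 2L), 2, 1))
  expect_equal(weighted_sample_traits(eq, assigned, min_coverage = 0)$ave.gc, 55)
  # missing trait for one taxon: weights renormalize over the annotated one
  assigned$genome_size[2] <- NA
  prof2 <- weighted_sample_traits(counts, assigned, min_coverage = 0)
  expect_equal(prof2$ave.gs, 4e6)
  # coverage floor: only 3/4 of reads annotated -> below 0.9 floor gets NA
  expect_warning(prof3 <- weighted_sample_traits(counts, assigned,
                                                 min_coverage = 0.9),
                 "annotation")
  expect_true(is.na(prof3$ave.gs))
  expect_equal(prof3$coverage_ave.gs, 0.75)
})

test_that("fallback provenance matches construction on synthetic data", {
  dat <- generate_dataset(generator_config(seed = 8, n_taxa = 120,
                                           n_samples = 20, mean_depth = 4000,
                                           n_low_depth = 0))
  idx <- build_reference_index(dat$reference)
  a <- assign_traits(dat$taxonomy, idx)
  tr <- dat$truth$taxa
  expected_rank <- ifelse(tr$genus_in_reference, "genus", "family")
  got <- a$genome_size_rank[match(tr$taxon_id, a$taxon_id)]
  expect_equal(mean(got == expected_rank), 1)
  # weighted means bounded by per-taxon extrema
  r <- rarefy(dat$counts, min(colSums(dat$counts)), seed = 1)
  prof <- weighted_sample_traits(r, a, min_coverage = 0)
  expect_true(all(prof$ave.gs >= min(a$genome_size, na.rm = TRUE) - 1e-9))
  expect_true(all(prof$ave.gs <= max(a$genome_size, na.rm = TRUE) + 1e-9))
})
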