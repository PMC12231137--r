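test_that("filter_taxa removes organellar and non-prokaryotic lineages", {
  m <- toy_counts(matrix(10L, 5, 2))
  tax <- toy_taxonomy(rownames(m))
  tax$order[1] <- "Chloroplast"          # organellar at order rank
  tax$family[2] <- "Mitochondria"        # organellar at family rank
  tax$domain[3] <- "Eukaryota"
  tax$domain[5] <- "Archaea"
  out <- filter_taxa(m, tax)
  expect_setequal(rownames(out), c("T4", "T5"))
  # read conservation: retained reads = input minus removed taxa's reads
  expect_equal(sum(out), sum(m) - sum(m[c("T1", "T2", "T3"), ]))
  # all-prokaryote input unchanged
  expect_identical(filter_taxa(m, toy_taxonomy(rownames(m))), m)
  # taxa absent from the taxonomy count as unclassified domain -> removed
  expect_error(filter_taxa(m, toy_taxonomy("T9")), "every taxon")
})

test_that("filter_samples applies the read floor inclusively", {
  m <- toy_counts(matrix(c(7999L, 8000L, 12000L), 1, 3))
  out <- filter_samples(m, 8000)
  expect_setequal(colnames(out), c("S2", "S3"))
  expect_identical(filter_samples(m, 0), m)
  expect_error(filter_samples(m, 1e6), "every sample")
})

test_that("rarefy draws without replacement to an exact common depth", {
  m <- toy_counts(30, seed = 1, n_taxa = 12)
  depth <- min(colSums(m)) - 5L
  r <- rarefy(m, depth, seed = 9)
  expect_true(all(colSums(r) == depth))
  expect_true(all(r <= m))                       # subsampling never adds reads
  expect_identical(rarefy(m, depth, seed = 9), r)  # seed-reproducible
  # a sample already at depth is returned unchanged
  m2 <- m[, 1, drop = FALSE]
  expect_identical(rarefy(m2, sum(m2)), m2)
  # sample below depth: error naming it
  expect_error(rarefy(m, max(colSums(m))), colnames(m)[which.min(colSums(m))])
})

test_that("rarefied counts match the hypergeometric expectation", {
  x <- matrix(c(50L, 30L, 15L, 5L), 4, 1,
              dimnames = list(paste0("T", 1:4), "S1"))
  depth <- 40L
  set.seed(123)
  draws <- vapply(1:500, function(i) rarefy(x, depth)[, 1], numeric(4))
  p <- x[, 1] / sum(x)
  expected <- depth * p
  N <- sum(x)
  v <- depth * p * (1 - p) * (N - depth) / (N - 1)
  se <- sqrt(v / 500)
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * se))
})

test_that("bray_curtis matches formula examples and the brute-force oracle", {
  m <- toy_counts(matrix(c(5L, 5L, 0L, 0L, 5L, 5L), 3, 2))
  expect_equal(bray_curtis(m)["S1", "S2"], 0.5)
  ident <- toy_counts(matrix(c(3L, 1L, 3L, 1L), 2, 2))
  expect_equal(bray_curtis(ident)["S1", "S2"], 0)
  disj <- toy_counts(matrix(c(4L, 0L, 0L, 6L), 2, 2))
  expect_equal(bray_curtis(disj)["S1", "S2"], 1)
  for (seed in 1:3) {
    rnd <- toy_counts(4, seed = seed, n_taxa = 6)
    expect_equal(bray_curtis(rnd), bc_matrix_brute(rnd), tolerance = 1e-12)
  }
  # independent library cross-check
  rnd <- toy_counts(5, seed = 7, n_taxa = 8)
  expect_equal(unname(as.matrix(vegan::vegdist(t(rnd), "bray"))),
               unname(bray_curtis(rnd)), tolerance = 1e-12)
  expect_error(bray_curtis(toy_counts(matrix(c(1L, 0L), 1, 2))), "zero-sum")
})

test_that("nmds embeds collinear points near-perfectly and is deterministic", {
  x <- seq(0, 10, length.out = 8)
  d <- as.matrix(dist(x)) / max(dist(x))
  dimnames(d) <- list(paste0("S", 1:8), paste0("S", 1:8))
  fit <- nmds(d, n_dim = 2, seed = 42, restarts = 5)
  expect_lt(fit$stress, 0.01)
  expect_true(all(fit$stress <= fit$all_stress + 1e-12))  # argmin contract
  expect_equal(colMeans(fit$points), c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-9)
  fit2 <- nmds(d, n_dim = 2, seed = 42, restarts = 5)
  expect_identical(fit$points, fit2$points)
  expect_error(nmds(d, n_dim = 8), "n_dim")
})

test_that("Gini-Simpson diversity follows the closed form and evenness", {
  u <- toy_counts(matrix(c(5L, 5L, 5L, 5L), 4, 1))
  expect_equal(unname(simpson_diversity(u)), 0.75)  # 1 - 4*(1/4)^2
  single <- toy_counts(matrix(10L, 1, 1))
  expect_equal(unname(simpson_diversity(single)), 0)
  # evenness monotonicity: moving reads from the dominant taxon to the others
  # strictly increases D (checked against the brute-force formula)
  skew <- c(60L, 10L, 10L, 10L)
  evener <- c(45L, 15L, 15L, 15L)
  expect_equal(unname(simpson_diversity(toy_counts(matrix(skew, 4, 1)))),
               simpson_brute(skew))
  expect_lt(simpson_brute(skew), simpson_brute(evener))
  expect_lt(unname(simpson_diversity(toy_counts(matrix(skew, 4, 1)))),
            unname(simpson_diversity(toy_counts(matrix(evener, 4, 1)))))
  # library cross-check
  rnd <- toy_counts(3, seed = 2, n_taxa = 7)
  expect_equal(unname(simpson_diversity(rnd)),
               unname(vegan::diversity(t(rnd), "simpson")), tolerance = 1e-12)
})

test_that("phylum screen finds monotone signal and stays quiet under null", {
  set.seed(21)
  n_s <- 24
  meta <- data.frame(sample_id = paste0("S", 1:n_s), pH = seq(5, 9, length.out = n_s))
  counts <- toy_counts(matrix(10L, 20, n_s))
  tax <- toy_taxonomy(rownames(counts), phylum = paste0("P", 1:20),
                      genus = paste0("G", 1:20))
  # constant background, so P1's relative abundance is strictly increasing
  # in pH
  counts["T1", ] <- as.integer(round(10 + 50 * seq_len(n_s)))
  res <- phylum_env_correlations(counts, tax, meta)
  expect_equal(res$rho[res$phylum == "P1" & res$variable == "pH"], 1)
  # aggregation conserves reads per sample
  agg <- rowsum(counts, tax$phylum[match(rownames(counts), tax$taxon_id)])
  expect_equal(colSums(agg), colSums(counts))
  # permuted metadata: few false positives at adjusted 0.05
  set.seed(77)
  meta_perm <- meta
  meta_perm$pH <- sample(meta$pH)
  counts0 <- toy_counts(n_s, seed = 5, n_taxa = 20)
  res0 <- phylum_env_correlations(counts0, tax, meta_perm)
  expect_lte(mean(res0$p_adjusted < 0.05, na.rm = TRUE), 0.1)
})

test_that("archaea:bacteria ratio is exact and scale invariant", {
  m <- toy_counts(matrix(c(100L, 900L), 2, 1))
  tax <- toy_taxonomy(rownames(m), domain = c("Archaea", "Bacteria"))
  expect_equal(round(unname(archaea_bacteria_ratio(m, tax)), 4), 0.1111)
  expect_equal(unname(archaea_bacteria_ratio(m * 2L, tax)),
               unname(archaea_bacteria_ratio(m, tax)))
  tax0 <- toy_taxonomy(rownames(m), domain = c("Bacteria", "Bacteria"))
  expect_equal(unname(archaea_bacteria_ratio(m, tax0)), 0)
})
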