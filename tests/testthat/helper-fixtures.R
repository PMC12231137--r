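# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (double loops, direct formula transcription) so they
# stay independent of the vectorized implementations they check.

options(soiltraits.log_level = "warn")

toy_counts <- function(m, seed = NULL, n_taxa = 8) {
  if (is.matrix(m)) {
    dimnames(m) <- list(paste0("T", seq_len(nrow(m))),
                        paste0("S", seq_len(ncol(m))))
    storage.mode(m) <- "integer"
    return(m)
  }
  # m = n_samples; random table
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rpois(n_taxa * m, 15), n_taxa, m,
              dimnames = list(paste0("T", seq_len(n_taxa)),
                              paste0("S", seq_len(m))))
  storage.mode(x) <- "integer"
  x
}

toy_taxonomy <- function(taxon_id, domain = "Bacteria", phylum = "PhyA",
                         class = "ClA", order = "OrA", family = "FamA",
                         genus = "GenA", species = "unclassified") {
  data.frame(taxon_id = taxon_id, domain = domain, phylum = phylum,
             class = class, order = order, family = family, genus = genus,
             species = species, stringsAsFactors = FALSE)
}

# Bray-Curtis by direct double loop over taxa
bc_brute <- function(x, y) {
  num <- 0
  for (k in seq_along(x)) num <- num + min(x[k], y[k])
  1 - 2 * num / (sum(x) + sum(y))
}

bc_matrix_brute <- function(counts) {
  m <- ncol(counts)
  d <- matrix(0, m, m, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) d[i, j] <- bc_brute(counts[, i], counts[, j])
  d
}

simpson_brute <- function(x) {
  p <- x / sum(x)
  s <- 0
  for (pi in p) s <- s + pi^2
  1 - s
}

# SNB by explicit enumeration of sample pairs where the taxon is present
snb_brute <- function(counts, dmat, taxon) {
  s <- which(counts[taxon, ] > 0)
  if (length(s) < 2) return(NA_real_)
  vals <- c()
  for (a in seq_along(s)) for (b in seq_along(s)) if (a < b)
    vals <- c(vals, dmat[s[a], s[b]])
  mean(vals)
}

# ILR balance by direct formula transcription on one sample
ilr_brute <- function(x, R, S, pc = 1) {
  rel <- (x + pc) / sum(x + pc)
  gmR <- prod(rel[R])^(1 / length(R))
  gmS <- prod(rel[S])^(1 / length(S))
  r <- length(R); s <- length(S)
  sqrt(r * s / (r + s)) * log(gmR / gmS)
}

# Brownian tip values on a tree via the Cholesky of its covariance
simulate_bm <- function(tree, n_rep = 1) {
  C <- ape::vcv(tree)
  L <- t(chol(C))
  y <- L %*% matrix(rnorm(nrow(C) * n_rep), nrow(C))
  rownames(y) <- tree$tip.label
  y
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
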