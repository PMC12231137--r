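# Tabular and tree I/O with validation.
#
# Canonical table dialect: TSV with a literal "taxon_id" first header cell for
# taxon-indexed tables; CSV only for sample metadata. Trees are Newick; rooted
# input is silently unrooted (downstream phylofactorization requires an
# unrooted tree).

RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Package-level logging
#'
#' Emits a structured log line via [message()] when its level is at or above
#' the active threshold (`options(soiltraits.log_level = ...)`, default
#' `"info"`). Every filtering or repair action in the pipeline logs through
#' this hook so runs are auditable.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`.
#' @param ... Pieces pasted into the message.
#' @return Invisibly, the message string.
#' @export
st_log <- function(level = "info", ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  threshold <- getOption("soiltraits.log_level", "info")
  msg <- paste0("[soiltraits:", level, "] ", paste0(..., collapse = ""))
  if (levels[[level]] >= levels[[threshold]]) message(msg)
  invisible(msg)
}

#' Validate an ASV-by-sample count table
#'
#' A count table is a base integer matrix with taxa as rows and samples as
#' columns: unique non-empty dimnames, all counts finite, non-negative whole
#' numbers, at least one taxon and one sample.
#'
#' @param counts Matrix to validate.
#' @return The validated matrix (storage mode integer), invisibly unchanged
#'   otherwise.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts)) stop("count table must be a matrix (taxa x samples)")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count table needs at least 1 taxon and 1 sample")
  tid <- rownames(counts); sid <- colnames(counts)
  if (is.null(tid) || is.null(sid) || any(tid == "") || any(sid == ""))
    stop("count table must carry taxon ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(tid)) stop("duplicate taxon ids: ",
                               paste(unique(tid[duplicated(tid)]), collapse = ", "))
  if (anyDuplicated(sid)) stop("duplicate sample ids: ",
                               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!is.finite(counts))) {
    bad <- which(!is.finite(counts), arr.ind = TRUE)[1L, ]
    stop("non-finite count at taxon '", tid[bad[1L]], "', sample '", sid[bad[2L]], "'")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at taxon '", tid[bad[1L]], "', sample '", sid[bad[2L]], "'")
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stop("non-integer count at taxon '", tid[bad[1L]], "', sample '", sid[bad[2L]], "'")
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read an ASV-by-sample count table from TSV
#'
#' Expects a header row of sample ids with a first `taxon_id` column.
#' Cells must be non-negative integers; violations are rejected with the
#' offending taxon and sample named.
#'
#' @param path Path to a TSV file.
#' @return Validated integer matrix, taxa as rows, samples as columns.
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a taxon_id column plus >=1 sample column")
  if (names(df)[1L] != "taxon_id")
    stop("first header cell must be 'taxon_id', got '", names(df)[1L], "'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    nonnum <- which(!vapply(df[-1L], is.numeric, logical(1L)))
    stop("non-numeric counts in sample column(s): ",
         paste(names(df)[-1L][nonnum], collapse = ", "))
  }
  rownames(m) <- as.character(df[[1L]])
  validate_count_table(m)
}

#' Write a count table to TSV
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_count_table(counts)
  df <- data.frame(taxon_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

normalize_taxon_name <- function(x) {
  x <- trimws(ifelse(is.na(x), "", x))
  # SILVA-style prefixes with an empty suffix ("g__") mean unclassified
  x[grepl("^[a-z]__$", x)] <- ""
  x[x %in% c("", "NA", "na", "unclassified", "Unclassified")] <- "unclassified"
  x
}

#' Read a ranked taxonomy table from TSV
#'
#' Expects a `taxon_id` column plus the seven positional ranks
#' (domain..species). Empty cells, `NA`, and bare SILVA prefixes (`g__`)
#' normalize to the sentinel `"unclassified"`. Lineages violating the
#' unclassified-suffix rule (a rank classified below an unclassified one)
#' are repaired by truncation, with a logged warning naming how many rows
#' were touched.
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with columns `taxon_id` and the seven ranks.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!"taxon_id" %in% names(df)) stop("taxonomy table must have a 'taxon_id' column")
  missing_ranks <- setdiff(RANKS, names(df))
  if (length(missing_ranks))
    stop("taxonomy table missing rank column(s): ", paste(missing_ranks, collapse = ", "))
  df <- df[, c("taxon_id", RANKS)]
  for (r in RANKS) df[[r]] <- normalize_taxon_name(df[[r]])
  repair_taxonomy(df)
}

# Enforce: once a rank is unclassified all lower ranks are unclassified.
repair_taxonomy <- function(df) {
  m <- as.matrix(df[RANKS])
  uncl <- m == "unclassified"
  # first unclassified rank per row (8 = none)
  first <- apply(uncl, 1L, function(z) if (any(z)) which(z)[1L] else 8L)
  repaired <- 0L
  for (i in seq_len(nrow(m))) {
    if (first[i] < 7L && any(m[i, (first[i] + 1L):7L] != "unclassified")) {
      m[i, first[i]:7L] <- "unclassified"
      repaired <- repaired + 1L
    }
  }
  if (repaired > 0L) {
    st_log("warn", "taxonomy: truncated ", repaired,
           " lineage(s) classified below an unclassified rank")
    warning(repaired, " lineage(s) repaired by truncation (rank classified below an unclassified rank)")
  }
  df[RANKS] <- as.data.frame(m, stringsAsFactors = FALSE)
  df
}

#' Write a taxonomy table to TSV
#' @param taxonomy Taxonomy `data.frame` (taxon_id + 7 ranks).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("taxon_id", RANKS)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Expects `sample_id`, `pH`, `om_loi` (% dry mass by loss on ignition),
#' `phosphorus`/`potassium`/`magnesium` (mg/l), `sand`/`silt`/`clay`
#' (% of total) and `rotation` (one of arable, mixed, grass). pH must lie in
#' (0, 14); sand+silt+clay must total 99-101 when all three are present.
#'
#' @param path Path to a CSV file.
#' @return Validated `data.frame`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' Validate sample metadata
#' @param df Metadata `data.frame`.
#' @return The validated data frame.
#' @export
validate_sample_metadata <- function(df) {
  if (!"sample_id" %in% names(df)) stop("metadata must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  if (!"pH" %in% names(df)) stop("metadata must have a 'pH' column")
  ph <- df$pH
  if (any(!is.na(ph) & (ph <= 0 | ph >= 14))) stop("pH values must lie in (0, 14)")
  tex <- c("sand", "silt", "clay")
  if (all(tex %in% names(df))) {
    tot <- df$sand + df$silt + df$clay
    bad <- which(!is.na(tot) & (tot < 99 | tot > 101))
    if (length(bad)) stop("sand+silt+clay outside [99, 101] for sample(s): ",
                          paste(df$sample_id[bad], collapse = ", "))
  }
  if ("rotation" %in% names(df)) {
    ok <- df$rotation %in% c("arable", "mixed", "grass") | is.na(df$rotation)
    if (!all(ok)) stop("rotation must be one of arable/mixed/grass")
  }
  df
}

#' Write sample metadata to CSV
#' @param meta Metadata `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.csv(validate_sample_metadata(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genomic trait reference table from TSV
#'
#' Rows of `(taxon_name, rank, genome_size, rrna_copies, gc, coding_density)`;
#' any trait cell may be empty (missing). Optional lineage columns named after
#' higher ranks let rows aggregate upward (see [build_reference_index()]).
#'
#' @param path Path to a TSV file.
#' @return Validated `data.frame`.
#' @export
read_trait_reference <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_trait_reference(df)
}

#' Validate a trait reference table
#' @param df Reference `data.frame`.
#' @return The validated data frame.
#' @export
validate_trait_reference <- function(df) {
  need <- c("taxon_name", "rank")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait reference missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$rank %in% RANKS))
    stop("trait reference rank values must be one of: ", paste(RANKS, collapse = ", "))
  if ("genome_size" %in% names(df) &&
      any(!is.na(df$genome_size) & df$genome_size <= 0))
    stop("genome_size must be > 0 when present")
  if ("gc" %in% names(df) && any(!is.na(df$gc) & (df$gc <= 0 | df$gc >= 100)))
    stop("gc must lie in (0, 100) when present")
  df
}

#' Write a trait reference table to TSV
#' @param ref Reference `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trait_reference <- function(ref, path) {
  utils::write.table(ref, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-ASV predicted rRNA copy numbers from TSV
#'
#' Two columns: `taxon_id`, `rrna_predicted`. Used as the second source in
#' [consensus_rrna()].
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with `taxon_id` and `rrna_predicted`.
#' @export
read_predicted_rrna <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "rrna_predicted") %in% names(df)))
    stop("predicted rRNA table needs columns taxon_id, rrna_predicted")
  df
}

#' Read a Newick tree, unrooting on the way in
#'
#' Rooted input is converted to unrooted by collapsing the degree-2 root node
#' (phylofactorization and the signal statistics' rooting convention expect an
#' unrooted tree as the stored form). Branch lengths must be non-negative.
#'
#' @param path Path to a Newick file.
#' @return An unrooted `ape::phylo` tree.
#' @seealso [write_newick()]
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: could not read a tree from '", path, "'")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_tree(tr)
}

#' Validate a phylogenetic tree
#'
#' Checks unique leaf labels and non-negative branch lengths; unroots a rooted
#' tree.
#'
#' @param tr An `ape::phylo` object.
#' @return The validated (unrooted) tree.
#' @export
validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("expected an ape 'phylo' tree")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths in tree")
  if (ape::is.rooted(tr) && length(tr$tip.label) > 2L) tr <- ape::unroot(tr)
  tr
}

#' Write a tree to Newick
#' @param tr An `ape::phylo` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tr, path) {
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Read a labeled square distance matrix from TSV
#'
#' First header cell is ignored; row and column labels must agree. The matrix
#' must be symmetric with a zero diagonal.
#'
#' @param path Path to a TSV file.
#' @return Symmetric numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  validate_distance_matrix(m)
}

#' Validate a distance matrix
#' @param m Square numeric matrix.
#' @param max_one Require values `<= 1` (dissimilarities); default `FALSE`.
#' @return The validated matrix.
#' @export
validate_distance_matrix <- function(m, max_one = FALSE) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (!identical(rownames(m), colnames(m))) stop("distance matrix labels must agree")
  if (any(!is.finite(m))) stop("non-finite distances")
  if (any(m < 0)) stop("negative distances")
  if (max_one && any(m > 1 + 1e-12)) stop("dissimilarities must lie in [0, 1]")
  if (any(abs(m - t(m)) > 1e-9)) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be zero")
  m
}

#' Write a labeled square distance matrix to TSV
#' @param m Symmetric matrix with dimnames.
#' @param path Output path.
#' @param label First header cell (defaults to `"id"`).
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(m, path, label = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1L] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
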