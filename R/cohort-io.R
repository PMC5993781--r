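# Reading, validation and writing of the standard tabular formats.
#
# Canonical table dialect: TSV with a header row; the first column holds row
# labels. Missing values are encoded "NA"; counts may never be missing.

#' Load and cross-validate a cohort bundle
#'
#' Reads an OTU count table (samples x OTUs), a taxonomy table, sample
#' metadata, and optionally a rooted phylogeny, checks them against each other
#' and returns a single validated bundle. Samples are ordered by infant id and
#' then day since birth, so repeated loads are byte-identical.
#'
#' @param counts_path TSV; first column sample ids, remaining columns OTU
#'   counts (non-negative integers).
#' @param taxonomy_path TSV; first column OTU ids, then ranked lineage columns
#'   (`domain`, `phylum`, `class`, `order`, `family`, `genus`; `species` and
#'   `assignment_probability` optional). Unassigned ranks may be
#'   `"unclassified"`.
#' @param metadata_path TSV with columns `sample_id`, `infant_id`,
#'   `day_since_birth` (integer, day 1 = first day of life) and optionally
#'   `preservation` (`frozen`, `ethanol`, `unknown`).
#' @param tree_path optional newick file; leaf labels must cover all OTU ids.
#' @return An object of class `gut_cohort`: a list with elements `counts`
#'   (integer matrix), `taxonomy` (data.frame keyed by OTU id), `meta`
#'   (data.frame, one row per sample, ordered), and `tree` (`ape::phylo` or
#'   `NULL`).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' cfg <- sim_config(n_infants = 3, n_otus = 12, sampling_rate = 0.1,
#'                   late_starter = 0)
#' sim <- simulate_cohort(cfg, seed = 1)
#' write_cohort(sim, dir)
#' ch <- load_cohort(file.path(dir, "counts.tsv"), file.path(dir, "taxonomy.tsv"),
#'                   file.path(dir, "metadata.tsv"), file.path(dir, "tree.nwk"))
#' ch
#' @export
load_cohort <- function(counts_path, taxonomy_path, metadata_path,
                        tree_path = NULL) {
  for (p in c(counts_path, taxonomy_path, metadata_path, tree_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  counts_df <- read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  taxonomy <- read.delim(taxonomy_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta <- read.delim(metadata_path, check.names = FALSE,
                     stringsAsFactors = FALSE)

  sample_ids <- as.character(counts_df[[1L]])
  mat <- as.matrix(counts_df[, -1L, drop = FALSE])
  rownames(mat) <- sample_ids

  # counts must be non-negative integers; report the offending cell
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-integer or negative count at sample '",
         sample_ids[bad[1L, 1L]], "', OTU '", colnames(mat)[bad[1L, 2L]], "'")
  }
  storage.mode(mat) <- "integer"

  names(taxonomy)[1L] <- "otu_id"
  rownames(taxonomy) <- as.character(taxonomy$otu_id)

  req <- c("sample_id", "infant_id", "day_since_birth")
  if (!all(req %in% names(meta))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$infant_id <- as.character(meta$infant_id)
  meta$day_since_birth <- as.integer(meta$day_since_birth)

  validate_cohort(mat, taxonomy, meta,
                  tree = if (!is.null(tree_path)) ape::read.tree(tree_path))
}

#' Assemble and validate a cohort bundle from in-memory pieces
#'
#' @param counts integer matrix, samples x OTUs, with dimnames.
#' @param taxonomy data.frame with column `otu_id` and lineage columns.
#' @param meta data.frame with `sample_id`, `infant_id`, `day_since_birth`.
#' @param tree optional `ape::phylo`.
#' @return A `gut_cohort` object (see [load_cohort()]).
#' @export
validate_cohort <- function(counts, taxonomy, meta, tree = NULL) {
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  }
  if (any(meta$day_since_birth < 0L | meta$day_since_birth > 400L)) {
    stop("day_since_birth must lie in [0, 400]")
  }
  miss_counts <- setdiff(meta$sample_id, rownames(counts))
  miss_meta <- setdiff(rownames(counts), meta$sample_id)
  if (length(miss_counts) || length(miss_meta)) {
    stop("sample id mismatch between counts and metadata: ",
         paste(c(miss_counts, miss_meta), collapse = ", "))
  }
  miss_tax <- setdiff(colnames(counts), taxonomy$otu_id)
  if (length(miss_tax)) {
    stop("OTUs missing from taxonomy: ", paste(miss_tax, collapse = ", "))
  }
  zero <- rownames(counts)[rowSums(counts) == 0]
  if (length(zero)) {
    stop("all-zero sample row(s): ", paste(zero, collapse = ", "))
  }
  per_inf <- split(meta$day_since_birth, meta$infant_id)
  weak <- names(per_inf)[vapply(per_inf, function(d) {
    length(d) < 4L || length(unique(d)) < 2L
  }, logical(1))]
  if (length(weak)) {
    stop("infant(s) with < 4 samples or < 2 distinct days: ",
         paste(weak, collapse = ", "))
  }
  if (!is.null(tree)) {
    miss_leaf <- setdiff(colnames(counts), tree$tip.label)
    if (length(miss_leaf)) {
      stop("OTUs missing from tree leaves: ", paste(miss_leaf, collapse = ", "))
    }
    if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  }

  ord <- order(meta$infant_id, meta$day_since_birth, meta$sample_id)
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  counts <- counts[meta$sample_id, , drop = FALSE]
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id), ,
                       drop = FALSE]
  rownames(taxonomy) <- taxonomy$otu_id

  structure(list(counts = counts, taxonomy = taxonomy, meta = meta,
                 tree = tree),
            class = "gut_cohort")
}

#' @export
print.gut_cohort <- function(x, ...) {
  cat("gut_cohort:", nrow(x$counts), "samples,", ncol(x$counts), "OTUs,",
      length(unique(x$meta$infant_id)), "infants,",
      if (is.null(x$tree)) "no tree\n" else "with phylogeny\n")
  rng <- range(x$meta$day_since_birth)
  cat("  days", rng[1L], "-", rng[2L], "; library sizes",
      min(rowSums(x$counts)), "-", max(rowSums(x$counts)), "\n")
  invisible(x)
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Write a labeled distance matrix as TSV
#'
#' Square TSV with row and column labels; values round-trip through
#' [read_distance_matrix()] to at least 12 significant digits.
#'
#' @param d square numeric matrix with dimnames (e.g. from
#'   [distance_matrix()]).
#' @param path output file.
#' @export
write_distance_matrix <- function(d, path) {
  if (is.null(dim(d)) || nrow(d) == 0L) stop("empty distance matrix")
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  df <- data.frame(id = rownames(d),
                   matrix(fmt_num(d), nrow(d)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(d))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Write/read a labeled series table (rows x grid columns) as TSV
#'
#' `NA` entries are written as the literal string `NA` and read back as
#' missing. Round-trips are value-identical to at least 12 significant digits.
#'
#' @param values numeric matrix with dimnames (ragged input is rejected).
#' @param path output file.
#' @export
write_series_table <- function(values, path) {
  if (is.list(values) && !is.data.frame(values)) {
    len <- vapply(values, length, integer(1))
    if (length(unique(len)) != 1L) stop("ragged input: unequal row lengths")
    values <- do.call(rbind, values)
  }
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- seq_len(nrow(values))
  if (is.null(colnames(values))) colnames(values) <- seq_len(ncol(values))
  df <- data.frame(id = rownames(values),
                   matrix(fmt_num(values), nrow(values)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_table
#' @export
read_series_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Write a simulated cohort to TSV/newick files
#'
#' Writes `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `tree.nwk` and
#' `truth.tsv` (planted latent ground truth) into `dir`.
#'
#' @param sim a `gut_cohort` produced by [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cdf <- data.frame(sample_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(cdf, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sim$tree)) ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  if (!is.null(sim$truth)) {
    tr <- data.frame(key = names(sim$truth$scalars),
                     value = unlist(sim$truth$scalars),
                     stringsAsFactors = FALSE)
    write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
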