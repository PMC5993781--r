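# Library normalization, relative abundances, taxon aggregation, prevalence
# and alpha diversity.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Common-scaling library normalization
#'
#' Each count c in a library of total size L becomes
#' `round(c * S / L)`, where S is the smallest library size in the table (or
#' an explicit `reference_size`). This produces the scaling one would obtain
#' by averaging infinitely many rarefactions; rounding is half-away-from-zero.
#' The minimum-size library is returned unchanged.
#'
#' @param counts integer matrix, samples x OTUs (or a `gut_cohort`).
#' @param reference_size optional target size S; must not exceed the smallest
#'   library.
#' @return integer matrix of scaled counts.
#' @examples
#' m <- rbind(A = c(10, 90), B = c(25, 25))
#' common_scale(m)        # A scaled from 100 to 50 reads
#' @export
common_scale <- function(counts, reference_size = NULL) {
  if (inherits(counts, "gut_cohort")) counts <- counts$counts
  ls <- rowSums(counts)
  if (any(ls == 0)) {
    stop("zero-sum library: ", rownames(counts)[which(ls == 0)[1L]])
  }
  s <- if (is.null(reference_size)) min(ls) else reference_size
  if (s > min(ls)) stop("reference_size (", s, ") exceeds smallest library (",
                        min(ls), ")")
  out <- round_half_away(counts * (s / ls))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  attr(out, "reference_size") <- s
  out
}

#' Row-normalize counts to relative abundances
#'
#' @param counts numeric matrix, samples x features, all row sums > 0 (or a
#'   `gut_cohort`).
#' @return matrix of fractions; rows sum to 1. Attribute `level` records the
#'   feature level (`"otu"` unless set by [aggregate_by_rank()]).
#' @export
to_relative <- function(counts) {
  if (inherits(counts, "gut_cohort")) counts <- counts$counts
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop("zero-sum row: ", rownames(counts)[which(rs == 0)[1L]])
  }
  rel <- counts / rs
  attr(rel, "level") <- "otu"
  rel
}

#' Aggregate feature columns by taxonomic rank
#'
#' Columns are summed within each value of the chosen rank; missing or empty
#' assignments count as `"unclassified"`, which is kept as its own column.
#' Row sums are preserved exactly.
#'
#' @param rel samples x OTUs matrix (relative abundances or counts).
#' @param taxonomy data.frame with `otu_id` and the rank column.
#' @param rank `"phylum"` or `"genus"`.
#' @return matrix with one column per rank value, ordered by descending total.
#' @export
aggregate_by_rank <- function(rel, taxonomy, rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  key <- taxonomy[[rank]][match(colnames(rel), taxonomy$otu_id)]
  if (anyNA(match(colnames(rel), taxonomy$otu_id))) {
    stop("OTUs missing from taxonomy: ",
         paste(setdiff(colnames(rel), taxonomy$otu_id), collapse = ", "))
  }
  key[is.na(key) | key == ""] <- "unclassified"
  out <- t(rowsum(t(rel), group = key))
  out <- out[, order(-colSums(out), colnames(out), method = "radix"),
             drop = FALSE]
  attr(out, "level") <- rank
  out
}

#' Rank features by grand total relative abundance
#'
#' Ties are broken lexicographically (C locale) by feature id.
#'
#' @param rel samples x features matrix.
#' @param n how many features to return (clamped to the number available).
#' @return character vector of feature ids, most abundant first.
#' @export
top_n_features <- function(rel, n) {
  if (n < 1) stop("n must be >= 1")
  tot <- colSums(rel)
  ids <- colnames(rel)
  ord <- order(-tot, ids, method = "radix")
  ids[ord][seq_len(min(n, length(ids)))]
}

#' Between-infant OTU sharing spectrum
#'
#' An OTU is present in an infant if it has count > 0 in at least one of that
#' infant's samples. `spectrum[k]` counts OTUs present in exactly `k`
#' infants; OTUs absent everywhere contribute nowhere.
#'
#' @param counts samples x OTUs count matrix.
#' @param meta metadata with `sample_id`, `infant_id`.
#' @return integer vector of length `n_infants`, named `"1"`..`"n"`.
#' @export
prevalence_spectrum <- function(counts, meta) {
  infants <- unique(meta$infant_id)
  pres <- vapply(infants, function(i) {
    rows <- meta$sample_id[meta$infant_id == i]
    colSums(counts[rows, , drop = FALSE] > 0) > 0
  }, logical(ncol(counts)))
  k <- rowSums(pres)
  spectrum <- tabulate(k[k > 0], nbins = length(infants))
  names(spectrum) <- seq_along(spectrum)
  spectrum
}

#' Per-sample alpha diversity
#'
#' @param counts samples x OTUs matrix with positive row sums.
#' @return data.frame with `sample_id`, `observed_otus`, and `shannon`
#'   (natural log units).
#' @export
alpha_diversity <- function(counts) {
  if (inherits(counts, "gut_cohort")) counts <- counts$counts
  rs <- rowSums(counts)
  if (any(rs == 0)) stop("zero-sum row")
  shannon <- apply(counts / rs, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  data.frame(sample_id = rownames(counts),
             observed_otus = as.integer(rowSums(counts > 0)),
             shannon = shannon,
             row.names = NULL, stringsAsFactors = FALSE)
}
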