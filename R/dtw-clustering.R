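# Dynamic time warping of phylum-level trajectories and complete-linkage
# clustering.

#' Dynamic time warping distance
#'
#' Euclidean (absolute-difference) pointwise local cost, `symmetric2` step
#' pattern (`D(i,j) = min(D(i-1,j) + c, D(i,j-1) + c, D(i-1,j-1) + 2c)`), no
#' global constraint on the warping path. The normalized distance divides the
#' raw cost by `n + m`, the normalization admitted by this step pattern.
#'
#' @param x,y non-empty finite numeric series (lengths may differ).
#' @return list with `raw` and `normalized`.
#' @examples
#' dtw_distance(c(0), c(3))  # raw 3, normalized 1.5
#' @export
dtw_distance <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty series")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite series")
  raw <- dtw_cost_cpp(as.numeric(x), as.numeric(y))
  list(raw = raw, normalized = raw / (length(x) + length(y)))
}

#' Extract each infant's day-ordered phylum trajectories
#'
#' Aggregates the cohort's relative abundances to phylum level and splits
#' them into per-infant, day-ordered series matrices — the raw (observed,
#' non-interpolated) series DTW is designed for.
#'
#' @param cohort a `gut_cohort`.
#' @param phyla phylum columns to keep (all must be present after
#'   aggregation).
#' @return named list per infant of (days x phyla) matrices, ordered by day.
#' @export
phylum_series <- function(cohort, phyla = c("Actinobacteria", "Bacteroidetes",
                                            "Firmicutes", "Proteobacteria")) {
  rel <- to_relative(cohort$counts)
  ph <- aggregate_by_rank(rel, cohort$taxonomy, "phylum")
  missing <- setdiff(phyla, colnames(ph))
  if (length(missing)) {
    stop("missing phylum column(s): ", paste(missing, collapse = ", "),
         " (aggregate first or check taxonomy)")
  }
  infants <- unique(cohort$meta$infant_id)
  out <- lapply(infants, function(i) {
    rows <- which(cohort$meta$infant_id == i)
    rows <- rows[order(cohort$meta$day_since_birth[rows])]
    m <- ph[cohort$meta$sample_id[rows], phyla, drop = FALSE]
    rownames(m) <- cohort$meta$day_since_birth[rows]
    m
  })
  names(out) <- infants
  out
}

#' Pairwise mean normalized DTW distances over phylum trajectories
#'
#' For every infant pair and every phylum, the normalized DTW distance
#' between the two observed series; the combined matrix is the arithmetic
#' mean over the phyla.
#'
#' @param series per-infant list of day-ordered (days x phyla) matrices, as
#'   from [phylum_series()].
#' @param phyla the phylum columns to use.
#' @return object of class `dtw_matrix`: `per_phylum` (named list of infant x
#'   infant matrices) and `combined`.
#' @export
phylum_dtw_matrix <- function(series,
                              phyla = c("Actinobacteria", "Bacteroidetes",
                                        "Firmicutes", "Proteobacteria")) {
  infants <- names(series)
  n <- length(infants)
  for (s in series) {
    missing <- setdiff(phyla, colnames(s))
    if (length(missing)) {
      stop("missing phylum column(s): ", paste(missing, collapse = ", "))
    }
  }
  per <- lapply(phyla, function(ph) {
    m <- matrix(0, n, n, dimnames = list(infants, infants))
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        m[i, j] <- m[j, i] <-
          dtw_distance(series[[i]][, ph], series[[j]][, ph])$normalized
      }
    }
    m
  })
  names(per) <- phyla
  combined <- Reduce(`+`, per) / length(per)
  structure(list(per_phylum = per, combined = combined),
            class = "dtw_matrix")
}

#' @export
print.dtw_matrix <- function(x, ...) {
  cat("DTW distance matrix:", nrow(x$combined), "infants, phyla:",
      paste(names(x$per_phylum), collapse = ", "), "\n")
  print(signif(x$combined, 3))
  invisible(x)
}

#' Agglomerative complete-linkage clustering
#'
#' Complete linkage: the distance between clusters is the maximum pairwise
#' distance. Ties in the merge choice are broken by the lexicographically
#' smallest pair of current cluster indices, so results are deterministic.
#' Returns a standard `hclust` object (so `plot()`, `cutree()` and
#' `ape::as.phylo()` apply).
#'
#' @param d symmetric distance matrix with labels, no `NaN`.
#' @param linkage only `"complete"` is implemented.
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(d, linkage = "complete") {
  linkage <- match.arg(linkage, "complete")
  d <- as.matrix(d)
  if (anyNA(d)) stop("NaN/NA in distance matrix")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active clusters carry hclust-convention ids: -i for singletons, merge row
  # numbers for merged clusters
  active_id <- -seq_len(n)
  cur <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  merged_members <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(active_id)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        if (cur[i, j] < best_d) {           # strict <: earliest pair wins ties
          best_d <- cur[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    pair <- c(active_id[i], active_id[j])
    # hclust row convention: singletons before clusters, ascending otherwise
    merge[step, ] <- pair[order(pair >= 0L, abs(pair))]
    height[step] <- best_d
    merged_members[[step]] <- c(members[[i]], members[[j]])
    # complete linkage update
    newrow <- pmax(cur[i, ], cur[j, ])[-c(i, j)]
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- cur[keep, keep, drop = FALSE]
    cur <- rbind(cbind(cur, newrow), c(newrow, 0))
    members <- c(members[keep], merged_members[step])
    active_id <- c(active_id[keep], step)
  }

  # leaf order by traversing merges
  unpack <- function(id) {
    if (id < 0L) return(-id)
    c(unpack(merge[id, 1L]), unpack(merge[id, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = unpack(n - 1L), labels = labels,
                 method = "complete", call = match.call(),
                 dist.method = "precomputed"),
            class = "hclust")
}

#' Export a dendrogram as newick
#'
#' Branch lengths are the differences of cumulative merge heights, so
#' leaf-to-root path lengths equal the final merge height.
#'
#' @param h an `hclust` (e.g. from [hierarchical_cluster()]).
#' @param path optional output file.
#' @return the newick string, invisibly if written to `path`.
#' @export
dendrogram_newick <- function(h, path = NULL) {
  phy <- ape::as.phylo(h)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
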