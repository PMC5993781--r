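# Pairwise dissimilarity kernels: Bray-Curtis and generalized UniFrac.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`; 0 for identical vectors, 1 for disjoint
#' supports.
#'
#' @param x,y non-negative numeric vectors of equal length, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(2, 2, 0), c(0, 2, 2))  # 0.5
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("negative abundance")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Precompute per-branch leaf sets of a rooted phylogeny
#'
#' For each branch (edge) of the tree, records its length and the OTU leaves
#' below it, as the incidence matrix used by [generalized_unifrac()]. The
#' (non-existent) branch above the root is naturally excluded. Unrooted trees
#' are midpoint-rooted with a warning.
#'
#' @param tree an `ape::phylo` with branch lengths; leaf labels are OTU ids.
#' @param otu_ids the OTU ordering of the abundance vectors; must be a subset
#'   of the tree's leaves.
#' @return a list of class `branch_table`: `lengths` (per branch),
#'   `incidence` (OTUs x branches 0/1 matrix), `otu_ids`.
#' @export
branch_table <- function(tree, otu_ids = tree$tip.label) {
  if (!ape::is.rooted(tree)) {
    warning("unrooted tree: midpoint-rooting for UniFrac")
    tree <- phangorn_free_midpoint(tree)
  }
  missing <- setdiff(otu_ids, tree$tip.label)
  if (length(missing)) {
    stop("OTU(s) missing from tree: ", paste(missing, collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  # postorder: accumulate, for every node, which tips lie below it
  below <- matrix(FALSE, n_tip + n_node, n_tip)
  below[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    below[par, ] <- below[par, ] | below[child, ]
  }
  inc <- t(below[tr$edge[, 2L], , drop = FALSE])  # tips x edges
  rownames(inc) <- tree$tip.label
  inc <- inc[otu_ids, , drop = FALSE]
  structure(list(lengths = tr$edge.length,
                 incidence = 1 * inc,
                 otu_ids = otu_ids),
            class = "branch_table")
}

phangorn_free_midpoint <- function(tree) {
  if (requireNamespace("phangorn", quietly = TRUE)) {
    return(phangorn::midpoint(tree))
  }
  # fallback: root at one end of the tree diameter
  dm <- ape::cophenetic.phylo(tree)
  ij <- which(dm == max(dm), arr.ind = TRUE)[1L, ]
  ape::root(tree, outgroup = rownames(dm)[ij[1L]], resolve.root = TRUE)
}

#' Generalized UniFrac dissimilarity
#'
#' With per-branch lengths `L_b` and the relative-abundance mass below each
#' branch `p_b`, `q_b` for the two samples,
#' `d = sum(L_b (p+q)^alpha |p-q|/(p+q)) / sum(L_b (p+q)^alpha)`, summed over
#' branches with `p + q > 0`. `alpha = 1` is abundance-weighted normalized
#' UniFrac; `alpha = 0.5` (the default used throughout) moderates the weight
#' on abundant lineages.
#'
#' @param x,y relative-abundance vectors aligned to `branches$otu_ids`,
#'   each summing to 1.
#' @param branches a [branch_table()].
#' @param alpha abundance weight exponent in \[0, 1\].
#' @return dissimilarity in \[0, 1\].
#' @export
generalized_unifrac <- function(x, y, branches, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (length(x) != length(branches$otu_ids) ||
      length(y) != length(branches$otu_ids)) {
    stop("abundance vectors must align with branch table OTUs")
  }
  if (abs(sum(x) - 1) > 1e-6 || abs(sum(y) - 1) > 1e-6) {
    stop("inputs must be relative abundances summing to 1")
  }
  p <- as.vector(x %*% branches$incidence)
  q <- as.vector(y %*% branches$incidence)
  keep <- (p + q) > 0
  if (!any(keep)) stop("no shared tree mass between samples")
  s <- (p + q)[keep]
  w <- branches$lengths[keep] * s^alpha
  den <- sum(w)
  if (den == 0) stop("empty denominator: no shared tree mass")
  sum(w * abs(p - q)[keep] / s) / den
}

#' All-pairs distance matrix
#'
#' @param rel samples x features relative-abundance matrix with rownames.
#' @param metric `"bray_curtis"` or `"gunifrac"`.
#' @param tree rooted `ape::phylo`; required for `"gunifrac"`.
#' @param alpha generalized-UniFrac exponent.
#' @return symmetric labeled matrix with zero diagonal, entries in \[0, 1\].
#' @export
distance_matrix <- function(rel, metric = c("bray_curtis", "gunifrac"),
                            tree = NULL, alpha = 0.5) {
  metric <- match.arg(metric)
  if (anyNA(rel) || any(!is.finite(rel))) stop("non-finite abundances")
  n <- nrow(rel)
  if (metric == "bray_curtis") {
    man <- as.matrix(dist(rel, method = "manhattan"))
    rs <- rowSums(rel)
    d <- man / outer(rs, rs, "+")
  } else {
    if (is.null(tree)) stop("metric 'gunifrac' requires a tree")
    bt <- branch_table(tree, colnames(rel))
    mass <- rel %*% bt$incidence                      # samples x branches
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      p <- mass[i, ]
      for (j in seq((i + 1L), n)) {
        q <- mass[j, ]
        s <- p + q
        keep <- s > 0
        w <- bt$lengths[keep] * s[keep]^alpha
        d[i, j] <- d[j, i] <- sum(w * abs(p - q)[keep] / s[keep]) / sum(w)
      }
    }
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(rel), rownames(rel))
  d
}
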