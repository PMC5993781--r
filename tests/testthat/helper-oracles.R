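# Independent brute-force oracles. Each deliberately avoids the code paths of
# the implementation it checks.

bc_oracle <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# descendant tips of a node, by naive recursion over the edge list
tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

# generalized UniFrac by explicit summation over an enumerated branch list
unifrac_oracle <- function(x, y, tree, alpha) {
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    leaves <- tips_below(tree, tree$edge[e, 2])
    p <- sum(x[leaves]); q <- sum(y[leaves])
    if (p + q > 0) {
      w <- tree$edge.length[e] * (p + q)^alpha
      num <- num + w * abs(p - q) / (p + q)
      den <- den + w
    }
  }
  num / den
}

# DTW by exhaustive enumeration of monotone warping paths (symmetric2
# weights: cost of the start cell once, then +c for a horizontal or vertical
# step and +2c for a diagonal step into the new cell)
dtw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  cost <- function(i, j) abs(x[i] - y[j])
  best <- Inf
  walk <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc + cost(i + 1, j))
    if (j < m) walk(i, j + 1, acc + cost(i, j + 1))
    if (i < n && j < m) walk(i + 1, j + 1, acc + 2 * cost(i + 1, j + 1))
  }
  walk(1, 1, cost(1, 1))
  best
}

# PERMANOVA sums written out longhand
permanova_oracle <- function(d, groups) {
  n <- nrow(d)
  ss_tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in seq(a + 1, length(idx))) {
        s <- s + d[idx[a], idx[b]]^2
      }
    }
    ss_w <- ss_w + s / length(idx)
  }
  a <- length(unique(groups))
  list(ss_total = ss_tot, ss_within = ss_w, ss_among = ss_tot - ss_w,
       pseudo_f = ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a)),
       r_squared = (ss_tot - ss_w) / ss_tot)
}

# exact weighted monotone regression for tiny n: enumerate all partitions of
# 1..n into consecutive blocks, pool each block at its weighted mean, keep
# monotone candidates, return the weighted-least-squares best
pava_oracle <- function(y, w) {
  n <- length(y)
  cuts <- expand.grid(rep(list(c(TRUE, FALSE)), n - 1))
  best <- NULL; best_sse <- Inf
  for (r in seq_len(nrow(cuts))) {
    bounds <- c(0, which(unlist(cuts[r, ])), n)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- seq(bounds[b] + 1, bounds[b + 1])
      fit[idx] <- sum(w[idx] * y[idx]) / sum(w[idx])
    }
    if (is.unsorted(fit)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse) { best_sse <- sse; best <- fit }
  }
  best
}

# naive O(n^3) complete-linkage agglomeration, tracking member sets only
linkage_heights_oracle <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; pick <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; pick <- c(i, j) }
      }
    }
    heights <- c(heights, best)
    clusters[[pick[1]]] <- c(clusters[[pick[1]]], clusters[[pick[2]]])
    clusters[[pick[2]]] <- NULL
  }
  heights
}

# all permutations of 1..n as rows (n small)
gtools_style_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_style_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

random_composition <- function(k) {
  v <- stats::runif(k)
  v / sum(v)
}

random_distance_matrix <- function(n) {
  p <- matrix(stats::runif(n * 3), n)
  d <- as.matrix(stats::dist(p))
  dimnames(d) <- list(letters[seq_len(n)], letters[seq_len(n)])
  d
}
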