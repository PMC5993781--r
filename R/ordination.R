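# Ordination and inference: non-metric MDS with Kruskal stress-1, PERMANOVA,
# axis-vs-time regression, and fixed-df spline smooths.

#' Weighted isotonic (monotone) regression
#'
#' Least-squares non-decreasing fit by pool-adjacent-violators. Preserves the
#' weighted mean of the input.
#'
#' @param targets numeric vector in predictor order.
#' @param weights positive weights of the same length.
#' @return non-decreasing fitted values.
#' @examples
#' isotonic_fit(c(1, 3, 2))  # 1, 2.5, 2.5
#' @export
isotonic_fit <- function(targets, weights = rep(1, length(targets))) {
  if (length(targets) == 0L) stop("empty input")
  if (length(weights) != length(targets)) stop("weights length mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  pava_cpp(as.numeric(targets), as.numeric(weights))
}

lower_tri <- function(m) m[lower.tri(m)]

kruskal_stress <- function(dvec, dhat) {
  sqrt(sum((dvec - dhat)^2) / sum(dvec^2))
}

# disparities: isotonic fit of configuration distances over the dissimilarity
# order; ties in the dissimilarities are broken by the current configuration
# distance (Kruskal's primary approach, favouring monotonicity)
disparities <- function(delta, dvec) {
  ord <- order(delta, dvec, method = "radix")
  dhat <- numeric(length(delta))
  dhat[ord] <- isotonic_fit(dvec[ord])
  dhat
}

#' Non-metric multidimensional scaling
#'
#' Kruskal-style nMDS: initialized from classical metric scaling of `d`, then
#' alternates isotonic regression of the configuration distances on the rank
#' order of `d` with a Guttman-transform descent step on stress-1
#' `sqrt(sum((dhat - delta)^2) / sum(delta^2))`. Only stress-improving steps
#' are accepted, so stress is non-increasing; iteration stops when the
#' relative stress change drops below `tol`. Axes are ordered by variance and
#' the first axis' sign is fixed so its correlation with sample index is
#' non-negative.
#'
#' @param d symmetric distance matrix (labels in dimnames).
#' @param k embedding dimension.
#' @param max_iter,tol iteration controls.
#' @param seed RNG seed (used only to jitter a rank-deficient classical-scaling
#'   start).
#' @return object of class `nmds_fit`: `coordinates` (n x k, centered),
#'   `stress`, `n_iterations`, `converged`.
#' @export
nmds <- function(d, k = 2L, max_iter = 200L, tol = 1e-6, seed = 1L) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("non-finite distances")
  if (all(d == 0)) stop("degenerate distance matrix (all zeros)")
  n <- nrow(d)
  if (n < k + 2L) stop("need at least k + 2 samples")
  delta <- lower_tri(d)

  x <- cmdscale(d, k = k)
  if (ncol(x) < k || any(apply(x, 2L, var) == 0)) {
    pad <- with_seed(seed, matrix(rnorm(n * k, 0, 1e-6), n, k))
    if (ncol(x) < k) x <- cbind(x, matrix(0, n, k - ncol(x)))
    x <- x + pad
  }

  config_dist <- function(x) lower_tri(as.matrix(dist(x)))
  dvec <- config_dist(x)
  dhat <- disparities(delta, dvec)
  stress <- kruskal_stress(dvec, dhat)
  stress0 <- stress
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # Guttman transform with the current disparities
    ratio <- matrix(0, n, n)
    ratio[lower.tri(ratio)] <- ifelse(dvec > 0, dhat / dvec, 0)
    ratio <- ratio + t(ratio)
    b <- -ratio
    diag(b) <- rowSums(ratio)
    x_new <- (b %*% x) / n
    dvec_new <- config_dist(x_new)
    dhat_new <- disparities(delta, dvec_new)
    stress_new <- kruskal_stress(dvec_new, dhat_new)
    if (stress_new > stress) break            # only accept improving steps
    done <- (stress - stress_new) < tol * max(stress, .Machine$double.eps)
    x <- x_new; dvec <- dvec_new; dhat <- dhat_new; stress <- stress_new
    if (done) { converged <- TRUE; break }
  }

  x <- scale(x, center = TRUE, scale = FALSE)
  ord <- order(apply(x, 2L, var), decreasing = TRUE)
  x <- x[, ord, drop = FALSE]
  if (stats::sd(x[, 1L]) > 0 && cor(x[, 1L], seq_len(n)) < 0) {
    x[, 1L] <- -x[, 1L]
  }
  dimnames(x) <- list(rownames(d), paste0("MDS", seq_len(k)))
  structure(list(coordinates = x, stress = stress,
                 initial_stress = stress0,
                 n_iterations = it, converged = converged),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat("nMDS:", nrow(x$coordinates), "points in", ncol(x$coordinates),
      "dimensions; stress-1 =", signif(x$stress, 4),
      if (x$converged) "(converged)\n" else "(not converged)\n")
  invisible(x)
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance.
#' `SS_total = sum(d^2)/n` over all pairs, `SS_within` sums within-group
#' squared distances scaled by group size, and the pseudo-F is
#' `(SS_among/(a-1)) / (SS_within/(n-a))`. The p-value uses the add-one
#' convention `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)`, so its
#' resolution is `1/(n_permutations + 1)` and it is never exactly zero.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param n_permutations number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return object of class `permanova`: `pseudo_f`, `r_squared`, `p_value`,
#'   `n_permutations`, `ss` (among/within/total).
#' @export
permanova <- function(d, groups, n_permutations = 1000L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4L) stop("need at least 4 samples")
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length must match d")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) {
    stop("group(s) of size 1: ", paste(names(tab)[tab < 2L], collapse = ", "))
  }
  a <- length(tab)
  d2 <- d^2
  ss_total <- sum(lower_tri(d2)) / n
  grp <- as.integer(factor(groups)) - 1L
  ss_within <- sum(vapply(split(seq_len(n), grp), function(idx) {
    sum(lower_tri(d2[idx, idx, drop = FALSE])) / length(idx)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  f_obs <- (ss_among / (a - 1)) / (ss_within / (n - a))

  perms <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) sample.int(n), integer(n))
  })
  f_perm <- permanova_F_cpp(d2, grp, perms, a)
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)

  structure(list(pseudo_f = f_obs, r_squared = ss_among / ss_total,
                 p_value = p, n_permutations = as.integer(n_permutations),
                 ss = c(among = ss_among, within = ss_within,
                        total = ss_total),
                 df = c(among = a - 1L, within = n - a)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", signif(x$pseudo_f, 4),
      " R2 =", signif(x$r_squared, 4),
      " p =", signif(x$p_value, 4),
      "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Ordinary least squares of an ordination axis on time
#'
#' Regresses the first nMDS axis on days since birth; reports the
#' sign-invariant R-squared and the two-sided slope-t p-value.
#'
#' @param fit an `nmds_fit`, or directly a numeric axis vector.
#' @param days days since birth, aligned with samples (>= 3, not constant).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
axis_time_regression <- function(fit, days) {
  axis1 <- if (inherits(fit, "nmds_fit")) fit$coordinates[, 1L] else fit
  if (length(axis1) != length(days)) stop("days must align with samples")
  if (length(axis1) < 3L) stop("need at least 3 samples")
  if (length(unique(days)) < 2L) stop("days are constant")
  m <- lm(axis1 ~ days)
  sm <- summary(m)
  list(slope = unname(coef(m)[2L]),
       intercept = unname(coef(m)[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L])
}

#' Fixed-df cubic spline smooth
#'
#' Unpenalized least-squares fit on a cubic B-spline basis of `df` basis
#' functions (interior knots at quantiles of `x`), the fixed-df stand-in for
#' a penalized additive-model smooth. Returns fitted values, analytic
#' pointwise 95% bands from the linear-model covariance, the derivative of
#' the fitted spline, and R-squared. Deterministic.
#'
#' @param x predictor values (>= df + 1 distinct values).
#' @param y responses.
#' @param df number of basis functions (>= 4 for a cubic basis).
#' @param grid evaluation grid (default: sorted unique `x`).
#' @return object of class `smooth_fit` with fields `grid`, `fitted`,
#'   `lower95`, `upper95`, `derivative`, `r_squared`, `df`.
#' @export
smooth_fit <- function(x, y, df = 9L, grid = sort(unique(x))) {
  if (df < 4L) stop("df must be >= 4 for a cubic basis; reduce to a line fit")
  if (length(x) != length(y)) stop("x and y must align")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  if (length(unique(x)) < df + 1L) {
    stop("need at least df + 1 = ", df + 1L,
         " distinct x values; use a smaller df")
  }
  basis <- splines::bs(x, df = df, intercept = TRUE)
  fitm <- lm(y ~ basis - 1)
  beta <- coef(fitm)
  rss <- sum(residuals(fitm)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1

  knots <- attr(basis, "knots")
  bnd <- attr(basis, "Boundary.knots")
  aug <- c(rep(bnd[1L], 4L), knots, rep(bnd[2L], 4L))
  g <- pmin(pmax(grid, bnd[1L]), bnd[2L])
  bg <- splines::splineDesign(aug, g, ord = 4L)
  dg <- splines::splineDesign(aug, g, ord = 4L, derivs = 1L)
  fitted <- as.vector(bg %*% beta)
  deriv <- as.vector(dg %*% beta)
  se <- sqrt(pmax(0, rowSums((bg %*% vcov(fitm)) * bg)))
  tq <- qt(0.975, fitm$df.residual)
  structure(list(grid = grid, fitted = fitted,
                 lower95 = fitted - tq * se, upper95 = fitted + tq * se,
                 derivative = deriv, r_squared = r2, df = as.integer(df),
                 coefficients = beta),
            class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat("spline smooth: df =", x$df, " R2 =", signif(x$r_squared, 4),
      " grid of", length(x$grid), "points\n")
  invisible(x)
}

#' @export
plot.smooth_fit <- function(x, ...) {
  plot(x$grid, x$fitted, type = "l", xlab = "x", ylab = "fitted", ...)
  graphics::lines(x$grid, x$lower95, lty = 2)
  graphics::lines(x$grid, x$upper95, lty = 2)
  invisible(x)
}
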