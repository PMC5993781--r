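# Pseudo-day interpolation, contemporaneous distance profiles, convergence
# window detection, OTU-convergence correlations, and twin similarity.

#' Interpolate one infant's composition series to a pseudo-day grid
#'
#' Each feature is interpolated independently with a cubic spline using the
#' exact-cubic end condition (a cubic polynomial fitted through the four
#' points at each end of the series; `stats::spline(method = "fmm")`),
#' evaluated at `n_points` equally spaced pseudo-days spanning the infant's
#' own `[first_day, last_day]`. Negative interpolated values are set to zero
#' and each grid composition is then renormalized to sum to 1. Duplicate-day
#' samples are averaged before fitting.
#'
#' @param days sampled days (>= 4 distinct values).
#' @param comp samples x features matrix of relative abundances, rows aligned
#'   with `days`.
#' @param n_points grid length (default 365 pseudo-days).
#' @param grid `"span"` (default) spaces the grid over the infant's own
#'   `[first_day, last_day]`, so series of unequal length align
#'   point-by-point; `"calendar"` evaluates at integer days `1..n_points`,
#'   extrapolating the end cubics outside the sampled range.
#' @return list with `values` (n_points x features), `grid_days` (the real
#'   days the grid points represent), `first_day`, `last_day`.
#' @export
interpolate_infant <- function(days, comp, n_points = 365L,
                               grid = c("span", "calendar")) {
  grid <- match.arg(grid)
  comp <- as.matrix(comp)
  if (any(!is.finite(days)) || any(!is.finite(comp))) {
    stop("non-finite input")
  }
  if (length(days) != nrow(comp)) stop("days must align with rows of comp")
  if (anyDuplicated(days)) {
    comp <- rowsum(comp, group = days) / as.vector(table(days))
    days <- sort(unique(days))
  } else {
    ord <- order(days)
    days <- days[ord]
    comp <- comp[ord, , drop = FALSE]
  }
  if (length(days) < 4L) {
    stop("need >= 4 distinct sampled days for exact-cubic end conditions")
  }
  xout <- if (grid == "span") {
    seq(min(days), max(days), length.out = n_points)
  } else {
    seq_len(n_points)
  }
  vals <- apply(comp, 2L, function(v) {
    spline(days, v, xout = xout, method = "fmm")$y
  })
  vals[vals < 0] <- 0
  rs <- rowSums(vals)
  if (any(rs == 0)) stop("interpolated composition degenerated to all zero")
  vals <- vals / rs
  colnames(vals) <- colnames(comp)
  list(values = vals, grid_days = xout,
       first_day = min(days), last_day = max(days))
}

#' Interpolate every infant in a cohort
#'
#' @param cohort a `gut_cohort`.
#' @param n_points pseudo-day grid length.
#' @param features optional subset of feature columns.
#' @param grid grid convention, see [interpolate_infant()].
#' @return object of class `interpolated_series`: a named list `series` (per
#'   infant, the [interpolate_infant()] slice), `pseudo_day_map` (infants x
#'   n_points matrix of real days), `n_points`.
#' @export
interpolate_cohort <- function(cohort, n_points = 365L, features = NULL,
                               grid = c("span", "calendar")) {
  grid <- match.arg(grid)
  rel <- to_relative(cohort$counts)
  if (!is.null(features)) rel <- rel[, features, drop = FALSE]
  infants <- unique(cohort$meta$infant_id)
  series <- lapply(infants, function(i) {
    rows <- cohort$meta$infant_id == i
    interpolate_infant(cohort$meta$day_since_birth[rows],
                       rel[cohort$meta$sample_id[rows], , drop = FALSE],
                       n_points = n_points, grid = grid)
  })
  names(series) <- infants
  pdm <- do.call(rbind, lapply(series, `[[`, "grid_days"))
  rownames(pdm) <- infants
  structure(list(series = series, pseudo_day_map = pdm,
                 n_points = as.integer(n_points)),
            class = "interpolated_series")
}

#' Drop infants whose sampling started late
#'
#' Infants whose first sampled day is at or after `cutoff_day` are removed
#' (with a notice), mirroring the exclusion of late starters from
#' contemporaneous-distance analyses.
#'
#' @param series an `interpolated_series`.
#' @param cutoff_day first-day cutoff (default 54).
#' @return the filtered `interpolated_series` (>= 2 infants must remain).
#' @export
exclude_late_starters <- function(series, cutoff_day = 54L) {
  first <- vapply(series$series, `[[`, numeric(1), "first_day")
  drop <- names(first)[first >= cutoff_day]
  if (length(drop)) {
    message("excluding late starter(s): ", paste(drop, collapse = ", "),
            " (first sampled day >= ", cutoff_day, ")")
  }
  keep <- setdiff(names(series$series), drop)
  if (length(keep) < 2L) stop("fewer than 2 infants remain after exclusion")
  series$series <- series$series[keep]
  series$pseudo_day_map <- series$pseudo_day_map[keep, , drop = FALSE]
  series
}

#' Contemporaneous pairwise distances across the cohort
#'
#' For each of the pseudo-day grid indices, the chosen dissimilarity between
#' every unordered infant pair at that index; per-infant means (each infant's
#' mean distance to all others per pseudo-day) and the grand mean over
#' infants.
#'
#' @param series an `interpolated_series`.
#' @param metric `"bray_curtis"` or `"gunifrac"`.
#' @param tree required for `"gunifrac"`.
#' @param alpha generalized-UniFrac exponent.
#' @return object of class `convergence_profile`: `pairwise` (grid x pairs),
#'   `per_infant_mean` (infants x grid), `grand_mean` (length-grid vector),
#'   `infants`, `metric`.
#' @export
contemporaneous_distances <- function(series,
                                      metric = c("bray_curtis", "gunifrac"),
                                      tree = NULL, alpha = 0.5) {
  metric <- match.arg(metric)
  infants <- names(series$series)
  n_inf <- length(infants)
  if (n_inf < 2L) stop("need at least 2 infants")
  np <- series$n_points
  if (metric == "gunifrac") {
    if (is.null(tree)) stop("metric 'gunifrac' requires a tree")
    bt <- branch_table(tree, colnames(series$series[[1L]]$values))
    mass <- lapply(series$series, function(s) s$values %*% bt$incidence)
  }
  pairs <- utils::combn(n_inf, 2L)
  pw <- matrix(NA_real_, np, ncol(pairs))
  colnames(pw) <- apply(pairs, 2L, function(p) {
    paste(infants[p[1L]], infants[p[2L]], sep = "|")
  })
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    if (metric == "bray_curtis") {
      a <- series$series[[i]]$values
      b <- series$series[[j]]$values
      pw[, k] <- rowSums(abs(a - b)) / rowSums(a + b)
    } else {
      p <- mass[[i]]; q <- mass[[j]]
      s <- p + q
      keep <- s > 0
      w <- matrix(0, np, length(bt$lengths))
      w[keep] <- rep(bt$lengths, each = np)[keep] * s[keep]^alpha
      num <- matrix(0, np, length(bt$lengths))
      num[keep] <- w[keep] * abs(p - q)[keep] / s[keep]
      pw[, k] <- rowSums(num) / rowSums(w)
    }
  }
  pim <- matrix(0, n_inf, np, dimnames = list(infants, NULL))
  for (i in seq_len(n_inf)) {
    cols <- which(pairs[1L, ] == i | pairs[2L, ] == i)
    pim[i, ] <- rowMeans(pw[, cols, drop = FALSE])
  }
  structure(list(pairwise = pw, per_infant_mean = pim,
                 grand_mean = colMeans(pim), infants = infants,
                 metric = metric, n_points = np),
            class = "convergence_profile")
}

#' Detect the window of accelerated convergence
#'
#' Fits a fixed-df spline smooth to the grand-mean distance profile and finds
#' the maximal contiguous run of pseudo-days, containing the steepest
#' descent, on which the fitted derivative is below `slope_fraction` times
#' the most negative derivative. Because unpenalized spline fits have
#' unreliable derivatives at the extremes of the grid, the steepest descent
#' is sought over the interior (the outermost `boundary_exclude` fraction of
#' grid points on each side is ignored when anchoring, though the detected
#' run may extend into it). Returns `NULL` when the profile never descends.
#'
#' @param profile a `convergence_profile`.
#' @param df smooth basis size.
#' @param slope_fraction fraction of the steepest descent that still counts
#'   as "accelerated".
#' @param boundary_exclude fraction of grid points at each boundary excluded
#'   from the steepest-descent search.
#' @return `c(start_day, end_day)` in pseudo-day index units, or `NULL`.
#' @export
detect_window <- function(profile, df = 9L, slope_fraction = 0.1,
                          boundary_exclude = 0.05) {
  gm <- profile$grand_mean
  x <- seq_along(gm)
  fit <- smooth_fit(x, gm, df = df, grid = x)
  der <- fit$derivative
  margin <- floor(length(x) * boundary_exclude)
  interior <- seq(1L + margin, length(x) - margin)
  m <- min(der[interior])
  if (m >= 0) return(NULL)
  sel <- der < slope_fraction * m
  anchor <- interior[which.min(der[interior])]
  runs <- rle(sel)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & starts <= anchor & ends >= anchor)
  c(start_day = x[starts[hit]], end_day = x[ends[hit]])
}

#' Linear trend of the grand-mean distance profile
#'
#' @param profile a `convergence_profile`.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value` from an OLS
#'   fit of the grand mean on pseudo-day index.
#' @export
convergence_trend <- function(profile) {
  gm <- profile$grand_mean
  axis_time_regression(gm, seq_along(gm))
}

#' Correlate OTU abundances with the convergence profile inside a window
#'
#' For each OTU, the Pearson correlation (with two-sided p-value) between its
#' cohort-mean interpolated relative abundance and the grand-mean
#' contemporaneous distance, over the pseudo-days inside `window`.
#' Zero-variance OTUs are reported as `NA` with a warning.
#'
#' @param series the `interpolated_series` the profile was computed from.
#' @param profile a `convergence_profile`.
#' @param otus feature ids to test.
#' @param window `c(start, end)` in pseudo-day index units.
#' @return data.frame with `otu_id`, `correlation`, `p_value`.
#' @export
otu_convergence_correlation <- function(series, profile, otus,
                                        window) {
  np <- profile$n_points
  idx <- seq(max(1L, round(window[1L])), min(np, round(window[2L])))
  keep <- profile$infants
  mats <- lapply(series$series[keep], `[[`, "values")
  cohort_mean <- Reduce(`+`, mats) / length(mats)
  gm <- profile$grand_mean[idx]
  res <- lapply(otus, function(o) {
    if (!o %in% colnames(cohort_mean)) stop("unknown OTU: ", o)
    v <- cohort_mean[idx, o]
    if (sd(v) == 0 || sd(gm) == 0) {
      warning("zero-variance series in window for ", o)
      return(c(NA_real_, NA_real_))
    }
    ct <- cor.test(v, gm)
    c(unname(ct$estimate), ct$p.value)
  })
  out <- do.call(rbind, res)
  data.frame(otu_id = otus, correlation = out[, 1L], p_value = out[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Twin-similarity test on contemporaneous distances
#'
#' Compares the 365 twin-pair contemporaneous distances against the pooled
#' per-pseudo-day mean distances from each twin to all non-twin infants
#' (2 x 365 values), with a one-sided Welch t-test (twin pair smaller). The
#' pseudo-days are autocorrelated, so the nominal n inflates significance;
#' interpret p-values comparatively.
#'
#' @param series an `interpolated_series` containing both twins.
#' @param twin_a,twin_b infant ids.
#' @param metric,tree,alpha as in [contemporaneous_distances()].
#' @return object of class `twin_comparison`: `t_statistic`, `p_value`,
#'   `mean_difference` (twin-pair minus others), `twin_pair_distances`,
#'   `twin_to_others` (2 x grid matrix).
#' @export
twin_similarity_test <- function(series, twin_a, twin_b,
                                 metric = c("bray_curtis", "gunifrac"),
                                 tree = NULL, alpha = 0.5) {
  metric <- match.arg(metric)
  ids <- names(series$series)
  if (!all(c(twin_a, twin_b) %in% ids)) {
    stop("missing twin id: ",
         paste(setdiff(c(twin_a, twin_b), ids), collapse = ", "))
  }
  if (length(ids) < 3L) stop("need at least 1 non-twin infant")
  prof <- contemporaneous_distances(series, metric = metric, tree = tree,
                                    alpha = alpha)
  pair_col <- paste(twin_a, twin_b, sep = "|")
  if (!pair_col %in% colnames(prof$pairwise)) {
    pair_col <- paste(twin_b, twin_a, sep = "|")
  }
  pair_d <- prof$pairwise[, pair_col]
  others <- setdiff(ids, c(twin_a, twin_b))
  to_others <- vapply(c(twin_a, twin_b), function(tw) {
    cols <- vapply(others, function(o) {
      cand <- c(paste(tw, o, sep = "|"), paste(o, tw, sep = "|"))
      cand[cand %in% colnames(prof$pairwise)][1L]
    }, character(1))
    rowMeans(prof$pairwise[, cols, drop = FALSE])
  }, numeric(prof$n_points))
  pooled <- as.vector(to_others)
  tt <- tryCatch(t.test(pair_d, pooled, alternative = "less"),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  structure(list(t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 mean_difference = mean(pair_d) - mean(pooled),
                 twin_pair_distances = pair_d,
                 twin_to_others = t(to_others),
                 twins = c(twin_a, twin_b), metric = metric),
            class = "twin_comparison")
}

#' @export
print.twin_comparison <- function(x, ...) {
  cat("twin comparison (", x$twins[1L], "vs", x$twins[2L], "):",
      "mean pair distance", signif(mean(x$twin_pair_distances), 4),
      "vs others", signif(mean(x$twin_to_others), 4),
      "; one-sided Welch t =", signif(x$t_statistic, 4),
      ", p =", format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Full convergence analysis of a cohort
#'
#' High-level wrapper: interpolates every infant's composition to 365
#' pseudo-days, drops late starters, computes the contemporaneous distance
#' profile, its fixed-df smooth, linear trend, and the detected convergence
#' window.
#'
#' @param cohort a `gut_cohort`.
#' @param metric,alpha distance choice (tree is taken from the cohort for
#'   `"gunifrac"`).
#' @param cutoff_day late-starter exclusion cutoff.
#' @param df smooth basis size.
#' @param slope_fraction see [detect_window()].
#' @param n_points pseudo-day grid length.
#' @return a `convergence_profile` with extra fields `smooth`
#'   ([smooth_fit()] of the grand mean), `window`, `trend`, and `series`.
#' @export
convergence_profile <- function(cohort, metric = c("bray_curtis", "gunifrac"),
                                alpha = 0.5, cutoff_day = 54L, df = 9L,
                                slope_fraction = 0.1, n_points = 365L) {
  metric <- match.arg(metric)
  series <- interpolate_cohort(cohort, n_points = n_points)
  series <- exclude_late_starters(series, cutoff_day = cutoff_day)
  prof <- contemporaneous_distances(series, metric = metric,
                                    tree = cohort$tree, alpha = alpha)
  prof$smooth <- smooth_fit(seq_len(n_points), prof$grand_mean, df = df,
                            grid = seq_len(n_points))
  prof$window <- detect_window(prof, df = df,
                               slope_fraction = slope_fraction)
  prof$trend <- convergence_trend(prof)
  prof$series <- series
  prof
}

#' @export
print.convergence_profile <- function(x, ...) {
  cat("convergence profile (", x$metric, "):", length(x$infants), "infants,",
      x$n_points, "pseudo-days\n")
  if (!is.null(x$trend)) {
    cat("  trend: slope", signif(x$trend$slope, 3), " R2",
        signif(x$trend$r_squared, 3), " p",
        format.pval(x$trend$p_value, digits = 3), "\n")
  }
  if (!is.null(x$window)) {
    cat("  accelerated convergence window: pseudo-days",
        x$window[1L], "-", x$window[2L], "\n")
  }
  invisible(x)
}

#' @export
plot.convergence_profile <- function(x, ...) {
  plot(seq_along(x$grand_mean), x$grand_mean, pch = 16, cex = 0.4,
       col = "grey50", xlab = "pseudo-day",
       ylab = paste("mean pairwise", x$metric, "distance"), ...)
  if (!is.null(x$smooth)) {
    graphics::lines(x$smooth$grid, x$smooth$fitted, col = "firebrick", lwd = 2)
    graphics::lines(x$smooth$grid, x$smooth$lower95, lty = 2, col = "firebrick")
    graphics::lines(x$smooth$grid, x$smooth$upper95, lty = 2, col = "firebrick")
  }
  if (!is.null(x$window)) graphics::abline(v = x$window, lty = 3)
  invisible(x)
}
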