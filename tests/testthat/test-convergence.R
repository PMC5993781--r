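fake_profile <- function(gm) {
  structure(list(grand_mean = gm, n_points = length(gm),
                 infants = c("A", "B")), class = "convergence_profile")
}

test_that("fmm interpolation reproduces a global cubic exactly", {
  days <- c(1, 30, 65, 120, 190, 260, 330, 365)
  f <- function(t) 1 + 4e-3 * t - 1e-5 * t^2 + 1e-8 * t^3
  comp <- cbind(a = f(days), b = 3 - f(days))   # rows sum to 3
  out <- interpolate_infant(days, comp, n_points = 365)
  grid <- out$grid_days
  expect_equal(out$values[, "a"], f(grid) / 3, tolerance = 1e-9)
  # grid endpoints span the infant's own sampling range
  expect_equal(range(grid), c(1, 365))
})

test_that("interpolation passes through observed values on grid days", {
  set.seed(91)
  days <- sort(sample(1:365, 40))
  days <- union(c(1, 365), days)
  comp <- t(replicate(length(days), random_composition(5)))
  colnames(comp) <- paste0("o", 1:5)
  out <- interpolate_infant(days, comp, n_points = 365)
  # the 365-point grid over [1, 365] hits the integers
  hit <- match(days, round(out$grid_days))
  for (k in seq_along(days)) {
    raw <- pmax(comp[k, ], 0)
    expect_equal(out$values[hit[k], ], raw / sum(raw), tolerance = 1e-8)
  }
})

test_that("negative interpolated values are clipped then renormalized", {
  days <- c(1, 40, 80, 120, 160, 200)
  # a feature that dips negative between knots
  dip <- c(0.3, 0.001, 0.3, 0.001, 0.3, 0.001)
  comp <- cbind(a = dip, b = 1 - dip)
  out <- interpolate_infant(days, comp, n_points = 200)
  expect_true(all(out$values >= 0))
  expect_equal(unname(rowSums(out$values)), rep(1, 200), tolerance = 1e-9)

  expect_error(interpolate_infant(c(1, 2, 3), comp[1:3, ]), "4 distinct")
})

test_that("the calendar grid evaluates at integer days with extrapolation", {
  days <- c(10, 100, 200, 300)
  f <- function(t) 1 + 1e-3 * t
  comp <- cbind(a = f(days), b = 3 - f(days))
  out <- interpolate_infant(days, comp, n_points = 365, grid = "calendar")
  expect_equal(out$grid_days, 1:365)
  # a single cubic (here linear) extrapolates exactly beyond the range
  expect_equal(out$values[, "a"], f(1:365) / 3, tolerance = 1e-9)
})

test_that("duplicate-day samples are averaged before fitting", {
  days <- c(1, 1, 50, 100, 150)
  comp <- cbind(a = c(0.2, 0.4, 0.5, 0.6, 0.7),
                b = c(0.8, 0.6, 0.5, 0.4, 0.3))
  out <- interpolate_infant(days, comp, n_points = 150)
  expect_equal(unname(out$values[1, "a"]), 0.3, tolerance = 1e-9)
})

test_that("late starters are excluded with the documented cutoff", {
  cfg <- sim_config(n_infants = 5L, n_otus = 12L, sampling_rate = 0.1,
                    twin_pair = NULL, late_starter = 2L)
  ch <- simulate_cohort(cfg, seed = 13)
  ser <- interpolate_cohort(ch, n_points = 50)
  expect_message(kept <- exclude_late_starters(ser), "ID2")
  expect_setequal(names(kept$series), paste0("ID", c(1, 3, 4, 5)))

  # all-early cohort: nothing dropped
  firsts <- vapply(ser$series, `[[`, numeric(1), "first_day")
  early <- ser
  early$series <- ser$series[firsts < 54]
  early$pseudo_day_map <- ser$pseudo_day_map[firsts < 54, ]
  expect_silent(out <- exclude_late_starters(early))
  expect_identical(names(out$series), names(early$series))

  expect_error(exclude_late_starters(ser, cutoff_day = 1), "fewer than 2")
})

test_that("contemporaneous distances satisfy the aggregation identity", {
  # tiny analytic case: 4 infants, 3 grid points, checked by triple loop
  set.seed(101)
  series <- list()
  for (i in 1:4) {
    vals <- t(replicate(3, random_composition(6)))
    colnames(vals) <- paste0("o", 1:6)
    series[[paste0("I", i)]] <- list(values = vals, grid_days = 1:3,
                                     first_day = 1, last_day = 3)
  }
  ser <- structure(list(series = series,
                        pseudo_day_map = matrix(1:3, 4, 3, byrow = TRUE),
                        n_points = 3L), class = "interpolated_series")
  prof <- contemporaneous_distances(ser, "bray_curtis")
  for (t in 1:3) {
    ds <- c()
    for (i in 1:3) for (j in (i + 1):4) {
      ds <- c(ds, bray_curtis(series[[i]]$values[t, ],
                              series[[j]]$values[t, ]))
    }
    expect_equal(prof$grand_mean[t], mean(ds), tolerance = 1e-12)
  }
  expect_equal(colMeans(prof$per_infant_mean), prof$grand_mean,
               tolerance = 1e-12)
  expect_equal(unname(rowMeans(prof$pairwise)), unname(prof$grand_mean),
               tolerance = 1e-12)

  # two infants: grand mean equals the single pairwise vector
  two <- ser; two$series <- series[1:2]
  two$pseudo_day_map <- ser$pseudo_day_map[1:2, ]
  p2 <- contemporaneous_distances(two, "bray_curtis")
  expect_equal(p2$grand_mean, unname(p2$pairwise[, 1]), tolerance = 1e-12)

  # identical infants: identically zero
  same <- ser; same$series <- series[c(1, 1)]
  names(same$series) <- c("I1", "I2")
  same$pseudo_day_map <- ser$pseudo_day_map[1:2, ]
  expect_equal(max(contemporaneous_distances(same, "bray_curtis")$grand_mean),
               0)
})

test_that("contemporaneous UniFrac matches per-day kernel evaluation", {
  tr <- random_tip_tree(6, seed = 111)
  set.seed(112)
  series <- list()
  for (i in 1:3) {
    vals <- t(replicate(4, random_composition(6)))
    colnames(vals) <- tr$tip.label
    series[[paste0("I", i)]] <- list(values = vals, grid_days = 1:4,
                                     first_day = 1, last_day = 4)
  }
  ser <- structure(list(series = series,
                        pseudo_day_map = matrix(1:4, 3, 4, byrow = TRUE),
                        n_points = 4L), class = "interpolated_series")
  prof <- contemporaneous_distances(ser, "gunifrac", tree = tr, alpha = 0.5)
  bt <- branch_table(tr)
  for (t in 1:4) {
    expect_equal(unname(prof$pairwise[t, "I1|I2"]),
                 generalized_unifrac(series[[1]]$values[t, ],
                                     series[[2]]$values[t, ], bt, 0.5),
                 tolerance = 1e-12)
  }
  expect_error(contemporaneous_distances(ser, "gunifrac"), "tree")
})

test_that("window detection finds planted descents and ignores ascents", {
  # strictly increasing profile: no window
  expect_null(detect_window(fake_profile(seq(0.2, 0.6, length.out = 365))))

  # cosine step descending exactly on [60, 130]
  t <- 1:365
  gm <- numeric(365)
  gm[t < 60] <- 0.6
  gm[t > 130] <- 0.4
  mid <- t >= 60 & t <= 130
  gm[mid] <- 0.4 + 0.2 * (1 + cos(pi * (t[mid] - 60) / 70)) / 2
  win <- detect_window(fake_profile(gm))
  # a df-9 basis on 365 points localizes edges to about half a knot span
  expect_lt(abs(win[1] - 60), 15)
  expect_lt(abs(win[2] - 130), 15)

  # V-shaped profile: window ends near the minimum
  v <- abs(t - 200) / 365
  winv <- detect_window(fake_profile(v))
  expect_lt(abs(winv[2] - 200), 10)
})

test_that("the linear convergence trend matches its OLS contract", {
  gm <- seq(0.7, 0.3, length.out = 365)
  res <- convergence_trend(fake_profile(gm))
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_lt(res$slope, 0)

  flat <- convergence_trend(fake_profile(rep(0.5, 365)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
})

test_that("OTU-convergence correlations recover exact anticorrelation", {
  gm <- 0.3 + 0.2 * sin(1:365 / 40)
  series <- list()
  vals <- cbind(a = 1 - gm, b = gm / 2, c = 1 - (1 - gm) - gm / 2)
  colnames(vals) <- c("a", "b", "c")
  for (i in c("A", "B")) {
    series[[i]] <- list(values = vals, grid_days = 1:365,
                        first_day = 1, last_day = 365)
  }
  ser <- structure(list(series = series,
                        pseudo_day_map = matrix(1:365, 2, 365, byrow = TRUE),
                        n_points = 365L), class = "interpolated_series")
  prof <- fake_profile(gm)
  res <- otu_convergence_correlation(ser, prof, c("a"), window = c(60, 130))
  expect_equal(res$correlation, -1, tolerance = 1e-9)

  const <- ser
  const$series <- lapply(series, function(s) {
    s$values <- cbind(a = 1 - gm, b = 0.1, c = gm - 0.1)
    s
  })
  # feature b is constant inside the window
  expect_warning(
    resc <- otu_convergence_correlation(const, prof, "b", c(60, 130)),
    "zero-variance")
  expect_true(is.na(resc$correlation))
  expect_error(otu_convergence_correlation(ser, prof, "zz", c(60, 130)),
               "zz")
})

test_that("twin similarity testing behaves at its degenerate limits", {
  set.seed(121)
  base <- t(replicate(10, random_composition(4)))
  colnames(base) <- paste0("o", 1:4)
  other <- t(replicate(10, random_composition(4)))
  colnames(other) <- paste0("o", 1:4)
  mk <- function(v) list(values = v, grid_days = 1:10, first_day = 1,
                         last_day = 10)
  ser <- structure(list(series = list(T1 = mk(base), T2 = mk(base),
                                      O1 = mk(other)),
                        pseudo_day_map = matrix(1:10, 3, 10, byrow = TRUE),
                        n_points = 10L), class = "interpolated_series")
  res <- twin_similarity_test(ser, "T1", "T2")
  expect_equal(mean(res$twin_pair_distances), 0)
  expect_lt(res$p_value, 1e-6)
  expect_lt(res$mean_difference, 0)

  # all infants identical: zero mean difference, no defined t
  ser_same <- ser
  ser_same$series <- list(T1 = mk(base), T2 = mk(base), O1 = mk(base))
  res_same <- twin_similarity_test(ser_same, "T1", "T2")
  expect_equal(res_same$mean_difference, 0)

  expect_error(twin_similarity_test(ser, "T1", "ZZ"), "ZZ")
})
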