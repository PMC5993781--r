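test_that("isotonic regression pools violators and preserves the mean", {
  expect_equal(isotonic_fit(c(1, 3, 2)), c(1, 2.5, 2.5))
  expect_equal(isotonic_fit(c(1, 2, 3)), c(1, 2, 3))
  expect_equal(isotonic_fit(rep(2, 4)), rep(2, 4))
  expect_error(isotonic_fit(numeric(0)), "empty")

  set.seed(21)
  for (k in 1:20) {
    y <- rnorm(30)
    fit <- isotonic_fit(y)
    expect_equal(fit, stats::isoreg(y)$yf, tolerance = 1e-12)
    expect_false(is.unsorted(fit))
    expect_equal(mean(fit), mean(y), tolerance = 1e-12)
  }
  # weighted case against exhaustive block enumeration
  for (k in 1:10) {
    set.seed(300 + k)
    y <- rnorm(6); w <- runif(6, 0.5, 2)
    fit <- isotonic_fit(y, w)
    expect_equal(fit, pava_oracle(y, w), tolerance = 1e-9)
    expect_equal(sum(w * fit) / sum(w), sum(w * y) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("nMDS recovers embeddable configurations with near-zero stress", {
  set.seed(41)
  pts <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:5], letters[1:5])
  fit <- nmds(d, k = 2, seed = 1)
  expect_lt(fit$stress, 1e-3)
  expect_lte(fit$stress, fit$initial_stress)
  expect_equal(unname(colMeans(fit$coordinates)), c(0, 0), tolerance = 1e-9)
})

test_that("nMDS stress depends only on the rank order of dissimilarities", {
  d <- random_distance_matrix(9)
  f1 <- nmds(d, seed = 2)
  f2 <- nmds(d^2, seed = 2)       # monotone transform preserves ranks
  expect_lt(abs(f1$stress - f2$stress), 0.02)
})

test_that("nMDS configuration distances are rotation invariant", {
  d <- random_distance_matrix(8)
  fit <- nmds(d, seed = 3)
  set.seed(4)
  q <- qr.Q(qr(matrix(rnorm(4), 2, 2)))    # random orthogonal matrix
  expect_equal(as.numeric(dist(fit$coordinates %*% q)),
               as.numeric(dist(fit$coordinates)), tolerance = 1e-9)
  expect_error(nmds(matrix(0, 5, 5)), "degenerate")
})

test_that("PERMANOVA reproduces the hand-worked toy analysis", {
  d <- matrix(2, 4, 4)
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 1
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- permanova(d, c("g1", "g1", "g2", "g2"), n_permutations = 99,
                   seed = 1)
  expect_equal(res$pseudo_f, 7)
  expect_equal(res$r_squared, 3.5 / 4.5)
  expect_equal(res$ss[["total"]], 4.5)

  expect_error(permanova(d, c("a", "a", "a", "b")), "size 1")
  expect_error(permanova(d[1:3, 1:3], c("a", "a", "b")), "4 samples")
})

test_that("PERMANOVA agrees with the longhand oracle and with vegan", {
  skip_if_not_installed("vegan")
  set.seed(51)
  for (k in 1:5) {
    m <- matrix(runif(12 * 6), 12, 6)
    rownames(m) <- paste0("s", 1:12)
    d <- distance_matrix(m / rowSums(m), "bray_curtis")
    g <- rep(c("a", "b", "c"), each = 4)
    res <- permanova(d, g, n_permutations = 49, seed = k)
    orc <- permanova_oracle(d, g)
    expect_equal(res$pseudo_f, orc$pseudo_f, tolerance = 1e-12)
    expect_equal(res$r_squared, orc$r_squared, tolerance = 1e-12)
    av <- vegan::adonis2(as.dist(d) ~ g, permutations = 9)
    expect_equal(res$pseudo_f, av$F[1], tolerance = 1e-9)
    expect_equal(res$r_squared, av$R2[1], tolerance = 1e-9)
    # relabeling the groups changes nothing
    res2 <- permanova(d, c(a = "x", b = "y", c = "z")[g],
                      n_permutations = 49, seed = k)
    expect_equal(res2$pseudo_f, res$pseudo_f)
  }
})

test_that("permutation p-values have add-one resolution and null behaviour", {
  # constant off-diagonal distances: all labelings equivalent
  d <- matrix(1, 8, 8); diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  res <- permanova(d, rep(c("a", "b"), 4), n_permutations = 199, seed = 5)
  expect_gt(res$p_value, 0.5)
  expect_equal((res$p_value * (res$n_permutations + 1)) %% 1, 0,
               tolerance = 1e-12)
})

test_that("axis-vs-time regression matches least squares expectations", {
  days <- 1:50
  fit <- list(coordinates = cbind(2 * days + 3, rnorm(50)))
  class(fit) <- "nmds_fit"
  res <- axis_time_regression(fit, days)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$slope, 2, tolerance = 1e-12)

  set.seed(61)
  noise <- rnorm(200)
  res2 <- axis_time_regression(noise, 1:200)
  expect_lt(res2$r_squared, 0.05)

  # duplicated points equal the weighted fit on unique points
  x <- c(1, 1, 2, 3)
  y <- c(2, 2, 2.5, 4)
  res3 <- axis_time_regression(y, x)
  wfit <- lm(c(2, 2.5, 4) ~ c(1, 2, 3), weights = c(2, 1, 1))
  expect_equal(res3$slope, unname(coef(wfit)[2]), tolerance = 1e-12)
  expect_error(axis_time_regression(y, rep(1, 4)), "constant")
})

test_that("fixed-df smooths are exact on cubics and track smooth signals", {
  x <- seq(1, 365, by = 2)
  y <- 1e-6 * (x - 100)^3 - 2e-4 * x^2 + 0.01 * x + 2
  for (df in c(4, 9)) {
    fit <- smooth_fit(x, y, df = df)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_equal(fit$fitted, y[order(x)], tolerance = 1e-6)
  }

  const <- smooth_fit(x, rep(3, length(x)), df = 9)
  expect_equal(max(abs(const$derivative)), 0, tolerance = 1e-9)

  set.seed(71)
  xs <- 1:365
  ys <- sin(xs / 30) + rnorm(365, 0, 0.05)
  sf <- smooth_fit(xs, ys, df = 9)
  expect_gt(sf$r_squared, 0.95)
  expect_true(all(sf$lower95 <= sf$fitted & sf$fitted <= sf$upper95))

  expect_error(smooth_fit(1:5, rnorm(5), df = 9), "distinct")
})

test_that("confidence bands widen where data are sparse", {
  set.seed(81)
  x <- c(1:40, 80:120)                      # gap between 40 and 80
  y <- rnorm(length(x))
  fit <- smooth_fit(x, y, df = 6, grid = c(20, 60, 100))
  width <- fit$upper95 - fit$lower95
  expect_gt(width[2], width[1])
  expect_gt(width[2], width[3])
})
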