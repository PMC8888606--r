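test_that("rank-one data are fully explained by a single template", {
  withr::with_seed(21, {
    t1 <- rand_map(10); t1 <- t1 / sqrt(sum(t1^2))
    maps <- sapply(1:50, function(i) t1 * rnorm(1, sd = 3))
    fit <- modified_kmeans(maps, k = 1, seed = 4)
    expect_equal(fit$gev, 1.0, tolerance = 1e-12)
    expect_equal(abs(sum(fit$templates[, 1] * t1)), 1.0, tolerance = 1e-10)
    expect_equal(fit$dispersion_W, 0.0, tolerance = 1e-10)
  })
})

test_that("orthogonal planted templates are perfectly separated", {
  TT <- ortho_templates(12, 2, seed = 2)
  withr::with_seed(9, {
    lab <- rep(1:2, each = 20)
    amp <- runif(40, 0.5, 2) * sample(c(-1, 1), 40, replace = TRUE)
    maps <- TT[, lab] * rep(amp, each = 12)
    fit <- modified_kmeans(maps, k = 2, n_restarts = 20, seed = 5)
    expect_equal(fit$gev, 1.0, tolerance = 1e-12)
    # labels separate the groups (up to cluster relabeling)
    expect_equal(length(unique(fit$labels[lab == 1])), 1)
    expect_equal(length(unique(fit$labels[lab == 2])), 1)
    expect_false(fit$labels[1] == fit$labels[40])
  })
})

test_that("GEV and W match direct formula evaluation on a random instance", {
  withr::with_seed(31, {
    maps <- matrix(rnorm(8 * 15), 8, 15)
    maps <- sweep(maps, 2, colMeans(maps), "-")
    fit <- modified_kmeans(maps, k = 3, n_restarts = 30, seed = 6)
    # term-by-term oracle with package primitives only at scalar level
    g <- apply(maps, 2, gfp)
    r <- vapply(1:15, function(i)
      spatial_correlation(maps[, i], fit$templates[, fit$labels[i]],
                          ignore_polarity = TRUE), numeric(1))
    expect_equal(global_explained_variance(maps, fit$templates, fit$labels),
                 sum(g^2 * r^2) / sum(g^2), tolerance = 1e-12)
    expect_equal(fit$gev, sum(g^2 * r^2) / sum(g^2), tolerance = 1e-12)
    # W via brute-force summation over members
    Vhat <- sweep(maps, 2, sqrt(colSums(maps^2)), "/")
    W_brute <- sum(vapply(1:15, function(i)
      sum((fit$polarity[i] * Vhat[, i] -
             fit$templates[, fit$labels[i]])^2), numeric(1)))
    expect_equal(fit$dispersion_W, W_brute, tolerance = 1e-10)
    expect_equal(within_dispersion(maps, fit$templates, fit$labels,
                                   fit$polarity), W_brute,
                 tolerance = 1e-10)
  })
})

test_that("templates orthogonal to the data give zero explained variance", {
  TT <- ortho_templates(10, 4, seed = 3)
  maps <- TT[, rep(1:2, 10)] * 2
  expect_equal(global_explained_variance(maps, TT[, 3:4, drop = FALSE],
                                         rep(1:2, 10)), 0,
               tolerance = 1e-12)
})

test_that("each map its own cluster yields zero dispersion", {
  withr::with_seed(41, {
    maps <- matrix(rnorm(6 * 4), 6, 4)
    maps <- sweep(maps, 2, colMeans(maps), "-")
    fit <- modified_kmeans(maps, k = 4, n_restarts = 50, seed = 7)
    expect_equal(fit$dispersion_W, 0, tolerance = 1e-10)
    expect_equal(fit$gev, 1, tolerance = 1e-12)
  })
})

test_that("clustering is invariant to sign flips of input maps", {
  withr::with_seed(51, {
    maps <- matrix(rnorm(10 * 30), 10, 30)
    maps <- sweep(maps, 2, colMeans(maps), "-")
    flip <- sample(c(-1, 1), 30, replace = TRUE)
    flipped <- sweep(maps, 2, flip, "*")
    f1 <- modified_kmeans(maps, k = 3, n_restarts = 40, seed = 12)
    f2 <- modified_kmeans(flipped, k = 3, n_restarts = 40, seed = 12)
    expect_identical(f1$labels, f2$labels)
    expect_equal(f1$gev, f2$gev, tolerance = 1e-12)
    expect_equal(f1$dispersion_W, f2$dispersion_W, tolerance = 1e-10)
    # templates agree up to a global sign per cluster
    agree <- abs(colSums(f1$templates * f2$templates))
    expect_equal(agree, rep(1, 3), tolerance = 1e-10)
    # per-map polarity flips with the map sign (modulo the global sign
    # freedom of each template)
    tsign <- sign(colSums(f1$templates * f2$templates))
    expect_equal(f1$polarity * flip * tsign[f1$labels], f2$polarity)
  })
})

test_that("GEV is non-decreasing and W non-increasing in k (best of restarts)", {
  withr::with_seed(61, {
    TT <- ortho_templates(8, 3, seed = 9)
    lab <- sample(1:3, 40, replace = TRUE)
    maps <- TT[, lab] + matrix(rnorm(8 * 40, sd = 0.3), 8)
    maps <- sweep(maps, 2, colMeans(maps), "-")
    fits <- lapply(1:6, function(k)
      modified_kmeans(maps, k = k, n_restarts = 100, seed = 13 + k))
    gev <- vapply(fits, `[[`, numeric(1), "gev")
    W <- vapply(fits, `[[`, numeric(1), "dispersion_W")
    expect_true(all(diff(gev) > -1e-9))
    expect_true(all(diff(W) < 1e-9))
  })
})

test_that("zero-GFP maps are excluded, not fatal", {
  withr::with_seed(71, {
    maps <- matrix(rnorm(6 * 10), 6, 10)
    maps <- sweep(maps, 2, colMeans(maps), "-")
    maps[, 4] <- 0
    fit <- modified_kmeans(maps, k = 2, n_restarts = 20, seed = 3)
    expect_true(is.na(fit$labels[4]))
    expect_equal(fit$excluded, 4L)
    expect_false(anyNA(fit$labels[-4]))
  })
})

test_that("k larger than the number of distinct maps errors", {
  t1 <- rand_map(6, seed = 5)
  maps <- cbind(t1, -2 * t1, 0.5 * t1)
  expect_error(modified_kmeans(maps, k = 2, seed = 1), "distinct")
})

test_that("best-of-restarts attains the exhaustive max-GEV partition", {
  # small instances where full enumeration is feasible
  withr::with_seed(81, {
    for (case in list(c(C = 4, N = 8, k = 2), c(C = 5, N = 9, k = 3))) {
      maps <- matrix(rnorm(case["C"] * case["N"]), case["C"])
      maps <- sweep(maps, 2, colMeans(maps), "-")
      oracle <- oracle_best_gev(maps, case["k"])
      fit <- modified_kmeans(maps, k = case["k"], n_restarts = 200,
                             seed = 17)
      expect_equal(fit$gev, oracle, tolerance = 1e-9)
    }
  })
})
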