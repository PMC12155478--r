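test_that("autoscaling centers and scales every retained column", {
  expect_equal(as.vector(autoscale(matrix(1:3, 3, 1))), c(-1, 0, 1))

  set.seed(11)
  m <- matrix(rnorm(8 * 20, mean = 5, sd = 3), 8, 20)
  s <- autoscale(m)
  # direct-summation oracle for mean 0, sd 1
  expect_true(all(abs(colSums(s) / 8) < 1e-10))
  expect_true(all(abs(sqrt(colSums(sweep(s, 2, colMeans(s))^2) / 7) - 1) < 1e-10))
  # idempotent
  expect_equal(autoscale(s), s, tolerance = 1e-10, ignore_attr = TRUE)

  m2 <- cbind(m, const = 1)
  expect_warning(s2 <- autoscale(m2), "constant")
  expect_equal(ncol(s2), 20)
  expect_error(autoscale(matrix(1, 4, 2)), "constant")
})

test_that("PCA agrees with an eigendecomposition of the covariance", {
  set.seed(21)
  m <- matrix(rnorm(8 * 10), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("v", 1:10)))
  k <- 5
  fit <- pca_fit(m, k)

  # oracle: eigendecomposition of the covariance matrix
  ev <- eigen(stats::cov(m), symmetric = TRUE)
  expect_equal(abs(unname(fit$loadings)), abs(ev$vectors[, 1:k]),
               tolerance = 1e-8)
  expect_equal(fit$explained_variance,
               (ev$values / sum(ev$values))[1:k], tolerance = 1e-8)
  centered <- scale(m, scale = FALSE)
  expect_equal(unname(fit$scores), unname(centered %*% fit$loadings))
  expect_equal(abs(unname(fit$scores)),
               abs(unname(centered %*% ev$vectors[, 1:k])), tolerance = 1e-8)

  # loadings orthonormal; explained fractions non-increasing
  g <- crossprod(fit$loadings)
  expect_equal(unname(g), diag(k), tolerance = 1e-8)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))

  # row order does not change the explained spectrum
  fit_perm <- pca_fit(m[sample(8), ], k)
  expect_equal(fit_perm$explained_variance, fit$explained_variance)

  # a single varying column carries all the variance
  one <- cbind(rnorm(6), 2, 2)
  expect_equal(pca_fit(one, 1)$explained_variance, 1)
  # a symmetric cross configuration splits the variance 50/50
  cross <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  expect_equal(pca_fit(cross, 2)$explained_variance, c(0.5, 0.5))

  expect_error(pca_fit(m, 9), "rank")
})

test_that("hierarchical clustering matches a brute-force agglomeration oracle", {
  # identical rows merge at height zero under ward linkage
  twin <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 9, 9))
  expect_equal(hca_fit(twin, linkage = "ward")$height[1], 0)

  # collinear points 0, 1, 10: the near pair merges first at distance 1
  line <- matrix(c(0, 1, 10), 3, 1)
  expect_equal(hca_fit(line, linkage = "complete")$height[1], 1)

  set.seed(31)
  m <- matrix(rnorm(8 * 5), 8, 5)
  for (lk in c("ward", "average", "complete")) {
    fit <- hca_fit(m, linkage = lk)
    expect_equal(sort(fit$height), sort(bf_hca_heights(m, lk)),
                 tolerance = 1e-8, info = lk)
    expect_true(all(diff(fit$height) >= -1e-10), info = lk)
    expect_equal(length(fit$height), 7)
    # row order leaves merge heights unchanged
    fit_perm <- hca_fit(m[sample(8), ], linkage = lk)
    expect_equal(sort(fit_perm$height), sort(fit$height), tolerance = 1e-8)
  }

  expect_error(hca_fit(m, metric = "manhattan"), "metric")
  expect_error(hca_fit(m[1, , drop = FALSE]), "at least 2")
})

test_that("NIPALS PLS-DA satisfies its algebraic contracts", {
  set.seed(41)
  n <- 12
  cls <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  x[, 3] <- x[, 3] + ifelse(cls == "A", 3, -3)  # one informative variable

  fit <- plsda_fit(x, cls, n_components = 2, scale. = FALSE)
  expect_equal(which.max(abs(fit$weights[, 1])), 3, ignore_attr = TRUE)

  # unit-norm weights, orthogonal scores
  expect_equal(unname(colSums(fit$weights^2)), c(1, 1))
  t1t2 <- abs(sum(fit$scores[, 1] * fit$scores[, 2]))
  expect_lt(t1t2 / sqrt(sum(fit$scores[, 1]^2) * sum(fit$scores[, 2]^2)), 1e-6)

  # closed-form first component: w1 proportional to X'y for centered binary y
  xc <- scale(x, scale = FALSE)
  y <- ifelse(cls == "A", 1, 0) - 0.5
  w_oracle <- drop(crossprod(xc, y))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(abs(unname(fit$weights[, 1])), abs(unname(w_oracle)), tolerance = 1e-8)

  # permuting rows with labels in lockstep permutes only the score rows
  perm <- sample(n)
  fit_p <- plsda_fit(x[perm, ], cls[perm], n_components = 2, scale. = FALSE)
  expect_equal(fit_p$weights, fit$weights, tolerance = 1e-7)
  expect_equal(unname(fit_p$scores), unname(fit$scores[perm, ]),
               tolerance = 1e-7)

  # residual X variance decreases monotonically with components
  expect_true(all(fit$explained_x_variance > 0))

  expect_error(plsda_fit(x, rep("A", n)), "2 classes")
})

test_that("VIP scores are normalized and identify the informative variable", {
  set.seed(51)
  # p = 1: normalization forces VIP = 1
  x1 <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "only"))
  cls <- rep(c("A", "B"), 5)
  expect_equal(unname(plsda_fit(x1, cls, 1, scale. = FALSE)$vip), 1)

  # A = 1, two variables: VIP reduces to sqrt(2) * |w|
  x2 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  x2[, 1] <- x2[, 1] + ifelse(cls == "A", 2, -2)
  f2 <- plsda_fit(x2, cls, 1, scale. = FALSE)
  expect_equal(unname(f2$vip), unname(sqrt(2) * abs(f2$weights[, 1])))

  # sum of squared VIPs equals the number of variables, across designs
  for (seed in 1:20) {
    set.seed(seed)
    p <- sample(3:10, 1)
    nc <- sample(2:3, 1)
    cls_i <- rep(c("A", "B", "C"), length.out = 12)
    x_i <- matrix(rnorm(12 * p), 12, p, dimnames = list(NULL, paste0("v", 1:p)))
    fit_i <- plsda_fit(x_i, cls_i, n_components = nc, scale. = FALSE)
    expect_equal(sum(fit_i$vip^2), p, tolerance = 1e-6)
  }

  # the dominant class-separating variable attains the top VIP
  hits <- 0
  for (seed in 1:25) {
    set.seed(100 + seed)
    x_i <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(NULL, paste0("v", 1:8)))
    cls_i <- rep(c("A", "B"), 6)
    x_i[, 5] <- x_i[, 5] + ifelse(cls_i == "A", 4, -4)
    fit_i <- plsda_fit(x_i, cls_i, 1, scale. = FALSE)
    if (which.max(fit_i$vip) == 5) hits <- hits + 1
  }
  expect_gte(hits, 24)
})

test_that("tidiers return long tibbles with the expected shape", {
  set.seed(61)
  m <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(paste0("s", 1:8), paste0("v", 1:6)))
  p <- pca_fit(m, 2)
  expect_equal(dim(tidy(p, "scores")), c(16, 3))
  expect_equal(dim(tidy(p, "loadings")), c(12, 3))
  expect_equal(nrow(glance(p)), 1)

  fit <- plsda_fit(m, rep(c("A", "B"), 4), 2, scale. = FALSE)
  v <- tidy(fit, "vip")
  expect_named(v, c("compound", "vip"))
  expect_equal(nrow(v), 6)
  expect_equal(glance(fit)$n_components, 2)
})
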