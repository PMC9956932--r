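pts345 <- rbind(c(0, 0), c(3, 4))

test_that("the five metrics evaluate correctly on the 3-4-5 pair", {
  d <- function(spec) pairwise_distances(pts345, spec)[1, 2]
  expect_equal(d(metric_spec("euclidean")), 5)
  expect_equal(d(metric_spec("cityblock")), 7)
  expect_equal(d(metric_spec("chebyshev")), 4)
  # (sqrt(3) + sqrt(4))^2 = 7 + 4*sqrt(3)
  expect_equal(d(metric_spec("minkowski", p = 0.5)), 7 + 4 * sqrt(3),
               tolerance = 1e-12)
})

test_that("distance matrices are symmetric, non-negative, zero-diagonal", {
  set.seed(11)
  pts <- rand_points(15)
  for (spec in list(metric_spec("euclidean"), metric_spec("cityblock"),
                    metric_spec("chebyshev"), metric_spec("minkowski", p = 0.5),
                    metric_spec("mahalanobis"))) {
    D <- pairwise_distances(pts, spec)
    expect_equal(D, t(D))
    expect_true(all(D >= 0))
    expect_equal(diag(D), rep(0, 15))
    expect_true(all(is.finite(D)))
  }
})

test_that("Minkowski reduces to cityblock (p=1) and euclidean (p=2)", {
  set.seed(12)
  pts <- rand_points(20)
  expect_equal(pairwise_distances(pts, metric_spec("minkowski", p = 1)),
               pairwise_distances(pts, metric_spec("cityblock")),
               tolerance = 1e-12)
  expect_equal(pairwise_distances(pts, metric_spec("minkowski", p = 2)),
               pairwise_distances(pts, metric_spec("euclidean")),
               tolerance = 1e-12)
})

test_that("Minkowski approaches Chebyshev as p grows", {
  # in 2-D, max(a,b) <= (a^p + b^p)^(1/p) <= max(a,b) * 2^(1/p): the gap is
  # bounded by the dimension factor and shrinks monotonically with p
  set.seed(13)
  for (i in 1:5) {
    pts <- rand_points(12, sd = i)
    Dc <- pairwise_distances(pts, metric_spec("chebyshev"))
    for (p in c(8, 64)) {
      Dp <- pairwise_distances(pts, metric_spec("minkowski", p = p))
      expect_true(all(Dp >= Dc - 1e-12))
      expect_true(all(Dp <= Dc * 2^(1 / p) + 1e-12))
    }
    gap8 <- max(abs(pairwise_distances(pts, metric_spec("minkowski", p = 8)) - Dc))
    gap64 <- max(abs(pairwise_distances(pts, metric_spec("minkowski", p = 64)) - Dc))
    expect_lt(gap64, gap8)
    expect_lt(gap64 / max(Dc), 2^(1 / 64) - 1)   # ~1.1% worst case
  }
})

test_that("fractional Minkowski is a dissimilarity, not a metric", {
  # 3 collinear axis-aligned points: direct path is longer than the detour
  pts <- rbind(c(0, 0), c(3, 4), c(3, 0))
  D <- pairwise_distances(pts, metric_spec("minkowski", p = 0.5))
  expect_gt(D[1, 2], D[1, 3] + D[3, 2])     # triangle inequality fails
  expect_equal(D, t(D))                     # but symmetry holds
})

test_that("triangle inequality holds for the true metrics", {
  set.seed(14)
  pts <- rand_points(12)
  for (spec in list(metric_spec("euclidean"), metric_spec("cityblock"),
                    metric_spec("chebyshev"), metric_spec("minkowski", p = 3),
                    metric_spec("mahalanobis"))) {
    D <- pairwise_distances(pts, spec)
    n <- nrow(D)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-9)
  }
})

test_that("Mahalanobis with identity covariance equals euclidean", {
  set.seed(15)
  pts <- rand_points(25, sd = 2)
  expect_equal(
    pairwise_distances(pts, metric_spec("mahalanobis",
                                        covariance_mode = "identity")),
    pairwise_distances(pts, metric_spec("euclidean")),
    tolerance = 1e-9)
})

test_that("per-batch Mahalanobis is invariant under invertible affine maps", {
  set.seed(16)
  spec <- metric_spec("mahalanobis", ridge = 0)
  for (i in 1:5) {
    pts <- rand_points(20)
    repeat {
      A <- matrix(rnorm(4), 2)
      if (abs(det(A)) > 0.1) break
    }
    b <- rnorm(2)
    mapped <- sweep(pts %*% t(A), 2, -b)
    expect_equal(pairwise_distances(pts, spec),
                 pairwise_distances(mapped, spec), tolerance = 1e-8)
  }
})

test_that("estimate_covariance matches closed forms and enforces n >= 3", {
  # points on y = x with unit per-axis variance -> [[1,1],[1,1]], singular
  pts <- cbind(c(-1, 0, 1), c(-1, 0, 1))          # per-axis var = 1 (n-1 = 2)
  C <- estimate_covariance(pts, ridge = 0)
  expect_equal(C, matrix(1, 2, 2))
  expect_equal(det(C), 0)

  set.seed(17)
  any_pts <- rand_points(10)
  Cbig <- estimate_covariance(any_pts, ridge = 1e6)
  expect_equal(Cbig / 1e6, diag(2), tolerance = 1e-3)

  expect_error(estimate_covariance(rand_points(2)), "n >= 3")
})

test_that("huge ridge makes Mahalanobis a scaled euclidean", {
  set.seed(18)
  pts <- rand_points(10)
  Dm <- pairwise_distances(pts, metric_spec("mahalanobis", ridge = 1e6))
  De <- pairwise_distances(pts, metric_spec("euclidean"))
  ratio <- Dm[upper.tri(Dm)] / De[upper.tri(De)]
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-4)
})

test_that("singular covariance without ridge is a clear error", {
  pts <- cbind(1:6, 1:6)                     # perfectly collinear
  expect_error(
    pairwise_distances(pts, metric_spec("mahalanobis", ridge = 0)),
    "singular|positive definite")
})

test_that("metric_spec validates its arguments", {
  expect_error(metric_spec("minkowski", p = 0), "positive")
  expect_error(metric_spec("minkowski", p = -1), "positive")
  expect_error(metric_spec("euclidean", ridge = -1), "non-negative")
  expect_error(pairwise_distances(rbind(c(0, 0)), metric_spec("euclidean")),
               "at least 2 points")
})
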