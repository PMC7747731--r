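test_that("feature matrices are standardized, complete and affine-location-free", {
  fx <- .fx()
  odf <- fitCsaOdf(fx$subjNF@dwi, fx$gtab, fx$mask)
  fm <- suppressMessages(buildFeatures(fx$mask, odf, fx$subjNF@affine))
  expect_equal(nrow(fm@x), sum(fx$mask))
  live <- fm@scale > 0
  expect_lt(max(abs(colMeans(fm@x[, live]))), 1e-8)
  expect_lt(max(abs(apply(fm@x[, live], 2, sd) - 1)), 1e-8)
  expect_true(all(fm@x[, !live] == 0))   # the unit-mass l=0 column
  # translating the affine leaves standardized spatial features unchanged
  aff2 <- fx$subjNF@affine
  aff2[1, 4] <- aff2[1, 4] + 10
  fm2 <- suppressMessages(buildFeatures(fx$mask, odf, aff2))
  expect_equal(fm@x[, 1:3], fm2@x[, 1:3], tolerance = 1e-10)
  # grid mismatch
  expect_error(buildFeatures(array(TRUE, c(2, 2, 2)), odf, aff2), "grid mismatch")
})

test_that("position-averaged initialization finds well-separated blob centers", {
  # two tight blobs on a line, k = 2: averaged centroids = blob means
  set.seed(21)
  p1 <- cbind(rnorm(40, -3, .1), rnorm(40, 0, .1), rnorm(40, 0, .1))
  p2 <- cbind(rnorm(40, 3, .1), rnorm(40, 0, .1), rnorm(40, 0, .1))
  x <- rbind(p1, p2)
  xs <- scale(x)
  fm <- new("FeatureMatrix", x = cbind(xs, 0), center = c(attr(xs, "scaled:center"), 0),
            scale = c(attr(xs, "scaled:scale"), 0), wSpatial = 0.5, wOdf = 0.5,
            voxels = cbind(seq_len(80), 1L, 1L), dim = c(80L, 1L, 1L),
            affine = diag(4))
  init <- initCentroids(fm, 2, n_runs = 20, seed = 1)
  blob_means <- rbind(colMeans(fm@x[1:40, 1:3]), colMeans(fm@x[41:80, 1:3]))
  d <- min(sum((init[1, 1:3] - blob_means[1, ])^2) +
             sum((init[2, 1:3] - blob_means[2, ])^2),
           sum((init[1, 1:3] - blob_means[2, ])^2) +
             sum((init[2, 1:3] - blob_means[1, ])^2))
  expect_lt(sqrt(d), 0.1)
  # determinism
  expect_identical(init, initCentroids(fm, 2, n_runs = 20, seed = 1))
  expect_error(initCentroids(fm, 100, n_runs = 5, seed = 1), "exceeds")
})

test_that("weighted k-means with w_odf = 0 reproduces reference spatial k-means", {
  fx <- .fx()
  odf <- fitCsaOdf(addRicianNoise(fx$subjNF, 20, seed = 3)@dwi, fx$gtab, fx$mask)
  fm <- suppressMessages(buildFeatures(fx$mask, odf, fx$subjNF@affine,
                                       w_spatial = 1, w_odf = 0))
  init <- initCentroids(fm, 4, n_runs = 20, seed = 5)
  mine <- weightedKmeans(fm, 4, init, max_iter = 200)
  ref <- suppressWarnings(
    stats::kmeans(fm@x[, 1:3], centers = init[, 1:3], iter.max = 200,
                  algorithm = "Lloyd"))
  expect_identical(clusterLabels(mine), unname(ref$cluster))
  expect_equal(centroids(mine)[, 1:3], unname(ref$centers), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the weighted k-means objective is non-increasing over iterations", {
  fx <- .fx()
  odf <- fitCsaOdf(addRicianNoise(fx$subjNF, 20, seed = 8)@dwi, fx$gtab, fx$mask)
  fm <- suppressMessages(buildFeatures(fx$mask, odf, fx$subjNF@affine))
  init <- initCentroids(fm, 4, n_runs = 20, seed = 2)
  km <- weightedKmeans(fm, 4, init)
  expect_gt(km@iterations, 1)
  expect_true(all(diff(km@objectiveTrace) <= 1e-12))
  expect_true(all(seq_len(4) %in% clusterLabels(km)))
  bad <- fm; bad@x[1, 1] <- NA_real_
  expect_error(weightedKmeans(bad, 4, init), "non-finite")
})

test_that("Davies-Bouldin matches hand-computed values and errors on empty clusters", {
  # 1-D points {0,1} and {10,11}, centroids {0.5, 10.5}: DB = (0.5+0.5)/10 = 0.1
  # (spatial x column only; weights 0.5/0.5 scale scatter and distance alike)
  x <- cbind(c(0, 1, 10, 11), 0, 0, 0)
  # scale = 0 marks columns as unstandardized constants (raw test geometry)
  fm <- new("FeatureMatrix", x = x, center = rep(0, 4), scale = rep(0, 4),
            wSpatial = 0.5, wOdf = 0.5, voxels = cbind(1:4, 1L, 1L),
            dim = c(4L, 1L, 1L), affine = diag(4))
  cen <- cbind(c(0.5, 10.5), 0, 0, 0)
  expect_equal(daviesBouldin(fm, c(1L, 1L, 2L, 2L), cen), 0.1,
               tolerance = 1e-12)
  # two singletons at distance 10: zero scatter -> DB = 0
  fm2 <- new("FeatureMatrix", x = x[c(1, 3), ], center = rep(0, 4),
             scale = rep(0, 4), wSpatial = 0.5, wOdf = 0.5,
             voxels = cbind(1:2, 1L, 1L), dim = c(2L, 1L, 1L), affine = diag(4))
  expect_equal(daviesBouldin(fm2, c(1L, 2L), x[c(1, 3), ]), 0)
  expect_error(daviesBouldin(fm, c(1L, 1L, 1L, 1L), cen), "empty cluster")
})

test_that("select_k handles a singleton range and returns finite scores", {
  fx <- .fx()
  odf <- fitCsaOdf(addRicianNoise(fx$subjNF, 20, seed = 4)@dwi, fx$gtab, fx$mask)
  fm <- suppressMessages(buildFeatures(fx$mask, odf, fx$subjNF@affine))
  sel <- selectK(fm, k_range = 2L, n_runs = 10, seed = 1)
  expect_equal(sel$best_k, 2L)
  expect_true(all(is.finite(sel$scores)) && all(sel$scores >= 0))
})

test_that("anatomical labelling follows the centroid geometry rules", {
  mk <- function(mm) {
    new("ClusterResult", labels = rep(1:4, each = 2L), centroids = matrix(0, 4, 5),
        centroidMm = mm, objective = 0, objectiveTrace = 0, iterations = 1L,
        db = NA_real_, anatomicalMap = character(),
        voxels = cbind(1:8, 1L, 1L), dim = c(8L, 1L, 1L),
        wSpatial = .5, wOdf = .5, seed = NA_real_)
  }
  # posterior y=-4 < intermediate y=-1 < anterior pair y=3, z +/- 2
  mm <- rbind(c(0, 3, 2), c(0, -4, 0), c(0, 3, -2), c(0, -1, 0))
  lab <- anatomicalMap(labelClustersAnatomically(mk(mm)))
  expect_equal(unname(lab), c("anterior-superior", "posterior",
                              "anterior-inferior", "intermediate"))
  # permuting cluster ids permutes the map coherently
  perm <- c(3, 1, 4, 2)
  lab_p <- anatomicalMap(labelClustersAnatomically(mk(mm[perm, ])))
  expect_equal(unname(lab_p), unname(lab)[perm])
  # anterior tie in z -> unclassifiable
  tie <- rbind(c(0, 3, 2), c(0, -4, 0), c(0, 3, 2.2), c(0, -1, 0))
  expect_equal(unname(anatomicalMap(suppressMessages(
    labelClustersAnatomically(tie_res <- mk(tie))))), "unclassifiable")
  # k != 4 refused
  r3 <- new("ClusterResult", labels = rep(1:3, each = 2L),
            centroids = matrix(0, 3, 5), centroidMm = mm[1:3, ],
            objective = 0, objectiveTrace = 0, iterations = 1L, db = NA_real_,
            anatomicalMap = character(), voxels = cbind(1:6, 1L, 1L),
            dim = c(6L, 1L, 1L), wSpatial = .5, wOdf = .5, seed = NA_real_)
  expect_error(labelClustersAnatomically(r3), "k=4 only")
})

test_that("the full parcellation is reproducible bit-for-bit under a fixed seed", {
  fx <- .fx()
  noisy <- addRicianNoise(fx$subjNF, 20, seed = 6)
  run <- function() {
    odf <- fitCsaOdf(noisy@dwi, fx$gtab, fx$mask)
    fm <- suppressMessages(buildFeatures(fx$mask, odf, fx$subjNF@affine))
    init <- initCentroids(fm, 4, n_runs = 25, seed = 9)
    weightedKmeans(fm, 4, init)
  }
  a <- run(); b <- run()
  expect_identical(clusterLabels(a), clusterLabels(b))
  expect_identical(centroids(a), centroids(b))
})
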