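# Weighted squared distances between feature rows and centroids:
# d(v, c)^2 = w_spatial ||p_v - p_c||^2 + w_odf ||o_v - o_c||^2.
.weightedSqDist <- function(x, centers, w_spatial, w_odf) {
  w <- c(rep(w_spatial, 3), rep(w_odf, ncol(x) - 3L))
  xs <- sweep(x, 2, sqrt(w), `*`)
  cs <- sweep(centers, 2, sqrt(w), `*`)
  d2 <- outer(rowSums(xs^2), rowSums(cs^2), `+`) - 2 * tcrossprod(xs, cs)
  pmax(d2, 0)
}

#' Position-averaged centroid initialization
#'
#' Runs `n_runs` randomly initialized k-means on the spatial block only,
#' aligns the centroids of every run to those of the first run by
#' minimum-cost matching (exhaustive over the k! permutations, k <= 6), and
#' averages the matched centroids. The ODF block of each initial centroid is
#' filled with the mean ODF features of the voxels nearest that averaged
#' spatial centroid. Deterministic for a fixed seed.
#'
#' @param features a [FeatureMatrix-class].
#' @param k number of clusters (k <= n_voxels).
#' @param n_runs number of spatial k-means runs to average (default 5000).
#' @param seed integer seed.
#' @return k x (3 + R) matrix of initial centroids in standardized feature
#'   space.
#' @export
initCentroids <- function(features, k, n_runs = 5000L, seed = 1L) {
  n <- nrow(features@x)
  if (k > n) stop("k exceeds the number of voxels")
  sp <- features@x[, 1:3, drop = FALSE]
  perms <- .permutations(as.integer(k))
  avg <- .withSeed(seed, {
    ref <- NULL
    acc <- matrix(0, k, 3)
    for (r in seq_len(n_runs)) {
      km <- stats::kmeans(sp, centers = k, nstart = 1, iter.max = 100)
      cen <- km$centers
      if (is.null(ref)) {
        ref <- cen
        acc <- acc + cen
      } else {
        costs <- vapply(perms, function(p) sum((cen[p, ] - ref)^2), numeric(1))
        acc <- acc + cen[perms[[which.min(costs)]], , drop = FALSE]
      }
    }
    acc / n_runs
  })
  # nearest-spatial-centroid assignment fills the ODF block
  d2 <- outer(rowSums(sp^2), rowSums(avg^2), `+`) - 2 * tcrossprod(sp, avg)
  assign <- max.col(-d2, ties.method = "first")
  init <- matrix(0, k, ncol(features@x))
  init[, 1:3] <- avg
  for (c in seq_len(k)) {
    members <- which(assign == c)
    if (!length(members)) members <- which.min(d2[, c])
    init[c, 4:ncol(init)] <-
      colMeans(features@x[members, -(1:3), drop = FALSE])
  }
  colnames(init) <- colnames(features@x)
  init
}

#' Equal-weighted k-means on spatial and ODF features
#'
#' Lloyd's algorithm under the block-weighted squared distance
#' `w_spatial ||p_v - p_c||^2 + w_odf ||o_v - o_c||^2` (defaults 0.5/0.5 from
#' the feature matrix): the spatial block constrains clusters to be
#' contiguous while the ODF block groups voxels with similar diffusion
#' profiles. Centroid updates are blockwise means (optimal for this metric).
#' Stops when the relative objective decrease falls below `tol` or after
#' `max_iter` iterations; an emptied cluster is re-seeded at the point
#' farthest from its centroid (reported via `message()`).
#'
#' @param features a [FeatureMatrix-class].
#' @param k number of clusters.
#' @param init k x (3 + R) initial centroid matrix (standardized space),
#'   e.g. from [initCentroids()].
#' @param max_iter maximum Lloyd iterations (default 300).
#' @param tol relative objective-change stopping threshold (default 1e-6).
#' @param seed seed recorded in the result (bookkeeping only; the algorithm
#'   itself is deterministic given `init`).
#' @return A [ClusterResult-class].
#' @export
weightedKmeans <- function(features, k, init, max_iter = 300L, tol = 1e-6,
                           seed = NA_real_) {
  x <- features@x
  if (!all(is.finite(x))) stop("non-finite features")
  if (nrow(init) != k || ncol(init) != ncol(x))
    stop("init must be a k x (3 + R) centroid matrix")
  ws <- features@wSpatial; wo <- features@wOdf
  centers <- init
  obj_prev <- Inf
  labels <- NULL
  iter <- 0L
  obj <- NA_real_
  trace <- numeric()
  repeat {
    iter <- iter + 1L
    d2 <- .weightedSqDist(x, centers, ws, wo)
    labels <- max.col(-d2, ties.method = "first")
    for (c in seq_len(k)) {
      if (!any(labels == c)) {
        far <- which.max(d2[cbind(seq_len(nrow(x)), labels)])
        message(sprintf("weightedKmeans: re-seeded empty cluster %d", c))
        labels[far] <- c
      }
    }
    obj <- sum(d2[cbind(seq_len(nrow(x)), labels)])
    trace <- c(trace, obj)
    for (c in seq_len(k))
      centers[c, ] <- colMeans(x[labels == c, , drop = FALSE])
    if ((is.finite(obj_prev) &&
         obj_prev - obj <= tol * max(obj_prev, .Machine$double.eps)) ||
        iter >= max_iter) break
    obj_prev <- obj
  }
  # world-mm centroid positions from the standardization parameters
  live <- features@scale[1:3]
  mm <- sweep(centers[, 1:3, drop = FALSE], 2, ifelse(live > 0, live, 1), `*`)
  mm <- sweep(mm, 2, features@center[1:3], `+`)
  new("ClusterResult", labels = as.integer(labels), centroids = centers,
      centroidMm = mm, objective = obj, objectiveTrace = trace,
      iterations = iter, db = NA_real_,
      anatomicalMap = character(), voxels = features@voxels,
      dim = features@dim, wSpatial = ws, wOdf = wo, seed = seed)
}

#' Davies-Bouldin index under the weighted metric
#'
#' DB = (1/k) sum_i max_{j != i} (s_i + s_j) / d(c_i, c_j), where s_i is the
#' mean weighted distance of cluster-i points to their centroid and d the
#' same weighted metric between centroids. Lower is better.
#'
#' @param features a [FeatureMatrix-class].
#' @param labels integer cluster labels in 1..k.
#' @param centroids k x (3 + R) centroid matrix.
#' @return Non-negative scalar score.
#' @export
daviesBouldin <- function(features, labels, centroids) {
  k <- nrow(centroids)
  if (k < 2) stop("Davies-Bouldin requires >= 2 clusters")
  if (!all(seq_len(k) %in% labels)) stop("empty cluster in Davies-Bouldin input")
  d2 <- .weightedSqDist(features@x, centroids, features@wSpatial, features@wOdf)
  s <- vapply(seq_len(k), function(c)
    mean(sqrt(d2[labels == c, c])), numeric(1))
  cd2 <- .weightedSqDist(centroids, centroids, features@wSpatial, features@wOdf)
  cd <- sqrt(cd2)
  ratio <- outer(s, s, `+`) / cd
  diag(ratio) <- -Inf
  mean(apply(ratio, 1, max))
}

#' Select the number of clusters by the Davies-Bouldin index
#'
#' Runs the full pipeline (position-averaged initialization, weighted k-means,
#' Davies-Bouldin scoring) for every k in `k_range` and returns the k with the
#' minimal score; ties break toward smaller k (reported via `message()`).
#'
#' @param features a [FeatureMatrix-class].
#' @param k_range candidate cluster counts (default 2:6).
#' @param n_runs initialization runs per k (see [initCentroids()]).
#' @param seed integer seed.
#' @param ... passed to [weightedKmeans()].
#' @return `list(best_k, scores (named per k), results (per-k
#'   [ClusterResult-class]))`.
#' @export
selectK <- function(features, k_range = 2:6, n_runs = 5000L, seed = 1L, ...) {
  if (max(k_range) > nrow(features@x)) stop("k exceeds the number of voxels")
  results <- vector("list", length(k_range))
  scores <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    init <- initCentroids(features, k, n_runs = n_runs, seed = seed + k)
    res <- weightedKmeans(features, k, init, seed = seed + k, ...)
    scores[i] <- daviesBouldin(features, res@labels, res@centroids)
    results[[i]] <- initialize(res, db = scores[i])
  }
  names(scores) <- names(results) <- as.character(k_range)
  ord <- order(scores, k_range)
  if (length(scores) > 1 && abs(scores[ord[1]] - scores[ord[2]]) < 1e-12)
    message("selectK: tie on Davies-Bouldin, choosing the smaller k")
  best <- k_range[ord[1]]
  list(best_k = best, scores = scores, results = results)
}

#' Anatomical labelling of a four-cluster parcellation
#'
#' Assigns the four clusters to hypothalamic subunits from their centroid
#' world coordinates: the most posterior centroid (smallest y) is `posterior`,
#' the next `intermediate`; the remaining two split by z into
#' `anterior-superior` (larger z) and `anterior-inferior`. If any deciding
#' coordinate difference is below `tol_mm` the configuration is declared
#' `"unclassifiable"` (as happens for a small fraction of real subjects).
#'
#' @param result a [ClusterResult-class] with k = 4.
#' @param tol_mm minimal deciding coordinate difference in mm (default 0.5).
#' @return The result with its `anatomicalMap` slot filled: either a named
#'   character vector (cluster id -> subunit) or the single value
#'   `"unclassifiable"`.
#' @export
labelClustersAnatomically <- function(result, tol_mm = 0.5) {
  k <- nrow(result@centroids)
  if (k != 4) stop("anatomical labelling defined for k=4 only")
  mm <- result@centroidMm
  o <- order(mm[, 2])
  anterior <- o[3:4]
  decisive <- c(mm[o[2], 2] - mm[o[1], 2],
                mm[o[3], 2] - mm[o[2], 2],
                abs(mm[anterior[1], 3] - mm[anterior[2], 3]))
  if (any(decisive < tol_mm)) {
    message("labelClustersAnatomically: ambiguous centroid layout -> unclassifiable")
    return(initialize(result, anatomicalMap = "unclassifiable"))
  }
  map <- character(4)
  map[o[1]] <- "posterior"
  map[o[2]] <- "intermediate"
  sup <- anterior[which.max(mm[anterior, 3])]
  inf <- setdiff(anterior, sup)
  map[sup] <- "anterior-superior"
  map[inf] <- "anterior-inferior"
  names(map) <- as.character(seq_len(4))
  initialize(result, anatomicalMap = map)
}
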