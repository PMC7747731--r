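#' Extract a single b-value shell
#'
#' Keeps all b = 0 volumes and every volume whose b-value lies within
#' `tol` of `b_target`, preserving acquisition order.
#'
#' @param dwi 4-D DWI array.
#' @param gtab a [GradientTable-class].
#' @param b_target shell b-value, s/mm^2.
#' @param tol b-value tolerance, s/mm^2 (default 100).
#' @return `list(dwi = <4-D array>, gtab = <GradientTable>)`.
#' @export
extractShell <- function(dwi, gtab, b_target = 1000, tol = 100) {
  keep <- gtab@bvals == 0 | abs(gtab@bvals - b_target) <= tol
  n_dirs <- sum(keep & gtab@bvals > 0)
  if (n_dirs < 6)
    stop(sprintf("insufficient directions: found %d within %g +/- %g s/mm^2 (need >= 6)",
                 n_dirs, b_target, tol))
  if (!any(keep & gtab@bvals == 0))
    stop("no b = 0 volume available for the requested shell")
  list(dwi = dwi[, , , keep, drop = FALSE],
       gtab = new("GradientTable", bvals = gtab@bvals[keep],
                  bvecs = gtab@bvecs[keep, , drop = FALSE]))
}

# Tensor design matrix: ln S = ln S0 - b g' D g, columns
# [1, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz] coefficients.
.tensorDesign <- function(gtab) {
  g <- gtab@bvecs
  b <- gtab@bvals
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit the diffusion tensor (weighted least squares)
#'
#' Log-linear tensor fit per in-mask voxel: an ordinary least-squares fit of
#' ln S on the b-matrix design followed by one weighted refinement with
#' weights equal to the squared predicted signals (the standard WLS scheme).
#' Non-positive signals are clipped to a small positive floor and flagged.
#' FA is computed as sqrt(1/2) sqrt(sum (lambda_i - lambda_j)^2) /
#' sqrt(sum lambda_i^2) over the three ordered pairs; MD as the eigenvalue
#' mean.
#'
#' @param dwi 4-D single-shell DWI array (including b = 0 volumes).
#' @param gtab matching [GradientTable-class].
#' @param mask 3-D logical array of voxels to fit.
#' @return A [TensorFit-class].
#' @export
fitTensor <- function(dwi, gtab, mask) {
  .stopIfGridMismatch(dim(dwi)[1:3], dim(mask), what = "DWI and mask")
  X <- .tensorDesign(gtab)
  if (qr(X)$rank < 7L)
    stop("singular tensor design: need >= 6 unique directions plus b = 0")
  vox <- which(mask, arr.ind = TRUE)
  n <- nrow(vox)
  nvol <- dim(dwi)[4]
  S <- matrix(dwi, ncol = nvol)[which(mask), , drop = FALSE]
  floor_ <- 1e-6 * max(S)
  n_clip <- sum(S < floor_)
  if (n_clip > 0)
    message(sprintf("fitTensor: clipped %d non-positive signals to floor", n_clip))
  S[S < floor_] <- floor_
  Y <- t(log(S))                         # nvol x nvox
  beta_ols <- solve(crossprod(X), crossprod(X, Y))
  evals <- matrix(NA_real_, n, 3)
  evecs <- matrix(NA_real_, n, 3)
  for (v in seq_len(n)) {
    w <- exp(2 * as.vector(X %*% beta_ols[, v]))   # predicted-signal^2 weights
    Xw <- X * w
    beta <- solve(crossprod(Xw, X), crossprod(Xw, Y[, v]))
    D <- matrix(c(beta[2], beta[5], beta[6],
                  beta[5], beta[3], beta[7],
                  beta[6], beta[7], beta[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    evals[v, ] <- e$values
    evecs[v, ] <- e$vectors[, 1]
  }
  md <- rowMeans(evals)
  num <- (evals[, 1] - evals[, 2])^2 + (evals[, 2] - evals[, 3])^2 +
    (evals[, 3] - evals[, 1])^2
  den <- rowSums(evals^2)
  fa <- sqrt(0.5) * sqrt(num / pmax(den, .Machine$double.eps))
  fa <- pmin(pmax(fa, 0), 1)
  fa_map <- array(NA_real_, dim(mask)); fa_map[mask] <- fa
  md_map <- array(NA_real_, dim(mask)); md_map[mask] <- md
  new("TensorFit", evals = evals, evecs = evecs, fa = fa_map, md = md_map,
      voxels = vox, mask = mask)
}

#' Constant-solid-angle q-ball ODF estimation
#'
#' Estimates the diffusion ODF per in-mask voxel from single-shell data in a
#' real, symmetric, even-order spherical-harmonic basis (see `shBasis`), using
#' the constant-solid-angle q-ball formulation: the attenuation E = S/S0
#' (b = 0 volumes averaged into one S0) is clipped into (eps, 1 - eps), the
#' double-log transform ln(-ln E) is fit in the SH basis with Laplace-Beltrami
#' regularization, and the ODF is
#'   psi = 1/(4 pi) + 1/(16 pi^2) FRT( Laplacian_b ln(-ln E) ),
#' which in SH coefficients multiplies order-l terms by
#' -l(l+1) P_l(0) / (8 pi) and fixes the l = 0 coefficient at the unit-mass
#' constant 1/(2 sqrt(pi)).
#'
#' @param dwi 4-D single-shell DWI array.
#' @param gtab matching [GradientTable-class].
#' @param mask 3-D logical array.
#' @param lmax maximum even SH order (default 6, i.e. 28 coefficients).
#' @param reg_lambda Laplace-Beltrami regularization weight (default 0.006).
#' @param clip_eps attenuation clipping bound (default 1e-4).
#' @return An [OdfField-class].
#' @export
fitCsaOdf <- function(dwi, gtab, mask, lmax = 6L, reg_lambda = 0.006,
                      clip_eps = 1e-4) {
  .stopIfGridMismatch(dim(dwi)[1:3], dim(mask), what = "DWI and mask")
  if (lmax %% 2 != 0) stop("lmax must be even")
  R <- shCount(lmax)
  sh <- .csaSetup(gtab, lmax, reg_lambda)
  if (sum(sh$dwi_sel) < R)
    stop(sprintf("fewer directions (%d) than SH coefficients (%d)",
                 sum(sh$dwi_sel), R))
  vox <- which(mask, arr.ind = TRUE)
  nvol <- dim(dwi)[4]
  S <- matrix(dwi, ncol = nvol)[which(mask), , drop = FALSE]
  co <- .csaCoefficients(S, sh, clip_eps)
  new("OdfField", coefficients = co, lmax = as.integer(lmax),
      basis = "real-sym-descartes", voxels = vox, dim = dim(mask))
}

# Shared pieces of the CSA fit: shell selection, design, regularized solver,
# and the FRT/Laplacian scaling per coefficient.
.csaSetup <- function(gtab, lmax, reg_lambda) {
  dwi_sel <- gtab@bvals > 0
  b0_sel <- gtab@bvals == 0
  if (!any(b0_sel)) stop("CSA fit requires at least one b = 0 volume")
  B <- shBasis(gtab@bvecs[dwi_sel, , drop = FALSE], lmax)
  ord <- shOrders(lmax)
  L <- diag(ord$l * (ord$l + 1))
  M <- solve(crossprod(B) + reg_lambda * L %*% L, t(B))
  scale <- -ord$l * (ord$l + 1) * legendreAtZero(ord$l) / (8 * pi)
  list(dwi_sel = dwi_sel, b0_sel = b0_sel, B = B, M = M, scale = scale,
       l0 = 1 / (2 * sqrt(pi)))
}

# S: n_vox x n_vol signal matrix -> n_vox x R ODF coefficients.
.csaCoefficients <- function(S, sh, clip_eps) {
  S0 <- rowMeans(S[, sh$b0_sel, drop = FALSE])
  dead <- S0 <= 0
  if (any(dead))
    message(sprintf("fitCsaOdf: %d all-zero voxels set to isotropic", sum(dead)))
  S0[dead] <- 1
  E <- S[, sh$dwi_sel, drop = FALSE] / S0
  E <- pmin(pmax(E, clip_eps), 1 - clip_eps)
  Y <- t(log(-log(E)))                       # n_dirs x n_vox
  Scoef <- sh$M %*% Y                        # R x n_vox
  co <- t(Scoef * sh$scale)
  co[, 1] <- sh$l0
  if (any(dead)) co[dead, -1] <- 0
  co
}

#' Residual-bootstrap averaged CSA ODFs
#'
#' Repeats the constant-solid-angle spherical-harmonic regression on residual
#' bootstrap replicates of the per-voxel double-log signal (residuals of the
#' SH fit resampled with replacement, independently per voxel), and returns
#' the per-voxel mean ODF coefficient vector over `n_samples` replicates.
#'
#' @inheritParams fitCsaOdf
#' @param n_samples number of bootstrap replicates (default 50).
#' @param seed integer seed.
#' @return An [OdfField-class] of bootstrap-mean coefficients.
#' @export
bootstrapOdf <- function(dwi, gtab, mask, lmax = 6L, reg_lambda = 0.006,
                         clip_eps = 1e-4, n_samples = 50L, seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  .stopIfGridMismatch(dim(dwi)[1:3], dim(mask), what = "DWI and mask")
  R <- shCount(lmax)
  sh <- .csaSetup(gtab, lmax, reg_lambda)
  if (sum(sh$dwi_sel) < R)
    stop(sprintf("fewer directions (%d) than SH coefficients (%d)",
                 sum(sh$dwi_sel), R))
  vox <- which(mask, arr.ind = TRUE)
  nvol <- dim(dwi)[4]
  S <- matrix(dwi, ncol = nvol)[which(mask), , drop = FALSE]
  S0 <- rowMeans(S[, sh$b0_sel, drop = FALSE])
  S0[S0 <= 0] <- 1
  E <- S[, sh$dwi_sel, drop = FALSE] / S0
  E <- pmin(pmax(E, clip_eps), 1 - clip_eps)
  Y <- t(log(-log(E)))                       # n_dirs x n_vox
  Shat <- sh$M %*% Y
  Yhat <- sh$B %*% Shat
  res <- Y - Yhat
  nd <- nrow(Y); nv <- ncol(Y)
  acc <- matrix(0, R, nv)
  .withSeed(seed, {
    for (i in seq_len(n_samples)) {
      idx <- matrix(sample.int(nd, nd * nv, replace = TRUE), nd, nv)
      Ystar <- Yhat + res[cbind(as.vector(idx), rep(seq_len(nv), each = nd))]
      dim(Ystar) <- c(nd, nv)
      acc <- acc + sh$M %*% Ystar
    }
  })
  co <- t((acc / n_samples) * sh$scale)
  co[, 1] <- sh$l0
  new("OdfField", coefficients = co, lmax = as.integer(lmax),
      basis = "real-sym-descartes", voxels = vox, dim = dim(mask))
}

#' Evaluate ODF amplitudes and find peak directions
#'
#' `odfAmplitudes()` evaluates the SH expansion at given unit directions;
#' `odfPeak()` returns the direction of the maximum amplitude over a dense
#' spherical-Fibonacci grid, per voxel.
#'
#' @param odfs an [OdfField-class].
#' @param dirs n x 3 unit direction matrix.
#' @param n_grid grid density for peak search (default 4000).
#' @return `odfAmplitudes()`: voxels x directions matrix; `odfPeak()`: voxels
#'   x 3 matrix of unit peak directions.
#' @export
odfAmplitudes <- function(odfs, dirs) {
  odfs@coefficients %*% t(shBasis(dirs, odfs@lmax))
}

#' @rdname odfAmplitudes
#' @export
odfPeak <- function(odfs, n_grid = 4000L) {
  grid <- fibonacciSphere(n_grid)
  amp <- odfAmplitudes(odfs, grid)
  grid[max.col(amp, ties.method = "first"), , drop = FALSE]
}
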