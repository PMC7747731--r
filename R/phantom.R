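# Lobe centres (voxel units relative to the grid centre), rows ordered
# anterior-superior, anterior-inferior, intermediate, posterior. y/z spacing
# implements the anatomical layout; alternating x offsets keep the
# standardized coordinate cloud three-dimensional.
.defaultLobeCenters <- rbind(c( 1.2,  3.0,  2.2),
                             c(-1.2,  3.0, -2.2),
                             c( 1.2, -0.7,  0.0),
                             c(-1.2, -3.9,  0.0))

#' Default four-subunit hypothalamus phantom
#'
#' Builds the geometry the package's validation experiments run on: a
#' hypothalamus-scale blob (~0.7 cm^3 at 1.25 mm voxels) formed as the union
#' of four overlapping spherical lobes — anterior-superior, anterior-inferior,
#' intermediate, and posterior — arranged along the anterior-posterior (y) and
#' inferior-superior (z) world axes with alternating left-right (x) offsets,
#' and surrounded by a one-voxel isotropic CSF rim. Voxels in the overlap are
#' assigned to the nearest lobe centre, so the ground-truth subunits partition
#' the mask into compact, 6-connected blocks whose centroid layout exercises
#' the anatomical labelling rule (posterior lowest y, intermediate next, the
#' anterior pair split by z). The x offsets spread the lobe centres over all
#' three axes: after per-axis standardization of voxel coordinates no axis
#' degenerates into a pure within-lobe direction, which keeps the
#' position-only k-means initialization well posed.
#'
#' Each subunit carries two orthogonal "crossing-fiber" stick compartments
#' (50/50, eigenvalues (1.5, 0.25, 0.25) x 10^-3 mm^2/s). The crossing
#' geometry gives strong, subunit-specific ODF signatures — the information
#' the parcellation clusters on — while the voxel-average tensor stays oblate
#' with FA ~ 0.50, below the 0.55 mask-refinement threshold, as in real
#' (grey-matter plus traversing-fiber) hypothalamic tissue. Orientation pairs
#' of different subunits differ by at least 45 degrees. CSF is isotropic at
#' 3.0 x 10^-3 mm^2/s.
#'
#' @param dim grid shape (default `c(16, 20, 16)`).
#' @param voxel_size voxel edge in mm (default 1.25).
#' @param lobe_centers 4 x 3 matrix of lobe centres in voxel units relative to
#'   the grid centre, rows ordered anterior-superior, anterior-inferior,
#'   intermediate, posterior.
#' @param lobe_radius lobe radius in voxels (default 2.9).
#' @param evals per-stick tensor eigenvalues, mm^2/s.
#' @param fiber_pairs named list (labels "1".."4") of 2 x 3 matrices of unit
#'   stick orientations per subunit.
#' @param csf_d,background_d isotropic diffusivities, mm^2/s.
#' @param S0 b = 0 signal level.
#' @param snr default SNR (S0/sigma).
#' @param seed default seed.
#' @return A [PhantomSpec-class]. Label ids: 1 = anterior-superior,
#'   2 = anterior-inferior, 3 = intermediate, 4 = posterior.
#' @examples
#' spec <- defaultPhantomSpec()
#' table(spec@labels[spec@labels > 0])
#' @export
defaultPhantomSpec <- function(dim = c(16L, 20L, 16L), voxel_size = 1.25,
                               lobe_centers = .defaultLobeCenters,
                               lobe_radius = 2.9,
                               evals = c(1.5, 0.25, 0.25) * 1e-3,
                               fiber_pairs = list(
                                 "1" = rbind(c(1, 0, 0), c(0, 1, 0)),
                                 "2" = rbind(c(1, 0, 1), c(1, 0, -1)) / sqrt(2),
                                 "3" = rbind(c(0, 1, 1), c(0, 1, -1)) / sqrt(2),
                                 "4" = rbind(c(1, 1, 0), c(1, -1, 0)) / sqrt(2)),
                               csf_d = 3.0e-3, background_d = 0.8e-3,
                               S0 = 1000, snr = 20, seed = 1L) {
  dim <- as.integer(dim)
  ctr <- (dim + 1) / 2
  g <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]), k = seq_len(dim[3]))
  P <- cbind(g$i - ctr[1], g$j - ctr[2], g$k - ctr[3])
  d2 <- vapply(1:4, function(r) rowSums(sweep(P, 2, lobe_centers[r, ])^2),
               numeric(nrow(P)))
  inmask <- apply(d2, 1, min) <= lobe_radius^2
  lab <- integer(nrow(P))
  lab[inmask] <- apply(d2[inmask, , drop = FALSE], 1, which.min)
  labels <- array(as.integer(lab), dim)
  csf <- .dilate6(labels > 0) & !(labels > 0)
  regions <- lapply(as.character(1:4), function(id)
    lapply(seq_len(nrow(fiber_pairs[[id]])), function(i)
      list(orientation = fiber_pairs[[id]][i, ],
           fraction = 1 / nrow(fiber_pairs[[id]]), evals = evals)))
  names(regions) <- as.character(1:4)
  new("PhantomSpec", dim = dim, voxelSize = voxel_size, labels = labels,
      regions = regions, csfMask = csf, csfDiffusivity = csf_d,
      backgroundDiffusivity = background_d, S0 = S0, snr = snr,
      seed = as.numeric(seed))
}

# Voxel-to-world affine of a phantom: RAS axes scaled by voxel size, origin at
# the grid centre (0-based voxel convention).
phantomAffine <- function(spec) {
  ctr <- (spec@dim + 1) / 2
  aff <- diag(c(rep(spec@voxelSize, 3), 1))
  aff[1:3, 4] <- -(ctr - 1) * spec@voxelSize
  aff
}

# Attenuation of one tensor compartment at all gradient-table volumes.
.compartmentAttenuation <- function(cp, gtab) {
  e1 <- cp$orientation / sqrt(sum(cp$orientation^2))
  # complete an orthonormal frame around the fiber axis
  up <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- up - sum(up * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  g <- gtab@bvecs
  q <- cp$evals[1] * (g %*% e1)^2 + cp$evals[2] * (g %*% e2)^2 +
    cp$evals[3] * (g %*% e3)^2
  exp(-gtab@bvals * as.vector(q))
}

#' Simulate noise-free DWI signal from a phantom specification
#'
#' Evaluates the multi-tensor model S(b, g) = S0 * sum_i f_i exp(-b g' D_i g)
#' in every labelled voxel, isotropic attenuation at the CSF diffusivity in
#' rim voxels and at the background diffusivity elsewhere. Covariates are left
#' empty; [makeCohort()] fills them.
#'
#' @param spec a [PhantomSpec-class].
#' @param gtab a [GradientTable-class].
#' @return A [SyntheticSubject-class] with noise-free DWI.
#' @export
simulateSignal <- function(spec, gtab) {
  validObject(spec)
  dim4 <- c(spec@dim, nVolumes(gtab))
  nvox <- prod(spec@dim)
  sig <- matrix(NA_real_, nvox, dim4[4])
  bg <- exp(-gtab@bvals * spec@backgroundDiffusivity)
  sig[] <- rep(bg, each = nvox)
  csf <- exp(-gtab@bvals * spec@csfDiffusivity)
  sig[which(spec@csfMask), ] <- rep(csf, each = sum(spec@csfMask))
  for (id in names(spec@regions)) {
    vox <- which(spec@labels == as.integer(id))
    if (!length(vox)) next
    att <- Reduce(`+`, lapply(spec@regions[[id]], function(cp)
      cp$fraction * .compartmentAttenuation(cp, gtab)))
    sig[vox, ] <- rep(att, each = length(vox))
  }
  dwi <- array(spec@S0 * sig, dim4)
  csfprob <- array(0, spec@dim)
  csfprob[spec@csfMask] <- 0.9
  csfprob[spec@labels > 0] <- 0.02
  new("SyntheticSubject", dwi = dwi, gtab = gtab, affine = phantomAffine(spec),
      labels = spec@labels, csf = csfprob, covariates = list())
}

#' Add Rician noise to a synthetic subject
#'
#' Replaces every measurement S by sqrt((S + e1)^2 + e2^2) with independent
#' e1, e2 ~ Normal(0, sigma^2) and sigma = S0/snr — the standard magnitude-MR
#' noise model.
#'
#' @param subject a [SyntheticSubject-class] with simulated DWI.
#' @param snr signal-to-noise ratio S0/sigma (> 0).
#' @param seed integer seed.
#' @param S0 reference signal level defining sigma; defaults to the mean b = 0
#'   intensity over non-background voxels.
#' @return The subject with noisy DWI.
#' @export
addRicianNoise <- function(subject, snr, seed = 1L, S0 = NULL) {
  if (snr <= 0) stop("snr must be positive")
  if (!length(subject@dwi)) stop("subject carries no simulated DWI")
  if (is.null(S0)) {
    b0 <- which(subject@gtab@bvals == 0)[1]
    vol <- subject@dwi[, , , b0]
    S0 <- mean(vol[subject@labels > 0])
  }
  sigma <- S0 / snr
  noisy <- .withSeed(seed, {
    e1 <- array(stats::rnorm(length(subject@dwi), 0, sigma), dim(subject@dwi))
    e2 <- array(stats::rnorm(length(subject@dwi), 0, sigma), dim(subject@dwi))
    sqrt((subject@dwi + e1)^2 + e2^2)
  })
  initialize(subject, dwi = noisy)
}
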