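#' Construct a single-shell gradient table
#'
#' Generates `n_dirs` diffusion-weighting directions spread nearly uniformly
#' over the sphere (spherical Fibonacci lattice rotated by a seed-determined
#' random rotation) at b-value `bval`, plus `n_b0` non-diffusion-weighted
#' volumes interspersed evenly through the acquisition, emulating a typical
#' single-shell protocol of ~90 directions and 6 b = 0 images.
#'
#' @param n_dirs number of diffusion-weighting directions (>= 6).
#' @param n_b0 number of b = 0 volumes.
#' @param bval shell b-value in s/mm^2 (> 0).
#' @param seed integer seed controlling the random rotation.
#' @return A [GradientTable-class].
#' @examples
#' gtab <- makeGradientTable(90, 6, 1000, seed = 1)
#' table(bvals(gtab))
#' @export
makeGradientTable <- function(n_dirs, n_b0 = 6L, bval = 1000, seed = 1L) {
  if (n_dirs < 6) stop("insufficient directions for lmax >= 2 fit (need n_dirs >= 6)")
  if (bval <= 0) stop("bval must be positive")
  dirs <- fibonacciSphere(n_dirs)
  rot <- .withSeed(seed, {
    repeat {
      q <- qr(matrix(stats::rnorm(9), 3))
      R <- qr.Q(q)
      R <- R %*% diag(sign(diag(qr.R(q))))
      if (det(R) > 0) break
    }
    R
  })
  dirs <- dirs %*% t(rot)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  n <- n_dirs + n_b0
  b0_at <- if (n_b0 > 0) unique(round(seq(1, n, length.out = n_b0))) else integer()
  if (length(b0_at) < n_b0)  # rounding collisions only occur for tiny n
    b0_at <- c(b0_at, setdiff(seq_len(n), b0_at)[seq_len(n_b0 - length(b0_at))])
  bvals <- rep(bval, n)
  bvecs <- matrix(0, n, 3)
  bvals[b0_at] <- 0
  dwi_at <- setdiff(seq_len(n), b0_at)
  bvecs[dwi_at, ] <- dirs
  new("GradientTable", bvals = bvals, bvecs = bvecs)
}

#' Read and write FSL-style gradient text files
#'
#' `readBvalsBvecs()` parses whitespace-separated `bvals` (one row) and
#' `bvecs` (three rows, x/y/z) files; `writeBvalsBvecs()` writes them.
#'
#' @param bvals_path,bvecs_path file paths.
#' @param gtab a [GradientTable-class].
#' @return `readBvalsBvecs()` returns a [GradientTable-class];
#'   `writeBvalsBvecs()` returns the paths invisibly.
#' @export
readBvalsBvecs <- function(bvals_path, bvecs_path) {
  for (p in c(bvals_path, bvecs_path))
    if (!file.exists(p)) stop("gradient file not found: ", p)
  bvals <- scan(bvals_path, quiet = TRUE)
  vec <- scan(bvecs_path, quiet = TRUE)
  if (length(vec) != 3 * length(bvals))
    stop("bvecs must contain 3 rows of ", length(bvals), " entries")
  bvecs <- t(matrix(vec, nrow = 3, byrow = TRUE))
  nz <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  bvecs[nz, ] <- bvecs[nz, , drop = FALSE] / nrm[nz]
  bvecs[!nz, ] <- 0
  new("GradientTable", bvals = bvals, bvecs = bvecs)
}

#' @rdname readBvalsBvecs
#' @export
writeBvalsBvecs <- function(gtab, bvals_path, bvecs_path) {
  writeLines(paste(format(gtab@bvals, trim = TRUE), collapse = " "), bvals_path)
  rows <- apply(t(gtab@bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(rows, bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}
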