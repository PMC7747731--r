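# Internal helpers shared across modules.

.subunitNames <- c("anterior-superior", "anterior-inferior",
                   "intermediate", "posterior")

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# 6-connectivity check (face neighbours) on a logical 3-D array.
.isConnected6 <- function(mask) {
  n <- sum(mask)
  if (n == 0L) return(TRUE)
  idx <- which(mask, arr.ind = TRUE)
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3])
  inside <- new.env(hash = TRUE, size = n)
  for (r in seq_len(n)) assign(key(idx[r, , drop = FALSE]), r, envir = inside)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    for (o in seq_len(6)) {
      nb <- idx[cur, ] + offs[o, ]
      k <- paste(nb[1], nb[2], nb[3])
      r <- get0(k, envir = inside)
      if (!is.null(r) && !seen[r]) {
        seen[r] <- TRUE
        queue <- c(queue, r)
      }
    }
  }
  all(seen)
}

# All permutations of 1..k (k small; used for centroid matching, k <= 6).
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- .permutations(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(k)) {
      i <- i + 1L
      out[[i]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# Map 1-based voxel indices (n x 3) to world mm via a 4x4 affine that follows
# the NIfTI convention (0-based voxel indices).
.voxelToWorld <- function(voxels, affine) {
  v0 <- cbind(voxels - 1, 1)
  t(affine %*% t(v0))[, 1:3, drop = FALSE]
}

# One step of 6-neighbour (face-connected) binary dilation.
.dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(a, ax, by) {
    res <- array(FALSE, d)
    src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    if (by == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    res[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    res
  }
  for (ax in 1:3) for (by in c(1, -1)) out <- out | shift(mask, ax, by)
  out
}

.stopIfGridMismatch <- function(..., what = "inputs") {
  dims <- list(...)
  ref <- dims[[1]]
  for (d in dims[-1]) {
    if (!identical(ref, d))
      stop(sprintf("grid mismatch: %s must share the same array dimensions", what))
  }
  invisible(TRUE)
}
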