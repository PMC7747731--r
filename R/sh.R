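# Real, symmetric (even-order-only) spherical-harmonic basis.
#
# Basis convention ("real-sym-descartes"): coefficients are ordered with l
# ascending over the even orders 0, 2, ..., lmax and m = -l..l within each l.
# With theta the polar angle from +z and phi the azimuth from +x,
#   Y_{l,m} = sqrt(2) N_{l|m|} P_l^{|m|}(cos theta) sin(|m| phi)   (m < 0)
#   Y_{l,0} = N_{l0} P_l^0(cos theta)
#   Y_{l,m} = sqrt(2) N_{lm}  P_l^m(cos theta)  cos(m phi)         (m > 0)
# with N_{lm} = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!) and P_l^m including the
# Condon-Shortley phase (as pracma::legendre / MATLAB). The basis is
# orthonormal on the sphere; Y_{0,0} = 1/(2 sqrt(pi)).

# (l, m) index table for the even orders up to lmax.
shOrders <- function(lmax) {
  ls <- seq(0L, as.integer(lmax), by = 2L)
  data.frame(l = unlist(lapply(ls, function(l) rep(l, 2L * l + 1L))),
             m = unlist(lapply(ls, function(l) seq(-l, l))))
}

# Number of coefficients R = (lmax+1)(lmax+2)/2 for even-order-only bases.
shCount <- function(lmax) as.integer((lmax + 1) * (lmax + 2) / 2)

# Evaluate the basis at unit directions: returns n x R design matrix.
shBasis <- function(dirs, lmax) {
  stopifnot(lmax %% 2 == 0, ncol(dirs) == 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  ord <- shOrders(lmax)
  B <- matrix(0, nrow(dirs), nrow(ord))
  for (l in seq(0L, as.integer(lmax), by = 2L)) {
    P <- if (l == 0L) matrix(1, 1L, length(ct)) else pracma::legendre(l, ct)
    if (is.vector(P)) P <- matrix(P, nrow = l + 1L)
    for (m in -l:l) {
      j <- which(ord$l == l & ord$m == m)
      am <- abs(m)
      nlm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      plm <- P[am + 1L, ]
      B[, j] <- if (m < 0) sqrt(2) * nlm * plm * sin(am * phi)
      else if (m == 0) nlm * plm
      else sqrt(2) * nlm * plm * cos(am * phi)
    }
  }
  B
}

# Legendre polynomial value at 0 for even l: P_l(0) = (-1)^(l/2) C(l, l/2) / 2^l.
legendreAtZero <- function(l) {
  ifelse(l %% 2 == 1, 0,
         (-1)^(l / 2) * exp(lchoose(l, l / 2) - l * log(2)))
}

# Deterministic, nearly uniform unit directions (spherical Fibonacci lattice).
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  phi <- ga * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}
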