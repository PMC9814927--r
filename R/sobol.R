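# Sobol' low-discrepancy sequences. Direction numbers are constructed from
# first principles: primitive polynomials over GF(2) are enumerated
# programmatically (a degree-d polynomial is primitive iff x has order
# 2^d - 1 in GF(2)[x]/(p)), and initial direction integers are taken as the
# unit choice m_i = 1 (valid: every m_i is odd and < 2^i). Dimension 1 is the
# van der Corput sequence in base 2. Points are generated by the Gray-code
# construction directly from the absolute index, so the i-th point never
# depends on how many points were generated before it.

SOBOL_NBITS <- 30

# carry-less multiplication of GF(2) polynomials (integer bitmasks)
gf2_mul <- function(a, b) {
  r <- 0
  while (b > 0) {
    if (bitwAnd(b, 1L) == 1L) r <- bitwXor(r, a)
    a <- bitwShiftL(a, 1L)
    b <- bitwShiftR(b, 1L)
  }
  r
}

gf2_degree <- function(p) {
  d <- -1L
  while (p > 0) { p <- bitwShiftR(p, 1L); d <- d + 1L }
  d
}

# reduce polynomial a modulo p
gf2_mod <- function(a, p) {
  dp <- gf2_degree(p)
  da <- gf2_degree(a)
  while (da >= dp) {
    a <- bitwXor(a, bitwShiftL(p, da - dp))
    da <- gf2_degree(a)
  }
  a
}

gf2_mulmod <- function(a, b, p) gf2_mod(gf2_mul(a, b), p)

gf2_powmod <- function(a, e, p) {
  r <- 1L
  while (e > 0) {
    if (e %% 2 == 1) r <- gf2_mulmod(r, a, p)
    a <- gf2_mulmod(a, a, p)
    e <- e %/% 2
  }
  r
}

prime_factors <- function(n) {
  f <- integer(0)
  d <- 2
  while (d * d <= n) {
    while (n %% d == 0) { f <- c(f, d); n <- n %/% d }
    d <- d + 1
  }
  if (n > 1) f <- c(f, n)
  unique(f)
}

# is the degree-d polynomial p primitive over GF(2)?
is_primitive_poly <- function(p) {
  d <- gf2_degree(p)
  if (bitwAnd(p, 1L) != 1L) return(FALSE) # constant term required
  r <- 2^d - 1
  if (gf2_powmod(2L, r, p) != 1L) return(FALSE)
  for (q in prime_factors(r)) {
    if (gf2_powmod(2L, r %/% q, p) == 1L) return(FALSE)
  }
  TRUE
}

# first n primitive polynomials, ordered by degree then value
primitive_polys <- function(n) {
  out <- integer(0)
  d <- 1L
  while (length(out) < n) {
    lo <- bitwShiftL(1L, d)
    for (p in seq(lo + 1L, 2L * lo - 1L, by = 2L)) {
      if (is_primitive_poly(p)) {
        out <- c(out, p)
        if (length(out) >= n) break
      }
    }
    d <- d + 1L
  }
  out
}

# direction integers V[k] (scaled by 2^(SOBOL_NBITS - k)) for `dim` dimensions
sobol_directions <- function(dim) {
  nb <- SOBOL_NBITS
  V <- matrix(0L, nb, dim)
  # dimension 1: van der Corput, m_k = 1
  V[, 1] <- bitwShiftL(1L, nb - seq_len(nb))
  if (dim > 1) {
    polys <- primitive_polys(dim - 1)
    for (j in 2:dim) {
      p <- polys[j - 1]
      s <- gf2_degree(p)
      # coefficient bits a_1..a_{s-1} of p = x^s + a_1 x^{s-1} + ... + 1
      a <- integer(max(s - 1, 0))
      for (t in seq_len(s - 1)) {
        a[t] <- bitwAnd(bitwShiftR(p, s - t), 1L)
      }
      m <- rep(1L, nb) # unit initialisation (all m_i odd, < 2^i)
      if (nb > s) {
        for (k in (s + 1):nb) {
          val <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
          for (t in seq_len(s - 1)) {
            if (a[t] == 1L) val <- bitwXor(val, bitwShiftL(m[k - t], t))
          }
          m[k] <- val
        }
      }
      V[, j] <- bitwShiftL(m, nb - seq_len(nb))
    }
  }
  V
}

#' Sobol' point at an absolute index
#'
#' Deterministic: the same index always yields the same point, independent of
#' any previously generated points.
#' @param index nonnegative integer index (index 0 is the origin)
#' @param dim dimension
#' @param directions optional precomputed direction matrix (from repeated
#'   calls, see [sobol_sequence()])
#' @return numeric vector in [0, 1)^dim
#' @export
sobol_point <- function(index, dim, directions = NULL) {
  if (is.null(directions)) directions <- sobol_directions(dim)
  g <- bitwXor(as.integer(index), bitwShiftR(as.integer(index), 1L))
  x <- integer(dim)
  k <- 1L
  while (g > 0) {
    if (bitwAnd(g, 1L) == 1L) x <- bitwXor(x, directions[k, ])
    g <- bitwShiftR(g, 1L)
    k <- k + 1L
  }
  x / 2^SOBOL_NBITS
}

#' Sobol' sequence
#' @param n number of points
#' @param dim dimension
#' @param offset index of the first point (default 0)
#' @return n x dim matrix of points in [0, 1)
#' @examples
#' head(sobol_sequence(8, 2))
#' @export
sobol_sequence <- function(n, dim, offset = 0) {
  V <- sobol_directions(dim)
  t(vapply(seq_len(n) - 1 + offset, sobol_point, numeric(dim),
           dim = dim, directions = V))
}
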