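# Sobol low-discrepancy sequence, Gray-code construction with Joe-Kuo
# direction numbers for up to 6 dimensions (dimension 1 is the van der
# Corput sequence in base 2). 30-bit precision.

.sobol_dirdata <- list(
  list(s = 1L, a = 0L, m = c(1L)),          # dimension 2
  list(s = 2L, a = 1L, m = c(1L, 3L)),      # dimension 3
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),  # dimension 4
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),  # dimension 5
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L))  # dimension 6
)

.sobol_maxbit <- 30L

# direction integers V_1..V_nbits for one dimension (scaled by 2^30)
.sobol_directions <- function(dim, nbits) {
  if (dim == 1L) return(bitwShiftL(1L, .sobol_maxbit - seq_len(nbits)))
  dd <- .sobol_dirdata[[dim - 1L]]
  s <- dd$s; a <- dd$a; m <- dd$m
  v <- integer(nbits)
  for (j in seq_len(min(s, nbits)))
    v[j] <- bitwShiftL(m[j], .sobol_maxbit - j)
  if (nbits > s) {
    for (j in (s + 1L):nbits) {
      val <- bitwXor(v[j - s], bitwShiftR(v[j - s], s))
      if (s > 1L) for (k in seq_len(s - 1L))
        if (bitwAnd(bitwShiftR(a, s - 1L - k), 1L) == 1L)
          val <- bitwXor(val, v[j - k])
      v[j] <- val
    }
  }
  v
}

# first n points (indices 1..n, origin skipped) of the d-dimensional
# Sobol sequence, rows in sequence order
sobol_points <- function(n, d) {
  stopifnot(n >= 1, d >= 1, d <= length(.sobol_dirdata) + 1L)
  nbits <- max(1L, ceiling(log2(n + 1)))
  vs <- lapply(seq_len(d), .sobol_directions, nbits = nbits)
  x <- integer(d)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    c_bit <- 1L
    ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c_bit <- c_bit + 1L }
    for (k in seq_len(d)) x[k] <- bitwXor(x[k], vs[[k]][c_bit])
    out[i, ] <- x / 2^.sobol_maxbit
  }
  out
}

#' Sobol initialization of the support grid
#'
#' Places `n` quasi-random support points inside the parameter bounds by
#' mapping a Sobol sequence (origin skipped) from the unit hypercube onto
#' the bounds box. Deterministic for fixed `n` and `bounds`.
#'
#' @param bounds A [param_bounds()] object.
#' @param n Number of support points (default 51).
#' @return A numeric matrix with `n` rows and one named column per
#'   parameter; every point lies inside the bounds.
#' @export
sobol_init <- function(bounds, n = 51L) {
  stopifnot(inherits(bounds, "param_bounds"), n >= 1)
  m <- bounds_matrix(bounds)
  d <- ncol(m)
  u <- sobol_points(n, d)
  pts <- sweep(sweep(u, 2, m["upper", ] - m["lower", ], "*"), 2,
               m["lower", ], "+")
  colnames(pts) <- colnames(m)
  pts
}
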