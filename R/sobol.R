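# Sobol low-discrepancy sequence (Gray-code construction) with Joe-Kuo
# direction numbers for dimensions 1-10. Dimension 1 is the van der Corput
# sequence in base 2. Quasi-Monte-Carlo integration over the random-effect
# distribution is the backbone of the FOCE- and MC-aggregate approximations,
# so the generator is part of the package rather than a dependency.
.sobol_dirs <- list(
  list(s = 0L, a = 0L, m = integer(0)),
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L, m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L, m = c(1L, 1L, 7L, 11L, 19L))
)

#' Sobol sequence points
#'
#' Deterministic low-discrepancy points in (0, 1)^d. The initial all-zero
#' point of the sequence is skipped by default (its inverse-normal image is
#' undefined), so `sobol_points(n, d)` returns sequence elements 1..n.
#'
#' @param n Number of points.
#' @param d Dimension, 1 to 10.
#' @param skip_zero Drop the leading all-zero point (default TRUE).
#' @return An n x d matrix of points in `[0, 1)^d`.
#' @export
sobol_points <- function(n, d, skip_zero = TRUE) {
  n <- as.integer(n); d <- as.integer(d)
  if (d < 1 || d > length(.sobol_dirs))
    stop("sobol_points supports dimensions 1 to ", length(.sobol_dirs))
  if (n < 1) stop("n must be >= 1")
  nb <- 30L                      # bits; n + 1 must stay below 2^nb
  ntot <- if (skip_zero) n + 1L else n
  if (ntot > bitwShiftL(1L, nb)) stop("n too large for the bit budget")
  P <- matrix(0, ntot, d)
  for (j in seq_len(d)) {
    dd <- .sobol_dirs[[j]]
    V <- integer(nb)
    if (j == 1L) {
      for (i in 1:nb) V[i] <- bitwShiftL(1L, nb - i)
    } else {
      s <- dd$s; a <- dd$a
      for (i in 1:s) V[i] <- bitwShiftL(dd$m[i], nb - i)
      if (s < nb) for (i in (s + 1L):nb) {
        V[i] <- bitwXor(V[i - s], bitwShiftR(V[i - s], s))
        if (s > 1L) for (k in 1:(s - 1L))
          if (bitwAnd(bitwShiftR(a, s - 1L - k), 1L) == 1L)
            V[i] <- bitwXor(V[i], V[i - k])
      }
    }
    x <- 0L
    if (ntot > 1L) for (i in seq_len(ntot - 1L)) {
      # Gray-code update: flip the direction of the lowest zero bit of i-1
      c <- 0L; ii <- i - 1L
      while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c <- c + 1L }
      x <- bitwXor(x, V[c + 1L])
      P[i + 1L, j] <- x / 2^nb
    }
  }
  if (skip_zero) P[-1L, , drop = FALSE] else P
}
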