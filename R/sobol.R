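## Sobol low-discrepancy sequences (Gray-code construction), dimensions 1-40.
## Direction numbers are the published Joe & Kuo (2008) "new-joe-kuo-6"
## primitive polynomials and initial values; each row below is
## "s a m1 ... ms" for one dimension (dimension 1 is the degenerate
## van der Corput case handled explicitly).
sobol_dirs <- list(
  c(1, 0, 1),
  c(1, 0, 1),
  c(2, 1, 1, 3),
  c(3, 1, 1, 3, 1),
  c(3, 2, 1, 1, 1),
  c(4, 1, 1, 1, 3, 3),
  c(4, 4, 1, 3, 5, 13),
  c(5, 2, 1, 1, 5, 5, 17),
  c(5, 4, 1, 1, 5, 5, 5),
  c(5, 7, 1, 1, 7, 11, 19),
  c(5, 11, 1, 1, 5, 1, 1),
  c(5, 13, 1, 1, 1, 3, 11),
  c(5, 14, 1, 3, 5, 5, 31),
  c(6, 1, 1, 3, 3, 9, 7, 49),
  c(6, 13, 1, 1, 1, 15, 21, 21),
  c(6, 16, 1, 3, 1, 13, 27, 49),
  c(6, 19, 1, 1, 1, 15, 7, 5),
  c(6, 22, 1, 3, 1, 15, 13, 25),
  c(6, 25, 1, 1, 5, 5, 19, 61),
  c(7, 1, 1, 3, 7, 11, 23, 15, 103),
  c(7, 4, 1, 3, 7, 13, 13, 15, 69),
  c(7, 7, 1, 1, 3, 13, 7, 35, 63),
  c(7, 8, 1, 3, 5, 9, 1, 25, 53),
  c(7, 14, 1, 3, 1, 13, 9, 35, 107),
  c(7, 19, 1, 3, 1, 5, 27, 61, 31),
  c(7, 21, 1, 1, 5, 11, 19, 41, 61),
  c(7, 28, 1, 3, 5, 3, 3, 13, 69),
  c(7, 31, 1, 1, 7, 13, 1, 19, 1),
  c(7, 32, 1, 3, 7, 5, 13, 19, 59),
  c(7, 37, 1, 1, 3, 9, 25, 29, 41),
  c(7, 41, 1, 3, 5, 13, 23, 1, 55),
  c(7, 42, 1, 3, 7, 3, 13, 59, 17),
  c(7, 50, 1, 3, 1, 3, 5, 53, 69),
  c(7, 55, 1, 1, 5, 5, 23, 33, 13),
  c(7, 56, 1, 1, 7, 7, 1, 61, 123),
  c(7, 59, 1, 1, 7, 9, 13, 61, 49),
  c(7, 62, 1, 3, 3, 5, 3, 55, 33),
  c(8, 14, 1, 3, 1, 15, 31, 13, 49, 245),
  c(8, 21, 1, 3, 5, 15, 31, 59, 63, 97),
  c(8, 22, 1, 3, 1, 11, 11, 11, 77, 249)
)

sobol_maxbit <- 30L

## per-dimension direction integers v[1..maxbit], scaled by 2^maxbit
sobol_directions <- function(j) {
  v <- integer(sobol_maxbit)
  if (j == 1) {
    for (k in seq_len(sobol_maxbit)) v[k] <- bitwShiftL(1L, sobol_maxbit - k)
    return(v)
  }
  row <- sobol_dirs[[j]]
  s <- row[1]; a <- row[2]; m <- row[-(1:2)]
  for (k in seq_len(min(s, sobol_maxbit)))
    v[k] <- bitwShiftL(as.integer(m[k]), sobol_maxbit - k)
  if (sobol_maxbit > s) {
    abits <- as.integer(intToBits(a))[seq_len(max(s - 1, 1))]  # a_1 = LSB-first
    for (k in (s + 1):sobol_maxbit) {
      vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
      if (s > 1) for (i in seq_len(s - 1))
        if (abits[s - i]) vk <- bitwXor(vk, v[k - i])
      v[k] <- vk
    }
  }
  v
}

#' Sobol quasi-random sequence
#'
#' First `n` points of the `d`-dimensional Sobol sequence in the unit cube
#' (Gray-code order, first point at the origin), optionally randomized by a
#' per-dimension digital shift. Space-filling with low discrepancy; used for
#' virtual-patient cohort designs and multi-start optimization.
#'
#' @param n Number of points.
#' @param d Dimension (1-40).
#' @param scramble Apply a random digital shift (`seed`-determined).
#' @param seed Integer seed for the digital shift; ignored unless
#'   `scramble = TRUE`.
#' @param skip Number of initial points to skip.
#' @return `n` x `d` matrix with entries in \[0, 1).
#' @export
sobol_seq <- function(n, d, scramble = FALSE, seed = NULL, skip = 0) {
  if (d < 1 || d > length(sobol_dirs))
    stop("dimension must be between 1 and ", length(sobol_dirs))
  if (n < 1) stop("n must be >= 1")
  V <- vapply(seq_len(d), sobol_directions, integer(sobol_maxbit))
  total <- n + skip
  X <- matrix(0L, nrow = total, ncol = d)
  x <- integer(d)
  if (total > 1) {
    for (i in 2:total) {
      ## rightmost zero bit of (i - 2): Gray-code increment
      c <- 1L; m <- i - 2L
      while (bitwAnd(m, 1L) == 1L) { m <- bitwShiftR(m, 1L); c <- c + 1L }
      x <- bitwXor(x, V[c, ])
      X[i, ] <- x
    }
  }
  if (skip > 0) X <- X[-seq_len(skip), , drop = FALSE]
  if (scramble) {
    if (is.null(seed)) stop("scrambling requires a seed")
    shift <- with_seed(seed, sample.int(2^sobol_maxbit, d, replace = TRUE) - 1L)
    X <- sweep(X, 2, shift, bitwXor)
  }
  X / 2^sobol_maxbit
}

## evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  expr
}
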