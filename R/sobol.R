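## Unscrambled Sobol low-discrepancy sequence (Gray-code construction) with
## the published Joe-Kuo direction numbers for dimensions up to 20.  The
## sequence is fully deterministic: identical (n, dim, skip) always yields
## the identical point set, which is what makes every quasi-Monte-Carlo
## campaign in this package reproducible without any RNG.

## Joe-Kuo primitive polynomial degree s, coefficient bits a, and initial
## direction numbers m for dimensions 2..20 (dimension 1 is the van der
## Corput sequence in base 2).
.sobol_table <- list(
  list(s = 1, a = 0,  m = 1),
  list(s = 2, a = 1,  m = c(1, 3)),
  list(s = 3, a = 1,  m = c(1, 3, 1)),
  list(s = 3, a = 2,  m = c(1, 1, 1)),
  list(s = 4, a = 1,  m = c(1, 1, 3, 3)),
  list(s = 4, a = 4,  m = c(1, 3, 5, 13)),
  list(s = 5, a = 2,  m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4,  m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7,  m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
  list(s = 6, a = 1,  m = c(1, 3, 3, 9, 7, 49)),
  list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49)),
  list(s = 6, a = 19, m = c(1, 1, 1, 15, 7, 5)),
  list(s = 6, a = 22, m = c(1, 3, 1, 15, 13, 25)),
  list(s = 6, a = 25, m = c(1, 1, 5, 5, 19, 61)),
  list(s = 7, a = 1,  m = c(1, 3, 7, 11, 23, 15, 103)))

.sobol_nbits <- 31L

## direction-integer matrix (nbits x dim)
.sobol_directions <- function(dim) {
  L <- .sobol_nbits
  V <- matrix(0L, nrow = L, ncol = dim)
  ## dimension 1: van der Corput
  V[, 1] <- bitwShiftL(1L, L - seq_len(L))
  for (j in seq_len(dim - 1)) {
    tb <- .sobol_table[[j]]
    s <- tb$s; a <- tb$a; m <- tb$m
    v <- integer(L)
    v[seq_len(min(s, L))] <- bitwShiftL(as.integer(m[seq_len(min(s, L))]),
                                        L - seq_len(min(s, L)))
    if (L > s) {
      for (k in (s + 1):L) {
        v[k] <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
        if (s > 1) for (i in seq_len(s - 1)) {
          if (bitwAnd(bitwShiftR(a, s - 1 - i), 1L) == 1L)
            v[k] <- bitwXor(v[k], v[k - i])
        }
      }
    }
    V[, j + 1] <- v
  }
  V
}

#' Sobol low-discrepancy points
#'
#' Generates `n` points of the unscrambled Sobol sequence (Joe-Kuo
#' direction numbers, Gray-code order, the origin included as the first
#' point) in the unit hypercube, optionally skipping an initial segment and
#' optionally mapped affinely onto a [parameter_space()]'s bounds.
#'
#' @param n number of points (>= 1).
#' @param dim dimension (1..20), or inferred from `space`.
#' @param skip number of initial points to discard.
#' @param space optional `cc_space`; points are mapped onto its bounds and
#'   columns are named by its symbols.
#' @return an `n x dim` numeric matrix.
#' @export
#' @examples
#' sobol_points(8, dim = 2)
sobol_points <- function(n, dim = NULL, skip = 0, space = NULL) {
  if (!is.null(space)) {
    stopifnot(inherits(space, "cc_space"))
    dim <- space$dim
  }
  stopifnot(n >= 1, !is.null(dim), dim >= 1)
  if (dim > length(.sobol_table) + 1)
    stop("Sobol direction numbers available up to dimension ",
         length(.sobol_table) + 1)
  V <- .sobol_directions(dim)
  total <- n + skip
  pts <- matrix(0, nrow = total, ncol = dim)
  x <- integer(dim)
  if (total > 1) {
    for (i in seq_len(total - 1)) {
      ## direction index = trailing-zero count of i (1-based)
      c <- 1L
      ii <- i
      while (bitwAnd(ii, 1L) == 0L) { ii <- bitwShiftR(ii, 1L); c <- c + 1L }
      x <- bitwXor(x, V[c, ])
      pts[i + 1L, ] <- x
    }
  }
  pts <- pts[(skip + 1):total, , drop = FALSE] / 2^.sobol_nbits
  if (!is.null(space)) {
    pts <- sweep(pts, 2, space$upper - space$lower, `*`)
    pts <- sweep(pts, 2, space$lower, `+`)
    colnames(pts) <- space$symbols
  }
  pts
}

#' Parameter hypercube for sensitivity and campaign studies
#'
#' Defines the sampling space over a subset of model parameters: bounds are
#' `[0, 2 * nominal]` per symbol (a +/- 100% relative range around the
#' nominal value).  The default subset is the eight screened parameters
#' P1-P8: `b1`, `k'13`, `m13`, `k8`, `g_Rb`, `m_E2F-RbP`, `d_cycE-p/p`
#' and `epsilon`.
#'
#' @param p a `cc_params` object supplying the nominal values.
#' @param symbols character vector of parameter symbols.
#' @return a `cc_space`: list with `symbols`, `nominal`, `lower`, `upper`,
#'   `dim`.
#' @export
parameter_space <- function(p, symbols = dgsm_default_symbols()) {
  stopifnot(inherits(p, "cc_params"))
  nominal <- cc_get(p, symbols)
  if (any(nominal == 0))
    stop("multiplicative +/-100% bounds are undefined for zero-valued ",
         "parameter(s): ",
         paste(symbols[nominal == 0], collapse = ", "))
  structure(list(symbols = symbols, nominal = unname(nominal),
                 lower = rep(0, length(symbols)),
                 upper = 2 * unname(nominal),
                 dim = length(symbols)),
            class = "cc_space")
}

#' The eight parameters screened for global sensitivity (P1-P8)
#'
#' @return character vector of parameter symbols.
#' @export
dgsm_default_symbols <- function() {
  c("b1", "k'13", "m13", "k8", "g_Rb", "m_E2F-RbP", "d_cycE-p/p", "epsilon")
}

#' @export
print.cc_space <- function(x, ...) {
  cat(sprintf("cc_space: %d-dimensional parameter hypercube\n", x$dim))
  for (j in seq_len(x$dim))
    cat(sprintf("  %-12s nominal %.4g, bounds [0, %.4g]\n",
                x$symbols[j], x$nominal[j], x$upper[j]))
  invisible(x)
}
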