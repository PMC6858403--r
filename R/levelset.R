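## 1-D squared distance transform (lower envelope of parabolas).
## f is the per-cell source cost; returns min_q (i - q)^2 + f[q].
.dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)
  zb <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  zb[1L] <- -Inf
  zb[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s > zb[k]) break
      k <- k - 1L
    }
    k <- k + 1L
    v[k] <- q
    zb[k] <- s
    zb[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (zb[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

## Exact squared Euclidean distance to the nearest TRUE cell.
.edt2 <- function(sites) {
  m <- nrow(sites); n <- ncol(sites)
  big <- (m * m + n * n) * 4
  f <- matrix(big, m, n)
  f[sites] <- 0
  for (j in seq_len(n)) f[, j] <- .dt1d(f[, j])
  for (i in seq_len(m)) f[i, ] <- .dt1d(f[i, ])
  f
}

#' Signed Euclidean distance function of a binary mask
#'
#' Positive inside the mask, negative outside; the zero crossing lies on the
#' mask boundary (a half-pixel offset centres it between the innermost
#' foreground and outermost background pixels).
#'
#' @param mask Logical matrix (TRUE = target).
#' @return Numeric matrix of signed distances in pixels.
#' @export
sdf_from_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  storage.mode(mask) <- "logical"
  stopifnot(!anyNA(mask))
  d_out <- sqrt(.edt2(!mask))  # distance to nearest background pixel
  d_in <- sqrt(.edt2(mask))    # distance to nearest foreground pixel
  ifelse(mask, d_out - 0.5, -(d_in - 0.5))
}

#' Initialize a level set from a binary mask
#'
#' @param mask Logical matrix marking the target region; must be non-empty
#'   and must not cover the whole frame.
#' @param th Background band threshold in pixels: the band is
#'   \eqn{-th < \phi < 0}.
#' @return Object of class \code{"level_set"}: list with \code{phi} (signed
#'   distance grid) and \code{th}.
#' @export
init_level_set <- function(mask, th = 10) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("empty mask")
  if (all(mask)) stop("mask covers the whole frame")
  stopifnot(th > 0)
  structure(list(phi = sdf_from_mask(mask), th = th), class = "level_set")
}

#' @export
print.level_set <- function(x, ...) {
  cat(sprintf("level set: %d x %d grid, %d foreground px, band th = %g px\n",
              nrow(x$phi), ncol(x$phi), sum(x$phi >= 0), x$th))
  invisible(x)
}

#' Regularized Heaviside and Dirac functions
#'
#' \eqn{H_\epsilon(\phi) = \tfrac12(1 + \tfrac{2}{\pi}\arctan(\phi/\epsilon))}
#' and its derivative
#' \eqn{\delta_\epsilon(\phi) = \epsilon / (\pi(\epsilon^2 + \phi^2))}.
#'
#' @param phi Numeric vector or matrix.
#' @param eps Regularization width in pixels (> 0).
#' @return Same shape as \code{phi}.
#' @export
heaviside_eps <- function(phi, eps = 1.5) {
  stopifnot(eps > 0)
  0.5 * (1 + (2 / pi) * atan(phi / eps))
}

#' @rdname heaviside_eps
#' @export
dirac_eps <- function(phi, eps = 1.5) {
  stopifnot(eps > 0)
  eps / (pi * (eps^2 + phi^2))
}
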