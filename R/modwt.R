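#' Orthonormal wavelet filter coefficients
#'
#' Returns the unit-energy scaling (low-pass) and wavelet (high-pass) filter
#' pair for the supported families.  The wavelet filter is the quadrature
#' mirror of the scaling filter, \eqn{h_k = (-1)^k g_{L-1-k}}.
#'
#' @param name Wavelet identifier, one of \code{"haar"} or \code{"db4"}
#'   (Daubechies, four vanishing moments, eight taps).
#' @return A list with components \code{g} (scaling) and \code{h} (wavelet),
#'   each a numeric vector with \eqn{\sum g_k^2 = 1}.
#' @export
wavelet_filters <- function(name = c("haar", "db4")) {
  name <- match.arg(name)
  g <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db4 = c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278))
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1) * rev(g)
  list(g = g, h = h, name = name)
}

## Circular filtering along one array dimension with an upsampled filter.
## Forward: y[t] = sum_k f[k] x[t - k*step]  (indices mod extent)
## Adjoint: y[t] = sum_k f[k] x[t + k*step]
.circ_filter <- function(x, f, step, margin, adjoint = FALSE) {
  n <- dim(x)[margin]
  y <- matrix(0, nrow(x), ncol(x))
  sgn <- if (adjoint) 1L else -1L
  for (k in seq_along(f)) {
    s <- sgn * (k - 1L) * step
    idx <- ((seq_len(n) - 1L + s) %% n) + 1L
    y <- y + f[k] * (if (margin == 1L) x[idx, , drop = FALSE]
                     else x[, idx, drop = FALSE])
  }
  y
}

.check_levels <- function(dim_min, L, levels) {
  span <- (L - 1L) * 2^(levels - 1L) + 1L
  if (span > dim_min)
    stop("levels = ", levels, " exceeds what a ", dim_min,
         "-pixel grid supports for this wavelet (filter span ", span, ")")
  invisible(span)
}

#' Two-dimensional maximal-overlap discrete wavelet transform
#'
#' Undecimated, shift-equivariant transform with circular boundary handling.
#' At each level the orthonormal filters are rescaled by \eqn{1/\sqrt 2} and
#' upsampled by \eqn{2^{l-1}}; every coefficient grid keeps the input size.
#' Detail orientation codes: \code{H} = high-pass along x (columns),
#' \code{V} = high-pass along y (rows), \code{D} = high-pass along both.
#'
#' @param frame Numeric matrix (M x N), M and N at least 8.
#' @param wavelet Wavelet family, see [wavelet_filters()].
#' @param levels Number of decomposition levels \eqn{l_0 \ge 1}.
#' @return An object of class \code{"modwt2d"}: list with \code{approx}
#'   (M x N matrix at the deepest level), \code{details} (list of
#'   \code{levels} lists with matrices \code{H}, \code{V}, \code{D}),
#'   \code{wavelet}, \code{levels}.
#' @seealso [modwt_inverse()]
#' @export
modwt_forward <- function(frame, wavelet = "haar", levels = 2L) {
  stopifnot(is.matrix(frame), is.numeric(frame), all(is.finite(frame)))
  if (nrow(frame) < 8L || ncol(frame) < 8L)
    stop("frame must be at least 8 x 8")
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  filt <- wavelet_filters(wavelet)
  .check_levels(min(dim(frame)), length(filt$g), levels)
  g <- filt$g / sqrt(2)
  h <- filt$h / sqrt(2)
  v <- frame
  details <- vector("list", levels)
  for (l in seq_len(levels)) {
    step <- 2L^(l - 1L)
    lo_x <- .circ_filter(v, g, step, 2L)
    hi_x <- .circ_filter(v, h, step, 2L)
    details[[l]] <- list(H = .circ_filter(hi_x, g, step, 1L),
                         V = .circ_filter(lo_x, h, step, 1L),
                         D = .circ_filter(hi_x, h, step, 1L))
    v <- .circ_filter(lo_x, g, step, 1L)
  }
  structure(list(approx = v, details = details,
                 wavelet = filt$name, levels = levels),
            class = "modwt2d")
}

#' Inverse two-dimensional MODWT
#'
#' Exact inverse of [modwt_forward()] (perfect reconstruction to floating
#' tolerance), built from the adjoint circular filters level by level.
#'
#' @param pyramid A \code{"modwt2d"} object.
#' @return Numeric matrix with the dimensions of the coefficient grids.
#' @export
modwt_inverse <- function(pyramid) {
  stopifnot(inherits(pyramid, "modwt2d"))
  filt <- wavelet_filters(pyramid$wavelet)
  g <- filt$g / sqrt(2)
  h <- filt$h / sqrt(2)
  v <- pyramid$approx
  dm <- dim(v)
  for (l in rev(seq_len(pyramid$levels))) {
    d <- pyramid$details[[l]]
    if (!all(vapply(d, function(m) identical(dim(m), dm), logical(1))))
      stop("detail grid shape mismatch at level ", l)
    step <- 2L^(l - 1L)
    lo_x <- .circ_filter(v,    g, step, 1L, adjoint = TRUE) +
            .circ_filter(d$V,  h, step, 1L, adjoint = TRUE)
    hi_x <- .circ_filter(d$H,  g, step, 1L, adjoint = TRUE) +
            .circ_filter(d$D,  h, step, 1L, adjoint = TRUE)
    v <- .circ_filter(lo_x, g, step, 2L, adjoint = TRUE) +
         .circ_filter(hi_x, h, step, 2L, adjoint = TRUE)
  }
  v
}

#' @export
print.modwt2d <- function(x, ...) {
  cat("2-D MODWT pyramid:", x$wavelet, "wavelet,", x$levels, "level(s),",
      paste(dim(x$approx), collapse = " x "), "grids\n")
  invisible(x)
}
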