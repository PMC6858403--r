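## Map intensities to histogram bins.  Uniform bins on [0, 1] unless
## explicit edges are supplied; values are clamped to the edge range.
.bin_index <- function(values, r, edges = NULL) {
  if (is.null(edges)) edges <- seq(0, 1, length.out = r + 1L)
  stopifnot(length(edges) == r + 1L)
  findInterval(values, edges, all.inside = TRUE)
}

#' Foreground and background histogram models
#'
#' Builds the r-bin intensity histogram of the foreground
#' (\eqn{\phi \ge 0}) and of the background band (\eqn{-th < \phi < 0}) on
#' the model frame, each normalized to unit mass (Kronecker-delta binning).
#'
#' @param frame Numeric matrix in [0, 1].
#' @param ls A [init_level_set()] object on the same grid.
#' @param r Number of bins (>= 2).
#' @param edges Optional r+1 bin edges on [0, 1]; uniform when NULL.
#' @return Object of class \code{"region_models"}: list with \code{fd},
#'   \code{bd} (probability vectors), \code{r}, \code{edges}.
#' @export
build_models <- function(frame, ls, r = 32L, edges = NULL) {
  stopifnot(inherits(ls, "level_set"), identical(dim(frame), dim(ls$phi)))
  r <- as.integer(r)
  if (r < 2L) stop("r must be >= 2")
  if (is.null(edges)) edges <- seq(0, 1, length.out = r + 1L)
  fg_px <- ls$phi >= 0
  bd_px <- ls$phi > -ls$th & ls$phi < 0
  if (!any(fg_px)) stop("empty foreground region")
  if (!any(bd_px)) stop("empty background band")
  bins <- .bin_index(frame, r, edges)
  fd <- tabulate(bins[fg_px], nbins = r)
  bd <- tabulate(bins[bd_px], nbins = r)
  structure(list(fd = fd / sum(fd), bd = bd / sum(bd),
                 r = r, edges = edges),
            class = "region_models")
}

#' Heaviside-weighted candidate-region distributions
#'
#' Soft foreground/background histograms of the candidate region: the
#' foreground distribution weights each near-foreground pixel
#' (\eqn{\phi > -2\epsilon}, the Heaviside transition zone) by
#' \eqn{H_\epsilon(\phi)}; the background distribution weights band pixels
#' (\eqn{-th < \phi < 0}) by \eqn{1 - H_\epsilon(\phi)}.  \code{Ff} and
#' \code{Fb} are the respective total weights, so each distribution sums
#' to one.  Truncating the foreground domain keeps the slowly decaying
#' arctan tails from leaking background mass into the foreground
#' histogram.
#'
#' @inheritParams build_models
#' @param eps Heaviside regularization width (px).
#' @return Object of class \code{"region_dist"}: list with \code{fg},
#'   \code{bg}, \code{Ff}, \code{Fb}, \code{r}, \code{edges}.
#' @export
region_distributions <- function(frame, ls, r = 32L, eps = 1.5,
                                 edges = NULL) {
  stopifnot(inherits(ls, "level_set"), identical(dim(frame), dim(ls$phi)))
  r <- as.integer(r)
  if (r < 2L) stop("r must be >= 2")
  if (is.null(edges)) edges <- seq(0, 1, length.out = r + 1L)
  phi <- ls$phi
  band <- phi > -ls$th & phi < 0
  H <- heaviside_eps(phi, eps)
  wf <- ifelse(phi > -2 * eps, H, 0)
  wb <- ifelse(band, 1 - H, 0)
  Ff <- sum(wf); Fb <- sum(wb)
  if (Ff < 1e-12 || Fb < 1e-12)
    stop("degenerate candidate region (Ff or Fb below 1e-12)")
  bins <- .bin_index(frame, r, edges)
  fg <- bg <- numeric(r)
  sf <- rowsum(c(wf), bins)
  sb <- rowsum(c(wb), bins)
  fg[as.integer(rownames(sf))] <- sf
  bg[as.integer(rownames(sb))] <- sb
  structure(list(fg = fg / Ff, bg = bg / Fb, Ff = Ff, Fb = Fb,
                 r = r, edges = edges),
            class = "region_dist")
}

#' Bhattacharyya matching energy
#'
#' \deqn{En_1 = \sum_{fs} \left(\sqrt{fg \cdot fd} +
#'   \gamma \sqrt{bg \cdot bd}\right)}
#' maximal (\eqn{1 + \gamma}) when the candidate distributions equal the
#' models.
#'
#' @param dist A [region_distributions()] object.
#' @param models A [build_models()] object of the same bin count.
#' @param gamma Background weight (>= 0).
#' @return Scalar energy in \eqn{[0, 1 + \gamma]}.
#' @export
bhattacharyya_energy <- function(dist, models, gamma = 0.5) {
  stopifnot(gamma >= 0)
  if (length(dist$fg) != length(models$fd))
    stop("bin count mismatch between distributions and models")
  sum(sqrt(dist$fg * models$fd)) + gamma * sum(sqrt(dist$bg * models$bd))
}

#' Per-pixel Bhattacharyya weights
#'
#' Taylor-expansion weights for registration and contour refinement:
#' \eqn{h_f(x) = \sqrt{fd_{b(x)} / fg_{b(x)}(\phi_0)}} and
#' \eqn{h_b(x) = \sqrt{bd_{b(x)} / bg_{b(x)}(\phi_0)}}, evaluated at the
#' bin of each pixel of the current frame.  Bins with a zero denominator
#' (or zero model mass) carry no gradient information and get weight 0.
#'
#' @param frame Current frame (numeric matrix).
#' @param models First-frame [build_models()] object.
#' @param dist0 [region_distributions()] at the initial pose \eqn{\phi_0}.
#' @return List with weight grids \code{h_f}, \code{h_b} and the
#'   normalization masses \code{Ff}, \code{Fb} of \code{dist0}.
#' @export
pixel_weights <- function(frame, models, dist0) {
  stopifnot(inherits(models, "region_models"), inherits(dist0, "region_dist"),
            models$r == dist0$r)
  ratio <- function(num, den) {
    out <- numeric(length(num))
    ok <- den > 0 & num > 0
    out[ok] <- sqrt(num[ok] / den[ok])
    out
  }
  rf <- ratio(models$fd, dist0$fg)
  rb <- ratio(models$bd, dist0$bg)
  bins <- .bin_index(frame, models$r, models$edges)
  h_f <- matrix(rf[bins], nrow(frame))
  h_b <- matrix(rb[bins], nrow(frame))
  list(h_f = h_f, h_b = h_b, Ff = dist0$Ff, Fb = dist0$Fb)
}
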