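#' Specification of a synthetic ground-truthed sequence
#'
#' Describes a piecewise-intensity target moving over a textured background
#' with additive zero-mean Gaussian noise, optional smooth illumination
#' drift and an optional partial occluder.  Frames emulate low/high
#' contrast grayscale medical video at desk scale; intensities live on
#' [0, 1] and are clipped after noise.
#'
#' @param size Frame size \code{c(M, N)} (rows, cols).
#' @param shape Target shape: \code{"square"}, \code{"disk"} or
#'   \code{"tool_polygon"} (an elongated rotated rectangle with a wedge
#'   tip, emulating a scissors/clipper silhouette).
#' @param center Initial target centre \code{c(x, y)}, 0-based pixel units.
#' @param radius Target half-size in px (disk radius, square half-side, or
#'   tool half-length).
#' @param fg,bg Foreground and background intensity levels.
#' @param texture_amp Amplitude of the smooth background texture.
#' @param vx,vy Per-frame translation (px/frame).
#' @param scale_step Per-frame multiplicative scale of the target (1 =
#'   rigid).
#' @param rot_step Per-frame rotation (radians/frame, tool shape only).
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param illum_drift Amplitude of a smooth sinusoidal illumination ramp
#'   added across the frame over time (0 disables).
#' @param occluder Optional list \code{list(x, y, w, h, value, frames)}:
#'   a rectangle drawn over the listed frames (not part of ground truth).
#' @param n_frames Number of frames (>= 1).
#' @param seed RNG seed making the sequence reproducible.
#' @return Object of class \code{"sequence_spec"}.
#' @export
sequence_spec <- function(size = c(64L, 64L), shape = "square",
                          center = NULL, radius = 10, fg = 0.8, bg = 0.35,
                          texture_amp = 0.05, vx = 2, vy = 0,
                          scale_step = 1, rot_step = 0,
                          noise_sigma = 0.05, illum_drift = 0,
                          occluder = NULL, n_frames = 20L, seed = 1L) {
  shape <- match.arg(shape, c("square", "disk", "tool_polygon"))
  size <- as.integer(size)
  stopifnot(length(size) == 2L, all(size >= 16L), radius >= 2,
            noise_sigma >= 0, n_frames >= 1, scale_step > 0)
  if (is.null(center)) center <- c((size[2] - 1) / 2, (size[1] - 1) / 2)
  ## reject targets that leave (or come within 5 px of) the frame border
  tmax <- n_frames - 1L
  rmax <- radius * scale_step^tmax * if (shape == "tool_polygon") 1.2 else 1
  xs <- center[1] + vx * c(0, tmax); ys <- center[2] + vy * c(0, tmax)
  if (min(xs) - rmax < 5 || max(xs) + rmax > size[2] - 6 ||
      min(ys) - rmax < 5 || max(ys) + rmax > size[1] - 6)
    stop("target leaves the frame (or its 5 px safety margin)")
  structure(list(size = size, shape = shape, center = center,
                 radius = radius, fg = fg, bg = bg,
                 texture_amp = texture_amp, vx = vx, vy = vy,
                 scale_step = scale_step, rot_step = rot_step,
                 noise_sigma = noise_sigma, illum_drift = illum_drift,
                 occluder = occluder, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "sequence_spec")
}

.raster_target <- function(spec, t) {
  m <- spec$size[1]; n <- spec$size[2]
  cx <- spec$center[1] + spec$vx * (t - 1L)
  cy <- spec$center[2] + spec$vy * (t - 1L)
  rad <- spec$radius * spec$scale_step^(t - 1L)
  x <- matrix(rep(0:(n - 1), each = m), m)
  y <- matrix(rep(0:(m - 1), times = n), m)
  if (spec$shape == "disk") {
    (x - cx)^2 + (y - cy)^2 <= rad^2
  } else if (spec$shape == "square") {
    abs(x - cx) <= rad & abs(y - cy) <= rad
  } else {
    ## tool silhouette: rotated elongated rectangle with a wedge tip
    ang <- spec$rot_step * (t - 1L)
    u <- (x - cx) * cos(ang) + (y - cy) * sin(ang)
    v <- -(x - cx) * sin(ang) + (y - cy) * cos(ang)
    whalf <- rad / 3
    body <- u >= -rad & u <= rad * 0.6 & abs(v) <= whalf
    tip <- u > rad * 0.6 & u <= rad * 1.2 &
      abs(v) <= whalf * (1 - (u - rad * 0.6) / (rad * 0.6))
    body | tip
  }
}

#' Generate a synthetic sequence with ground-truth masks
#'
#' Deterministic given the spec's seed; ground-truth masks are the exact
#' rasterized target before noise or occlusion.
#'
#' @param spec A [sequence_spec()].
#' @return List with \code{frames} (list of matrices in [0, 1]),
#'   \code{masks} (list of logical matrices), \code{clean} (noise-free
#'   frames) and \code{spec}.
#' @export
make_sequence <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  m <- spec$size[1]; n <- spec$size[2]
  texture <- box_mean(matrix(stats::rnorm(m * n), m), 7L)
  if (stats::sd(texture) > 0)
    texture <- texture / stats::sd(texture) * spec$texture_amp
  ramp <- matrix(rep(seq(-0.5, 0.5, length.out = n), each = m), m)
  frames <- masks <- clean <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    mask <- .raster_target(spec, t)
    img <- spec$bg + texture
    img[mask] <- spec$fg
    if (spec$illum_drift > 0)
      img <- img + spec$illum_drift * sin(2 * pi * (t - 1) /
                                          max(1, spec$n_frames)) * ramp
    occ <- spec$occluder
    if (!is.null(occ) && t %in% occ$frames) {
      xr <- occ$x + seq_len(occ$w) - 1L
      yr <- occ$y + seq_len(occ$h) - 1L
      xr <- xr[xr >= 0 & xr < n]; yr <- yr[yr >= 0 & yr < m]
      img[yr + 1L, xr + 1L] <- occ$value
    }
    clean[[t]] <- img
    noisy <- img + stats::rnorm(m * n, 0, spec$noise_sigma)
    frames[[t]] <- pmin(pmax(noisy, 0), 1)
    masks[[t]] <- mask
  }
  list(frames = frames, masks = masks, clean = clean, spec = spec)
}

#' Overlap index (Jaccard, in percent)
#'
#' \eqn{OI = 100 |P \cap G| / |P \cup G|}.
#'
#' @param pred,gt Logical matrices of equal size; at least one must be
#'   non-empty.
#' @return Percentage in [0, 100].
#' @export
overlap_index <- function(pred, gt) {
  stopifnot(identical(dim(pred), dim(gt)))
  pred <- as.logical(pred); gt <- as.logical(gt)
  uni <- sum(pred | gt)
  if (uni == 0L) stop("overlap index undefined: both masks empty")
  100 * sum(pred & gt) / uni
}

#' Dice coefficient
#'
#' \eqn{DC = 2|X \cap Y| / (|X| + |Y|)}.
#'
#' @inheritParams overlap_index
#' @return Value in [0, 1].
#' @export
dice <- function(pred, gt) {
  stopifnot(identical(dim(pred), dim(gt)))
  pred <- as.logical(pred); gt <- as.logical(gt)
  tot <- sum(pred) + sum(gt)
  if (tot == 0L) stop("Dice undefined: both masks empty")
  2 * sum(pred & gt) / tot
}
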