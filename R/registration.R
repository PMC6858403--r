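#' Six-parameter affine pose
#'
#' The pose \eqn{\Delta T = (p_1 \ldots p_6)} acts on 0-based pixel-centre
#' coordinates \eqn{(x, y)} (x = column, y = row) as
#' \deqn{x' = (1+p_1)x + p_3 y + p_5, \qquad y' = p_2 x + (1+p_4)y + p_6.}
#' The zero pose is the identity map.
#'
#' @param p Numeric length-6 vector \code{c(p1, p2, p3, p4, p5, p6)}.
#' @return Object of class \code{"affine_pose"}.
#' @export
affine_pose <- function(p = numeric(6)) {
  stopifnot(is.numeric(p), length(p) == 6L, all(is.finite(p)))
  structure(list(p = as.numeric(p)), class = "affine_pose")
}

#' @rdname affine_pose
#' @param pose An \code{"affine_pose"} object.
#' @return For \code{pose_matrix}, the 2 x 3 matrix
#'   \code{[[1+p1, p3, p5], [p2, 1+p4, p6]]}.
#' @export
pose_matrix <- function(pose) {
  p <- pose$p
  matrix(c(1 + p[1], p[2], p[3], 1 + p[4], p[5], p[6]), 2L, 3L)
}

.pose_det <- function(pose) {
  p <- pose$p
  (1 + p[1]) * (1 + p[4]) - p[2] * p[3]
}

#' Apply an affine pose to points
#'
#' @param pose An [affine_pose()] object.
#' @param points Numeric n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of warped coordinates.
#' @export
apply_affine <- function(pose, points) {
  stopifnot(inherits(pose, "affine_pose"))
  points <- rbind(points)  # accept a bare length-2 vector
  stopifnot(ncol(points) == 2L, all(is.finite(points)))
  A <- pose_matrix(pose)
  out <- cbind(A[1, 1] * points[, 1] + A[1, 2] * points[, 2] + A[1, 3],
               A[2, 1] * points[, 1] + A[2, 2] * points[, 2] + A[2, 3])
  dimnames(out) <- NULL
  out
}

## Bilinear sampling of grid z at 0-based (x, y); constant fill outside.
.bilinear <- function(z, x, y, fill) {
  m <- nrow(z); n <- ncol(z)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inside <- x0 >= 0 & x0 <= n - 2 & y0 >= 0 & y0 <= m - 2
  ## clamp so indexing is safe; overwritten by fill afterwards
  xi <- pmin(pmax(x0, 0), n - 2) + 1L
  yi <- pmin(pmax(y0, 0), m - 2) + 1L
  i00 <- yi + (xi - 1L) * m
  v <- (1 - fx) * ((1 - fy) * z[i00] + fy * z[i00 + 1L]) +
       fx * ((1 - fy) * z[i00 + m] + fy * z[i00 + m + 1L])
  ## points exactly on the max edge are valid samples
  edge <- !inside & x >= 0 & x <= n - 1 & y >= 0 & y <= m - 1
  v[!inside] <- fill
  if (any(edge)) {
    xe <- pmin(pmax(x[edge], 0), n - 1)
    ye <- pmin(pmax(y[edge], 0), m - 1)
    x0e <- pmin(floor(xe), n - 2); y0e <- pmin(floor(ye), m - 2)
    fxe <- xe - x0e; fye <- ye - y0e
    i00 <- (y0e + 1) + x0e * m
    v[edge] <- (1 - fxe) * ((1 - fye) * z[i00] + fye * z[i00 + 1L]) +
               fxe * ((1 - fye) * z[i00 + m] + fye * z[i00 + m + 1L])
  }
  v
}

#' Warp a level set by an affine pose
#'
#' The warped region is the image of the original region under the pose:
#' \eqn{\phi'(x) = \phi(h^{-1}(x))}, evaluated by inverse mapping with
#' bilinear interpolation.  Samples falling outside the frame are filled
#' with \eqn{-th} (background).
#'
#' @param ls A [init_level_set()] object.
#' @param pose An [affine_pose()] object; must be invertible
#'   (\eqn{|\det| \ge 10^{-6}}).
#' @return A new \code{"level_set"} object on the same grid.
#' @export
warp_level_set <- function(ls, pose) {
  stopifnot(inherits(ls, "level_set"), inherits(pose, "affine_pose"))
  d <- .pose_det(pose)
  if (abs(d) < 1e-6) stop("non-invertible pose (|det| < 1e-6)")
  m <- nrow(ls$phi); n <- ncol(ls$phi)
  A <- pose_matrix(pose)
  ## inverse map: A2^-1 (x - b)
  Ainv <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2L, 2L) / d
  gx <- rep(0:(n - 1), each = m)
  gy <- rep(0:(m - 1), times = n)
  ux <- gx - A[1, 3]; uy <- gy - A[2, 3]
  sx <- Ainv[1, 1] * ux + Ainv[1, 2] * uy
  sy <- Ainv[2, 1] * ux + Ainv[2, 2] * uy
  phi <- matrix(.bilinear(ls$phi, sx, sy, fill = -ls$th), m, n)
  structure(list(phi = phi, th = ls$th), class = "level_set")
}

## Matching energy of a warped pose: Heaviside-weighted means of the
## Taylor weights.  The normalization masses are those of the evaluated
## candidate itself (the linearized Bhattacharyya coefficient), which keeps
## the score bounded and area-invariant; a fixed-mass normalization would
## reward inflating the region.
.pose_energy <- function(lw, wts, gamma, eps) {
  roi <- lw$phi > -lw$th
  H <- heaviside_eps(lw$phi, eps) * roi
  wb <- (1 - heaviside_eps(lw$phi, eps)) * (roi & lw$phi < 0)
  Ff <- sum(H); Fb <- sum(wb)
  if (Ff < 1e-12 || Fb < 1e-12) return(-Inf)
  0.5 * sum(wts$h_f * H) / Ff + 0.5 * gamma * sum(wts$h_b * wb) / Fb
}

#' Estimate the inter-frame affine pose
#'
#' Maximizes the Bhattacharyya matching energy of the warped candidate
#' region over the six-parameter warp by preconditioned finite-difference
#' gradient ascent with a backtracking line search.  The foreground and
#' background candidate distributions are recomputed at every evaluated
#' pose; the background-band term anchors both the position and the scale
#' of the region (its linearized form with frozen normalization masses is
#' unbounded in area and is used only inside the contour evolution).
#'
#' @param frame Current (denoised) frame.
#' @param ls Level set carried over from the previous frame.
#' @param models First-frame [build_models()] object.
#' @param gamma Background balance weight.
#' @param eps Heaviside width (px) used for the candidate histograms.  The
#'   default is much sharper than the evolution width: the slowly decaying
#'   arctan tails would otherwise leak background mass into the soft
#'   foreground histogram in a scale-dependent way and bias the warp
#'   toward shrinking.
#' @param tol Convergence threshold on the pixel-equivalent pose increment.
#' @param max_iters Maximum accepted ascent steps.
#' @return List with \code{pose} (an [affine_pose()]), \code{trace}
#'   (non-decreasing energies of accepted steps), \code{iters},
#'   \code{converged}.
#' @export
estimate_pose <- function(frame, ls, models, gamma = 0.5, eps = 0.1,
                          tol = 1e-3, max_iters = 50L) {
  stopifnot(identical(dim(frame), dim(ls$phi)))
  dist0 <- region_distributions(frame, ls, r = models$r, eps = eps,
                                edges = models$edges)
  wts <- pixel_weights(frame, models, dist0)
  if (sum(ls$phi >= 0) < 4)
    stop("degenerate region: foreground nearly empty before registration")

  ## pixel-equivalent scale of the linear parameters: target radius
  rad <- max(2, sqrt(sum(ls$phi >= 0) / pi))
  scale <- c(rad, rad, rad, rad, 1, 1)
  fd_step <- c(rep(0.02, 4), rep(0.25, 2))

  ## optimize in coordinates centred on the current target centroid, so
  ## the linear parameters are not entangled with translation; the
  ## returned pose is the equivalent origin-based warp
  fg_idx <- which(ls$phi >= 0, arr.ind = TRUE)
  ctr <- c(mean(fg_idx[, 2]) - 1, mean(fg_idx[, 1]) - 1)  # (x, y)
  to_origin <- function(p) {
    A <- matrix(c(1 + p[1], p[2], p[3], 1 + p[4]), 2L, 2L)
    b <- ctr - A %*% ctr + p[5:6]
    c(p[1:4], b)
  }

  obj <- function(p) {
    lw <- warp_level_set(ls, affine_pose(to_origin(p)))
    d <- tryCatch(region_distributions(frame, lw, r = models$r, eps = eps,
                                       edges = models$edges),
                  error = function(e) NULL)
    if (is.null(d)) return(-Inf)
    bhattacharyya_energy(d, models, gamma)
  }
  p <- numeric(6)
  e <- obj(p)
  trace <- e
  iters <- 0L
  converged <- FALSE
  ascend <- function(active, budget) {
    alpha <- 1
    done <- FALSE
    for (it in seq_len(budget)) {
      g <- numeric(6)
      for (j in active) {
        dp <- fd_step[j]
        pp <- p; pp[j] <- pp[j] + dp
        pm <- p; pm[j] <- pm[j] - dp
        g[j] <- (obj(pp) - obj(pm)) / (2 * dp)
      }
      ## precondition: gradient in pixel-equivalent units, unit max step
      d <- g / scale^2
      gnorm <- max(abs(d * scale))
      if (gnorm < 1e-12) { done <- TRUE; break }
      d <- d / gnorm  # max pixel-equivalent component = 1
      accepted <- FALSE
      while (alpha > 1e-4) {
        cand <- p + alpha * d
        if (abs((1 + cand[1]) * (1 + cand[4]) - cand[2] * cand[3]) >= 1e-6) {
          ec <- obj(cand)
          if (ec > e + 1e-6) {
            step_px <- sqrt(sum((alpha * d * scale)^2))
            p <<- cand; e <<- ec
            trace <<- c(trace, ec)
            accepted <- TRUE
            alpha <- min(alpha * 1.5, 4)
            if (step_px < tol) done <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
      iters <<- iters + 1L
      if (!accepted) { done <- TRUE; break }
      if (done) break
    }
    done
  }
  ## translation first (the dominant inter-frame motion), then the full
  ## six-parameter refinement
  ascend(5:6, max_iters)
  converged <- ascend(1:6, max(0L, max_iters - iters))
  list(pose = affine_pose(to_origin(p)), trace = trace, iters = iters,
       converged = converged, energy = e)
}
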