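#' Mirror-padded k x k box mean
#'
#' Moving-average filter \eqn{g_k} with symmetric (mirror) boundary
#' handling, computed with an integral image.
#'
#' @param x Numeric matrix.
#' @param k Odd window side (>= 1).
#' @return Matrix of local means, same size as \code{x}.
#' @export
box_mean <- function(x, k) {
  k <- as.integer(k)
  stopifnot(is.matrix(x), k >= 1L, k %% 2L == 1L)
  if (k == 1L) return(x)
  r <- (k - 1L) %/% 2L
  m <- nrow(x); n <- ncol(x)
  if (k > 2L * m || k > 2L * n) stop("window larger than twice the image")
  ri <- c(r:1, 1:m, m:(m - r + 1L))
  ci <- c(r:1, 1:n, n:(n - r + 1L))
  xp <- x[ri, ci, drop = FALSE]
  ## integral image with a leading zero row/column
  S <- matrix(0, m + 2L * r + 1L, n + 2L * r + 1L)
  S[-1L, -1L] <- t(apply(apply(xp, 2L, cumsum), 1L, cumsum))
  i0 <- seq_len(m); j0 <- seq_len(n)
  (S[i0 + k, j0 + k] - S[i0, j0 + k] - S[i0 + k, j0] + S[i0, j0]) / (k * k)
}

#' Spatially varying global means
#'
#' Weighted local averages of the image inside and outside the contour:
#' \eqn{c_1 = g_k \ast (u_0 H_\epsilon(\phi)) / g_k \ast H_\epsilon(\phi)}
#' and the analogue with \eqn{1 - H_\epsilon(\phi)}; denominators are
#' floored at \code{mean_floor}.
#'
#' @param frame Numeric matrix \eqn{u_0}.
#' @param phi Level-set grid (same size).
#' @param k Averaging window side (odd).
#' @param eps Heaviside width (px).
#' @param mean_floor Small positive denominator floor.
#' @return List with grids \code{c1}, \code{c2}.
#' @export
compute_global_means <- function(frame, phi, k = 9L, eps = 1.5,
                                 mean_floor = 1e-3) {
  H <- heaviside_eps(phi, eps)
  bH <- box_mean(H, k)
  buH <- box_mean(frame * H, k)
  bu <- box_mean(frame, k)
  c1 <- buH / pmax(bH, mean_floor)
  c2 <- (bu - buH) / pmax(1 - bH, mean_floor)
  list(c1 = c1, c2 = c2)
}

#' Spatially varying local means of the difference image
#'
#' Forms \eqn{D = g_k \ast u_0 - u_0} and window-averages it inside and
#' outside the contour exactly as [compute_global_means()].
#'
#' @inheritParams compute_global_means
#' @return List with grids \code{d1}, \code{d2} and the difference image
#'   \code{D}.
#' @export
compute_local_means <- function(frame, phi, k = 9L, eps = 1.5,
                                mean_floor = 1e-3) {
  D <- box_mean(frame, k) - frame
  H <- heaviside_eps(phi, eps)
  bH <- box_mean(H, k)
  bDH <- box_mean(D * H, k)
  bD <- box_mean(D, k)
  d1 <- bDH / pmax(bH, mean_floor)
  d2 <- (bD - bDH) / pmax(1 - bH, mean_floor)
  list(d1 = d1, d2 = d2, D = D)
}

.shift_rep <- function(x, dr, dc) {
  m <- nrow(x); n <- ncol(x)
  ri <- pmin(pmax(seq_len(m) + dr, 1L), m)
  ci <- pmin(pmax(seq_len(n) + dc, 1L), n)
  x[ri, ci, drop = FALSE]
}

.grad_central <- function(phi) {
  list(px = (.shift_rep(phi, 0L, 1L) - .shift_rep(phi, 0L, -1L)) / 2,
       py = (.shift_rep(phi, 1L, 0L) - .shift_rep(phi, -1L, 0L)) / 2)
}

#' Mean curvature of the level-set function
#'
#' \eqn{\kappa = \nabla \cdot (\nabla\phi / |\nabla\phi|)} by central
#' differences with replicated borders; the gradient magnitude is floored
#' at \code{1e-8}.
#'
#' @param phi Numeric matrix.
#' @return Curvature grid (1/px).
#' @export
curvature <- function(phi) {
  g <- .grad_central(phi)
  px <- g$px; py <- g$py
  pxx <- .shift_rep(phi, 0L, 1L) - 2 * phi + .shift_rep(phi, 0L, -1L)
  pyy <- .shift_rep(phi, 1L, 0L) - 2 * phi + .shift_rep(phi, -1L, 0L)
  pxy <- (.shift_rep(phi, 1L, 1L) - .shift_rep(phi, 1L, -1L) -
          .shift_rep(phi, -1L, 1L) + .shift_rep(phi, -1L, -1L)) / 4
  gmag <- pmax(sqrt(px^2 + py^2), 1e-8)
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / gmag^3
}

#' Segmentation configuration
#'
#' @param lambda1 Global fitting weight.
#' @param lambda2 Local fitting weight.
#' @param mu Contour-length penalty weight.
#' @param nu Area penalty weight.
#' @param k Averaging window side (odd, >= 3).
#' @param eps Heaviside width (px).
#' @param dt_evolve Evolution time step.
#' @param n_steps Maximum evolution steps.
#' @param gamma Background balance weight (shared with registration).
#' @param mean_floor Denominator stabilizer for the squared-mean divisions
#'   (intensity-squared units; must sit at the dynamic-range scale, see
#'   vignette).
#' @param reinit_every Accepted steps between signed-distance
#'   re-initializations (0 disables).
#' @param strict_eq9 Use the literally printed asymmetric global energy
#'   (second numerator with \eqn{c_1}); default FALSE uses the symmetric
#'   reading consistent with the update equation.
#' @return Object of class \code{"seg_config"}.
#' @export
segmentation_config <- function(lambda1 = 1, lambda2 = 1, mu = 0.2, nu = 0,
                                k = 15L, eps = 1.5, dt_evolve = 0.1,
                                n_steps = 200L, gamma = 0.5,
                                mean_floor = 0.01, reinit_every = 20L,
                                strict_eq9 = FALSE) {
  k <- as.integer(k)
  stopifnot(lambda1 >= 0, lambda2 >= 0, mu >= 0, nu >= 0,
            k >= 3L, k %% 2L == 1L, eps > 0, dt_evolve > 0, n_steps >= 1,
            gamma >= 0, mean_floor > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, mu = mu, nu = nu,
                 k = k, eps = eps, dt_evolve = dt_evolve,
                 n_steps = as.integer(n_steps), gamma = gamma,
                 mean_floor = mean_floor,
                 reinit_every = as.integer(reinit_every),
                 strict_eq9 = isTRUE(strict_eq9)),
            class = "seg_config")
}

#' Discrete region-based energy of a contour
#'
#' Length + area penalties plus the global and local normalized fitting
#' terms evaluated with the current spatially varying means.  This is the
#' quantity the evolution decreases.
#'
#' @param frame Numeric matrix.
#' @param phi Level-set grid.
#' @param cfg A [segmentation_config()].
#' @return Scalar energy.
#' @export
region_energy <- function(frame, phi, cfg = segmentation_config()) {
  H <- heaviside_eps(phi, cfg$eps)
  dlt <- dirac_eps(phi, cfg$eps)
  g <- .grad_central(phi)
  gm <- compute_global_means(frame, phi, cfg$k, cfg$eps, cfg$mean_floor)
  lm <- compute_local_means(frame, phi, cfg$k, cfg$eps, cfg$mean_floor)
  fl <- cfg$mean_floor
  c1f <- pmax(gm$c1^2, fl); c2f <- pmax(gm$c2^2, fl)
  d1f <- pmax(lm$d1^2, fl); d2f <- pmax(lm$d2^2, fl)
  num2 <- if (cfg$strict_eq9) (frame - gm$c1)^2 else (frame - gm$c2)^2
  cfg$mu * sum(dlt * sqrt(g$px^2 + g$py^2)) +
    cfg$nu * sum(H) +
    cfg$lambda1 * sum((frame - gm$c1)^2 * H / c1f) +
    cfg$lambda1 * sum(num2 * (1 - H) / c2f) +
    cfg$lambda2 * sum((lm$D - lm$d1)^2 * H / d1f) +
    cfg$lambda2 * sum((lm$D - lm$d2)^2 * (1 - H) / d2f)
}

## Bhattacharyya matching contribution (Eq.-12 form) used in the combined
## accepted-step objective; weights may be NULL.
.bhatt_term <- function(phi, wts, cfg) {
  if (is.null(wts)) return(0)
  H <- heaviside_eps(phi, cfg$eps)
  0.5 * cfg$dt_evolve *
    (sum(wts$h_f * H) / wts$Ff -
       cfg$gamma * sum(wts$h_b * (1 - H)) / wts$Fb)
}

#' Level-set contour evolution
#'
#' Explicit steepest-descent iteration of the combined update: the
#' Dirac-gated curvature/area/global-contrast terms, the local-contrast
#' term (outside the Dirac gate, as printed in the source model), and the
#' Bhattacharyya weight term.  Steps are accepted only if the combined
#' objective (region energy minus the matching term) does not increase;
#' otherwise the time step is halved.  The level set is re-initialized to
#' a signed distance every \code{reinit_every} accepted steps (kept only
#' when it does not degrade the objective), borders follow a Neumann
#' condition by edge replication, and evolution stops when the zero level
#' has not moved for 10 consecutive steps.
#'
#' @param frame Numeric matrix in [0, 1].
#' @param ls A [init_level_set()] object (e.g. the registered contour).
#' @param weights Optional [pixel_weights()] list (with \code{Ff},
#'   \code{Fb}); NULL runs the segmentation stand-alone.
#' @param cfg A [segmentation_config()].
#' @return List with \code{ls} (evolved level set), \code{trace}
#'   (data.frame \code{step}, \code{energy}, \code{objective}),
#'   \code{steps}, \code{converged}.
#' @export
evolve_level_set <- function(frame, ls, weights = NULL,
                             cfg = segmentation_config()) {
  stopifnot(inherits(ls, "level_set"), identical(dim(frame), dim(ls$phi)))
  phi <- ls$phi
  ## the squared-mean stabilizer must dominate the noise variance of the
  ## difference image, or the local term minimizes energy by capturing
  ## noise; raise the floor to (2 sigma_hat)^2 when the data are noisier
  ## than the configured floor anticipates
  sigma_hat <- tryCatch(estimate_sigma0(frame), error = function(e) 0)
  cfg$mean_floor <- max(cfg$mean_floor, (2 * sigma_hat)^2)
  fl <- cfg$mean_floor
  objective <- function(p)
    region_energy(frame, p, cfg) - .bhatt_term(p, weights, cfg)
  obj <- objective(phi)
  dt <- cfg$dt_evolve
  trace_step <- integer(0); trace_e <- numeric(0); trace_o <- numeric(0)
  still <- 0L
  converged <- FALSE
  steps <- 0L
  for (it in seq_len(cfg$n_steps)) {
    H <- heaviside_eps(phi, cfg$eps)
    dlt <- dirac_eps(phi, cfg$eps)
    gm <- compute_global_means(frame, phi, cfg$k, cfg$eps, fl)
    lm <- compute_local_means(frame, phi, cfg$k, cfg$eps, fl)
    c1f <- pmax(gm$c1^2, fl); c2f <- pmax(gm$c2^2, fl)
    d1f <- pmax(lm$d1^2, fl); d2f <- pmax(lm$d2^2, fl)
    ## the lambda2 term is Dirac-gated like the others: this is the
    ## variational derivative of the local energy, and without the gate
    ## far-field noise flips distant pixels into the region
    field <- dlt * (cfg$mu * curvature(phi) - cfg$nu +
                    cfg$lambda1 * ((frame - gm$c2)^2 / c2f -
                                   (frame - gm$c1)^2 / c1f) +
                    cfg$lambda2 * ((lm$D - lm$d2)^2 / d2f -
                                   (lm$D - lm$d1)^2 / d1f))
    if (!is.null(weights))
      field <- field + 0.5 * cfg$dt_evolve * dlt *
        (weights$h_f / weights$Ff - cfg$gamma * weights$h_b / weights$Fb)
    accepted <- FALSE
    while (dt > cfg$dt_evolve / 4096) {
      cand <- phi + dt * field
      ## Neumann boundary by edge replication
      cand[1L, ] <- cand[2L, ]; cand[nrow(cand), ] <- cand[nrow(cand) - 1L, ]
      cand[, 1L] <- cand[, 2L]; cand[, ncol(cand)] <- cand[, ncol(cand) - 1L]
      if (!all(is.finite(cand)))
        stop("level-set evolution produced non-finite phi; reduce dt_evolve")
      ocand <- objective(cand)
      if (ocand <= obj + 1e-9 * max(1, abs(obj))) {
        moved <- sum((cand >= 0) != (phi >= 0))
        phi <- cand; obj <- ocand
        accepted <- TRUE
        dt <- min(dt * 1.25, cfg$dt_evolve)
        still <- if (moved == 0L) still + 1L else 0L
        break
      }
      dt <- dt / 2
    }
    if (!accepted) { converged <- TRUE; break }
    steps <- it
    if (cfg$reinit_every > 0L && it %% cfg$reinit_every == 0L &&
        any(phi >= 0) && !all(phi >= 0)) {
      cand <- sdf_from_mask(phi >= 0)
      ocand <- objective(cand)
      if (ocand <= obj + 1e-9 * max(1, abs(obj))) { phi <- cand; obj <- ocand }
    }
    trace_step <- c(trace_step, it)
    trace_e <- c(trace_e, region_energy(frame, phi, cfg))
    trace_o <- c(trace_o, obj)
    if (still >= 10L) { converged <- TRUE; break }
  }
  list(ls = structure(list(phi = phi, th = ls$th), class = "level_set"),
       trace = data.frame(step = trace_step, energy = trace_e,
                          objective = trace_o),
       steps = steps, converged = converged)
}
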