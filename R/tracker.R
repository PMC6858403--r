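## 32-bit FNV-1a hash of a string, returned as 8 hex digits; the multiply
## is split so every intermediate stays exactly representable in a double.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    ## xor on the low byte only (b < 256); h may exceed integer range
    lob <- h %% 256
    h <- h - lob + bitwXor(as.integer(lob), as.integer(b %% 256))
    lo <- h %% 65536; hi <- h %/% 65536
    ## h * 16777619 mod 2^32, split to stay within double precision
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Tracker configuration
#'
#' Bundles the per-stage settings of the full pipeline.
#'
#' @param denoise List of [denoise_frame()] arguments (\code{wavelet},
#'   \code{levels}, \code{w}, \code{z}, \code{dt}, \code{n_iter},
#'   \code{sigma0}, \code{skip_approx}); \code{enabled = FALSE} bypasses
#'   the stage.
#' @param r Histogram bin count.
#' @param th Background band threshold (px).
#' @param gamma Background balance weight.
#' @param eps Heaviside width (px) for the region distributions feeding
#'   the contour evolution.
#' @param eps_match Sharper Heaviside width used by [estimate_pose()].
#' @param reg_tol,reg_max_iters Registration convergence settings.
#' @param segmentation A [segmentation_config()].
#' @param model_update Model adaptation policy: \code{"none"} (fixed
#'   first-frame models), \code{"per_frame"}, or \code{"every_n"}.
#' @param update_n Frame period for \code{model_update = "every_n"}.
#' @param coast_fraction Occlusion guard: if the foreground mass falls
#'   below this fraction of its initial value the frame is flagged and the
#'   registered (unsegmented) contour is carried instead.
#' @return Object of class \code{"tracker_config"} with a \code{hash}
#'   field identifying the configuration.
#' @export
tracker_config <- function(denoise = list(enabled = TRUE, wavelet = "haar",
                                          levels = 2L, w = NA, z = 2.7e-5,
                                          dt = 0.007, n_iter = 200L,
                                          sigma0 = NULL,
                                          skip_approx = FALSE,
                                          rescale = "match"),
                           r = 32L, th = 10, gamma = 0.5, eps = 1.5,
                           eps_match = 0.1,
                           reg_tol = 1e-3, reg_max_iters = 50L,
                           segmentation = segmentation_config(),
                           model_update = c("none", "per_frame", "every_n"),
                           update_n = 5L, coast_fraction = 0.25) {
  model_update <- match.arg(model_update)
  stopifnot(inherits(segmentation, "seg_config"), r >= 2, th > 0,
            gamma >= 0, eps > 0, coast_fraction >= 0, coast_fraction < 1)
  defaults <- list(enabled = TRUE, wavelet = "haar", levels = 2L, w = NA,
                   z = 2.7e-5, dt = 0.007, n_iter = 200L, sigma0 = NULL,
                   skip_approx = FALSE, rescale = "match")
  denoise <- utils::modifyList(defaults, denoise)
  cfg <- list(denoise = denoise, r = as.integer(r), th = th, gamma = gamma,
              eps = eps, eps_match = eps_match, reg_tol = reg_tol,
              reg_max_iters = as.integer(reg_max_iters),
              segmentation = segmentation, model_update = model_update,
              update_n = as.integer(update_n),
              coast_fraction = coast_fraction)
  plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  cfg$hash <- .fnv1a(as.character(jsonlite::toJSON(plain, auto_unbox = TRUE,
                                                   digits = NA,
                                                   null = "null")))
  class(cfg) <- "tracker_config"
  cfg
}

.denoise_stage <- function(frame, dn) {
  if (!isTRUE(dn$enabled)) return(frame)
  denoise_frame(frame, wavelet = dn$wavelet, levels = dn$levels,
                sigma0 = dn$sigma0, w = dn$w, z = dn$z, dt = dn$dt,
                n_iter = dn$n_iter, skip_approx = dn$skip_approx,
                rescale = dn$rescale)$frame
}

#' Track a target through a frame sequence
#'
#' Full pipeline: the first frame is denoised, the initial mask is turned
#' into a level set, refined by the contour evolution and used to build the
#' foreground/background models.  Each later frame is denoised, the
#' inter-frame affine pose is estimated by Bhattacharyya matching, the
#' level set is warped accordingly, and the contour is refined by the
#' combined local/global evolution.  A frame whose foreground mass drops
#' below the coast threshold is flagged and keeps the registered contour.
#'
#' @param frames List of numeric matrices in [0, 1] (>= 2 frames).
#' @param init_mask Logical matrix marking the target on frame 1.
#' @param cfg A [tracker_config()].
#' @return Object of class \code{"track_result"}: list with \code{masks}
#'   (per-frame logical matrices), \code{poses} (n x 6 matrix),
#'   \code{energies} (per-frame summary data.frame), \code{flags}
#'   (character vector), \code{config_hash}, and \code{partial} (TRUE if
#'   tracking stopped early on a degenerate target).
#' @export
track_sequence <- function(frames, init_mask, cfg = tracker_config()) {
  stopifnot(is.list(frames), length(frames) >= 2L)
  stopifnot(inherits(cfg, "tracker_config"))
  n_frames <- length(frames)
  masks <- vector("list", n_frames)
  poses <- matrix(0, n_frames, 6,
                  dimnames = list(NULL, paste0("p", 1:6)))
  flags <- character(n_frames)
  reg_energy <- seg_energy <- rep(NA_real_, n_frames)
  partial <- FALSE

  f1 <- .denoise_stage(frames[[1L]], cfg$denoise)
  ls <- init_level_set(init_mask, th = cfg$th)
  ev <- evolve_level_set(f1, ls, weights = NULL, cfg = cfg$segmentation)
  ls <- ev$ls
  seg_energy[1L] <- if (nrow(ev$trace)) ev$trace$energy[nrow(ev$trace)] else
    region_energy(f1, ls$phi, cfg$segmentation)
  masks[[1L]] <- ls$phi >= 0
  if (!any(masks[[1L]])) stop("initial contour collapsed on frame 1")
  models <- build_models(f1, ls, r = cfg$r)
  init_mass <- sum(masks[[1L]])

  for (t in 2:n_frames) {
    ft <- .denoise_stage(frames[[t]], cfg$denoise)
    est <- tryCatch(
      estimate_pose(ft, ls, models, gamma = cfg$gamma, eps = cfg$eps_match,
                    tol = cfg$reg_tol, max_iters = cfg$reg_max_iters),
      error = function(e) e)
    if (inherits(est, "error")) {
      flags[t] <- paste("degenerate:", conditionMessage(est))
      partial <- TRUE
      masks <- masks[seq_len(t - 1L)]
      break
    }
    poses[t, ] <- est$pose$p
    reg_energy[t] <- est$energy
    ls_reg <- warp_level_set(ls, est$pose)
    dist0 <- region_distributions(ft, ls_reg, r = models$r, eps = cfg$eps,
                                  edges = models$edges)
    wts <- pixel_weights(ft, models, dist0)
    ev <- evolve_level_set(ft, ls_reg, weights = wts,
                           cfg = cfg$segmentation)
    mask_t <- ev$ls$phi >= 0
    if (sum(mask_t) < cfg$coast_fraction * init_mass) {
      ## likely occlusion: keep the registered contour, freeze refinement
      flags[t] <- "coast"
      ls <- ls_reg
      mask_t <- ls_reg$phi >= 0
      if (!any(mask_t)) {
        flags[t] <- "degenerate: empty mask after coast"
        partial <- TRUE
        masks <- masks[seq_len(t - 1L)]
        break
      }
    } else {
      ls <- ev$ls
      seg_energy[t] <- if (nrow(ev$trace))
        ev$trace$energy[nrow(ev$trace)] else NA_real_
    }
    masks[[t]] <- mask_t
    if (cfg$model_update == "per_frame" ||
        (cfg$model_update == "every_n" && t %% cfg$update_n == 0L))
      models <- build_models(ft, ls, r = cfg$r)
  }

  structure(list(masks = masks, poses = poses[seq_along(masks), , drop = FALSE],
                 energies = data.frame(frame = seq_along(masks),
                                       reg_energy = reg_energy[seq_along(masks)],
                                       seg_energy = seg_energy[seq_along(masks)]),
                 flags = flags[seq_along(masks)],
                 config_hash = cfg$hash, partial = partial),
            class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  cat(sprintf("track result: %d frame(s)%s, config %s\n", length(x$masks),
              if (x$partial) " (partial)" else "", x$config_hash))
  if (any(nzchar(x$flags)))
    cat("  flagged frames:",
        paste(which(nzchar(x$flags)), collapse = ", "), "\n")
  invisible(x)
}
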