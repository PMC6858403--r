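# Shared synthetic fixtures, built in code.

coord_grids <- function(m, n = m) {
  list(x = matrix(rep(0:(n - 1), each = m), m),
       y = matrix(rep(0:(m - 1), times = n), m))
}

disk_mask <- function(m, cx, cy, r, n = m) {
  g <- coord_grids(m, n)
  (g$x - cx)^2 + (g$y - cy)^2 <= r^2
}

square_mask <- function(m, cx, cy, half, n = m) {
  g <- coord_grids(m, n)
  abs(g$x - cx) <= half & abs(g$y - cy) <= half
}

# two-region phantom: fg intensity inside the mask, bg outside, plus noise
two_region_phantom <- function(mask, fg = 0.8, bg = 0.2, sigma = 0,
                               clip = TRUE) {
  f <- matrix(bg, nrow(mask), ncol(mask))
  f[mask] <- fg
  if (sigma > 0) f <- f + matrix(rnorm(length(f), 0, sigma), nrow(f))
  if (clip) f <- pmin(pmax(f, 0), 1)
  f
}

# a level set built directly from a phi grid (bypasses init_level_set)
raw_level_set <- function(phi, th = 10) {
  structure(list(phi = phi, th = th), class = "level_set")
}
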