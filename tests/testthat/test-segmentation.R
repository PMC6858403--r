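test_that("box mean matches a direct window average", {
  set.seed(401)
  z <- matrix(runif(30 * 26), 30, 26)
  b <- box_mean(z, 5)
  expect_equal(b[10, 10], mean(z[8:12, 8:12]), tolerance = 1e-12)
  expect_equal(b[15, 20], mean(z[13:17, 18:22]), tolerance = 1e-12)
  # mirror padding passes constants unchanged
  expect_equal(box_mean(matrix(0.7, 12, 12), 7), matrix(0.7, 12, 12),
               tolerance = 1e-12)
  # corner: mirrored indices (2:1, 1:3) x (2:1, 1:3)
  expect_equal(b[1, 1], mean(z[c(2, 1, 1, 2, 3), c(2, 1, 1, 2, 3)]),
               tolerance = 1e-12)
  expect_error(box_mean(z, 4))
})

test_that("global means are local region averages with the stated limits", {
  # constant frame: both means equal the constant
  fr <- matrix(0.7, 32, 32)
  phi <- sdf_from_mask(disk_mask(32, 16, 16, 8))
  gm <- compute_global_means(fr, phi, k = 9)
  expect_equal(gm$c1, fr, tolerance = 1e-10)
  expect_equal(gm$c2, fr, tolerance = 1e-10)

  # two-region phantom, pixel 5 px inside the disk
  mask <- disk_mask(64, 32, 32, 12)
  fr2 <- two_region_phantom(mask, 0.8, 0.2)
  phi2 <- sdf_from_mask(mask)
  gm2 <- compute_global_means(fr2, phi2, k = 9)
  expect_equal(gm2$c1[33, 33 - 7], 0.8, tolerance = 0.02)  # 5 px inside
  expect_equal(gm2$c2[33, 2], 0.2, tolerance = 0.02)       # deep outside

  # eps -> 0, k -> frame size: plain region means (two-phase constants)
  gm3 <- compute_global_means(fr2, phi2, k = 63, eps = 1e-6)
  expect_equal(mean(gm3$c1[mask]), mean(fr2[mask]), tolerance = 0.01)
  expect_equal(mean(gm3$c2[!mask]), mean(fr2[!mask]), tolerance = 0.01)
})

test_that("local means capture the difference image and ignore offsets", {
  fr <- matrix(0.4, 32, 32)
  phi <- sdf_from_mask(disk_mask(32, 16, 16, 8))
  lm <- compute_local_means(fr, phi, k = 9)
  expect_equal(max(abs(lm$d1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(lm$d2)), 0, tolerance = 1e-12)

  # vertical step edge: D is antisymmetric, d1/d2 take opposite signs
  step <- matrix(rep(c(rep(0.2, 16), rep(0.8, 16)), each = 32), 32)
  phi_s <- sdf_from_mask(matrix(rep(1:32 > 16, each = 32), 32))
  lm2 <- compute_local_means(step, phi_s, k = 9)
  band <- abs(phi_s) < 3
  expect_lt(max(lm2$d2 * lm2$d1 * band), 1e-10)  # opposite signs on band
  expect_gt(max(abs(lm2$D)), 0.1)

  # adding a constant leaves D (hence d1, d2) unchanged
  lm3 <- compute_local_means(step + 0.1, phi_s, k = 9)
  expect_equal(lm3$D, lm2$D, tolerance = 1e-12)
  expect_equal(lm3$d1, lm2$d1, tolerance = 1e-12)
})

test_that("curvature matches closed forms", {
  g <- coord_grids(64)
  # planar level set: zero curvature away from the borders
  kpl <- curvature(g$x - 20.3)
  expect_lt(max(abs(kpl[5:60, 5:60])), 1e-8)

  # disk of radius 15: |kappa| = 1/15 on the zero level; the sign flips
  # between the disk (inside-positive => negative kappa) and its complement
  # the mean over the zero-level band averages out rasterization spikes
  phi <- sdf_from_mask(disk_mask(64, 32, 32, 15))
  kd <- curvature(phi)
  sel <- abs(phi) < 0.8
  expect_equal(abs(mean(kd[sel])), 1 / 15, tolerance = 0.2)
  expect_lt(mean(kd[sel]), 0)
  kc <- curvature(sdf_from_mask(!disk_mask(64, 32, 32, 15)))
  expect_gt(mean(kc[sel]), 0)
  expect_equal(mean(kc[sel]), -mean(kd[sel]), tolerance = 0.15)
})

test_that("evolution is stationary at a clean boundary", {
  mask <- disk_mask(64, 32, 32, 12)
  fr <- two_region_phantom(mask, 0.8, 0.2)
  ev <- evolve_level_set(fr, init_level_set(mask, 10),
                         cfg = segmentation_config(n_steps = 100))
  expect_lt(sum((ev$ls$phi >= 0) != mask), 3)   # zero level barely moves
})

test_that("evolution recovers the boundary from an offset initialization", {
  mask <- disk_mask(64, 32, 32, 12)
  fr <- two_region_phantom(mask, 0.8, 0.2)
  init <- disk_mask(64, 37, 32, 12)             # 5 px offset
  ev <- evolve_level_set(fr, init_level_set(init, 10),
                         cfg = segmentation_config(n_steps = 300))
  expect_gte(dice(ev$ls$phi >= 0, mask), 0.98)
  expect_lte(max(diff(ev$trace$energy)), 1e-6)  # non-increasing energy
  expect_true(all(diff(ev$trace$objective) <= 1e-6))
})

test_that("the Dirac mass evolves smoothly (no per-step spikes)", {
  set.seed(402)
  mask <- disk_mask(48, 24, 24, 10)
  fr <- two_region_phantom(mask, 0.8, 0.2, sigma = 0.05)
  phi <- init_level_set(disk_mask(48, 26, 23, 10), 10)$phi
  masses <- sum(dirac_eps(phi, 1.5))
  for (i in 1:30) {
    ev <- evolve_level_set(fr, raw_level_set(phi, 10), cfg =
                             segmentation_config(n_steps = 1,
                                                 reinit_every = 0))
    phi <- ev$ls$phi
    masses <- c(masses, sum(dirac_eps(phi, 1.5)))
  }
  expect_lt(max(abs(diff(masses)) / masses[-length(masses)]), 0.05)
})

test_that("the local term only acts near the contour band", {
  set.seed(403)
  mask <- disk_mask(64, 32, 32, 12)
  fr <- two_region_phantom(mask, 0.8, 0.2, sigma = 0.1)
  phi <- sdf_from_mask(mask)
  cfg <- segmentation_config()
  lm <- compute_local_means(fr, phi, cfg$k, cfg$eps, cfg$mean_floor)
  fl <- max(cfg$mean_floor, (2 * estimate_sigma0(fr))^2)
  local_field <- dirac_eps(phi, cfg$eps) *
    ((lm$D - lm$d2)^2 / pmax(lm$d2^2, fl) -
     (lm$D - lm$d1)^2 / pmax(lm$d1^2, fl))
  band <- abs(phi) < 3
  interior <- abs(phi) > 8
  expect_gt(mean(abs(local_field[band])), 10 * mean(abs(local_field[interior])))
})

test_that("strict_eq9 switches the printed asymmetric energy", {
  mask <- disk_mask(32, 16, 16, 7)
  fr <- two_region_phantom(mask, 0.8, 0.2)
  phi <- sdf_from_mask(mask)
  e_sym <- region_energy(fr, phi, segmentation_config())
  e_strict <- region_energy(fr, phi, segmentation_config(strict_eq9 = TRUE))
  expect_false(isTRUE(all.equal(e_sym, e_strict)))
})
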