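test_that("histogram models match hand counts", {
  # 5x5 frame, 3x3 foreground block with intensities {0.1 x4, 0.6 x5}
  fr <- matrix(0.3, 5, 5)
  fr[2:4, 2:4] <- c(0.1, 0.6, 0.1, 0.6, 0.1, 0.6, 0.1, 0.6, 0.6)
  mask <- matrix(FALSE, 5, 5); mask[2:4, 2:4] <- TRUE
  ls <- init_level_set(mask, th = 3)
  mod <- build_models(fr, ls, r = 2, edges = c(0, 0.5, 1))
  expect_equal(mod$fd, c(4 / 9, 5 / 9))
  expect_equal(sum(mod$bd), 1)

  # single-intensity foreground occupies exactly one bin
  fr2 <- matrix(0.2, 16, 16); fr2[square_mask(16, 8, 8, 3)] <- 0.9
  ls2 <- init_level_set(square_mask(16, 8, 8, 3), th = 4)
  mod2 <- build_models(fr2, ls2, r = 8)
  expect_equal(mod2$fd, c(rep(0, 7), 1))   # 0.9 falls in bin 8 of 8
  expect_equal(sum(mod2$fd), 1)

  expect_error(build_models(fr, ls, r = 1), "r must be")
})

test_that("crisp region distributions reduce to the model histograms", {
  set.seed(201)
  fr <- matrix(runif(32 * 32), 32)
  ls <- init_level_set(disk_mask(32, 16, 16, 7), th = 6)
  mod <- build_models(fr, ls, r = 16)
  d <- region_distributions(fr, ls, r = 16, eps = 1e-9)
  expect_equal(d$fg, mod$fd, tolerance = 1e-9)
  expect_equal(d$bg, mod$bd, tolerance = 1e-9)
  expect_equal(sum(d$fg), 1, tolerance = 1e-12)
  expect_equal(sum(d$bg), 1, tolerance = 1e-12)
})

test_that("a boundary pixel with phi = 0 contributes half mass", {
  phi <- matrix(-1, 8, 8)
  phi[4, 4] <- 2; phi[4, 5] <- 0      # interior pixel plus boundary pixel
  fr <- matrix(0.1, 8, 8)
  fr[4, 4] <- 0.95; fr[4, 5] <- 0.55  # distinct bins
  d <- region_distributions(fr, raw_level_set(phi, th = 5), r = 10,
                            eps = 1.5)
  b_int <- findInterval(0.95, seq(0, 1, 0.1), all.inside = TRUE)
  b_bnd <- findInterval(0.55, seq(0, 1, 0.1), all.inside = TRUE)
  # interior pixel weight H(2) vs boundary H(0) = 1/2
  expect_equal(d$fg[b_bnd] / d$fg[b_int],
               0.5 / heaviside_eps(2, 1.5), tolerance = 1e-12)
})

test_that("Bhattacharyya energy matches hand values and its bounds", {
  mkdist <- function(fg, bg) structure(
    list(fg = fg, bg = bg, Ff = 1, Fb = 1, r = length(fg),
         edges = seq(0, 1, length.out = length(fg) + 1)),
    class = "region_dist")
  mkmod <- function(fd, bd) structure(
    list(fd = fd, bd = bd, r = length(fd),
         edges = seq(0, 1, length.out = length(fd) + 1)),
    class = "region_models")

  # perfect match: 1 + gamma
  p <- c(0.25, 0.75)
  expect_equal(bhattacharyya_energy(mkdist(p, p), mkmod(p, p), gamma = 1), 2)
  # disjoint supports: 0
  expect_equal(bhattacharyya_energy(mkdist(c(1, 0), c(1, 0)),
                                    mkmod(c(0, 1), c(0, 1)), gamma = 1), 0)
  # hand arithmetic, gamma = 0
  e <- bhattacharyya_energy(mkdist(c(0.5, 0.5), c(1, 0)),
                            mkmod(c(0.25, 0.75), c(1, 0)), gamma = 0)
  expect_equal(e, sqrt(0.125) + sqrt(0.375))
  expect_equal(e, 0.96593, tolerance = 1e-5)

  expect_error(bhattacharyya_energy(mkdist(p, p), mkmod(c(1, 0, 0), p)),
               "mismatch")

  # bounds and consistent-permutation invariance on random distributions
  set.seed(202)
  for (i in 1:25) {
    r <- sample(2:12, 1)
    gamma <- runif(1, 0, 2)
    fg <- runif(r); fg <- fg / sum(fg)
    bg <- runif(r); bg <- bg / sum(bg)
    fd <- runif(r); fd <- fd / sum(fd)
    bd <- runif(r); bd <- bd / sum(bd)
    e <- bhattacharyya_energy(mkdist(fg, bg), mkmod(fd, bd), gamma)
    expect_gte(e, 0); expect_lte(e, 1 + gamma + 1e-12)
    perm <- sample(r)
    ep <- bhattacharyya_energy(mkdist(fg[perm], bg[perm]),
                               mkmod(fd[perm], bd[perm]), gamma)
    expect_equal(ep, e, tolerance = 1e-12)
  }
})

test_that("pixel weights follow the model/candidate bin ratios", {
  mkmod <- function(fd, bd, edges) structure(
    list(fd = fd, bd = bd, r = length(fd), edges = edges),
    class = "region_models")
  mkdist <- function(fg, bg, edges) structure(
    list(fg = fg, bg = bg, Ff = 10, Fb = 5, r = length(fg), edges = edges),
    class = "region_dist")
  edges <- c(0, 0.5, 1)
  fr <- matrix(c(0.25, 0.75), 4, 4)  # alternating bins 1 and 2

  # fd = fg0: unit weights wherever the model has mass
  w <- pixel_weights(fr, mkmod(c(0.3, 0.7), c(1, 0), edges),
                     mkdist(c(0.3, 0.7), c(1, 0), edges))
  expect_true(all(w$h_f == 1))
  expect_equal(w$h_b[1, 1], 1)       # bin 1: sqrt(1/1)
  expect_equal(w$h_b[2, 1], 0)       # bin 2: model mass 0
  expect_equal(w$Ff, 10); expect_equal(w$Fb, 5)

  # hand ratios: fd = (0.8, 0.2), fg0 = (0.5, 0.5)
  w2 <- pixel_weights(fr, mkmod(c(0.8, 0.2), c(0.5, 0.5), edges),
                      mkdist(c(0.5, 0.5), c(0.5, 0.5), edges))
  expect_equal(w2$h_f[1, 1], sqrt(1.6), tolerance = 1e-12)
  expect_equal(w2$h_f[2, 1], sqrt(0.4), tolerance = 1e-12)
  expect_equal(w2$h_f[1, 1], 1.2649, tolerance = 1e-4)

  # zero-denominator bins carry weight 0
  w3 <- pixel_weights(fr, mkmod(c(1, 0), c(1, 0), edges),
                      mkdist(c(0, 1), c(1, 0), edges))
  expect_true(all(w3$h_f == 0))      # bin1: fg0=0 -> 0; bin2: fd=0 -> 0
})

test_that("matching energy peaks at the true translation of a rigid target", {
  set.seed(203)
  g <- coord_grids(48)
  frame1 <- two_region_phantom(square_mask(48, 20, 24, 6), 0.8, 0.3,
                               sigma = 0.02)
  frame2 <- two_region_phantom(square_mask(48, 23, 22, 6), 0.8, 0.3,
                               sigma = 0.02)
  ls <- init_level_set(square_mask(48, 20, 24, 6), th = 8)
  mod <- build_models(frame1, ls, r = 16)
  en <- function(dx, dy) {
    lw <- warp_level_set(ls, affine_pose(c(0, 0, 0, 0, dx, dy)))
    d <- region_distributions(frame2, lw, r = 16, eps = 0.1)
    bhattacharyya_energy(d, mod, gamma = 0.5)
  }
  gr <- expand.grid(dx = -4:4, dy = -4:4)
  gr$e <- mapply(en, gr$dx, gr$dy)
  best <- gr[which.max(gr$e), ]
  expect_equal(best$dx, 3)
  expect_equal(best$dy, -2)
})
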