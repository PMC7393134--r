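# Reduced volume, height/curvature, delta, fits, pair correlations,
# anisometry.

test_that("reduced volume: sphere near 1, spheroid matches the closed form", {
  sph <- sphere_fixture(200)
  expect_equal(reduced_volume(sph), 1, tolerance = 0.02)
  # oblate spheroid semi-axes (1, 1, 0.5): closed-form area and volume
  m <- sphere_fixture(200)
  mid0 <- (m$apical + m$basal) / 2
  scale_to_unit <- 2 / (2.879 + 4.573)
  sq <- m
  sq$apical <- mid0 * scale_to_unit
  sq$basal <- mid0 * scale_to_unit
  sq$apical[, 3] <- sq$apical[, 3] * 0.5
  sq$basal[, 3] <- sq$basal[, 3] * 0.5
  a <- 1
  c0 <- 0.5
  e <- sqrt(1 - c0^2 / a^2)
  area <- 2 * pi * a^2 + pi * (c0^2 / e) * log((1 + e) / (1 - e))
  vol <- 4 / 3 * pi * a^2 * c0
  v_oracle <- 6 * sqrt(pi) * vol / area^(3 / 2)
  expect_equal(reduced_volume(sq), v_oracle, tolerance = 0.025)
  # isoperimetric: v <= 1, decreasing as the shape flattens
  flatter <- sq
  flatter$apical[, 3] <- flatter$apical[, 3] * 0.5
  flatter$basal[, 3] <- flatter$basal[, 3] * 0.5
  expect_lt(reduced_volume(sq), 1)
  expect_lt(reduced_volume(flatter), reduced_volume(sq))
})

test_that("reduced volume decreases monotonically along a spheroid family", {
  m <- sphere_fixture(64)
  mid0 <- (m$apical + m$basal) / 2
  vs <- sapply(c(1, 0.8, 0.6, 0.4), function(cc) {
    sq <- m
    sq$apical <- mid0
    sq$basal <- mid0
    sq$apical[, 3] <- sq$apical[, 3] * cc
    sq$basal[, 3] <- sq$basal[, 3] * cc
    reduced_volume(sq)
  })
  expect_true(all(diff(vs) < 0))
})

test_that("truncated-cone curvature matches the concentric-sphere oracle", {
  sph <- sphere_fixture(64)
  hc <- cell_height_curvature(sph)
  mp <- midplane_surface(sph)
  r_mid <- (3 * mp$volume / (4 * pi))^(1 / 3)
  expect_equal(mean(hc$c), 1 / r_mid, tolerance = 0.05)
  # prism: flat limit has zero curvature
  hcp <- cell_height_curvature(hex_prism_mesh())
  expect_equal(hcp$c, 0)
  # swapping apical and basal flips the sign
  swapped <- sph
  swapped$apical <- sph$basal
  swapped$basal <- sph$apical
  hc2 <- cell_height_curvature(swapped)
  expect_equal(hc2$c, -hc$c, tolerance = 1e-12)
  expect_equal(hc2$h, hc$h, tolerance = 1e-12)
})

test_that("thickness modulation index is signed by the c-h correlation", {
  sph <- sphere_fixture(64)
  expect_equal(thickness_modulation(sph)$delta, 0, tolerance = 0.05)
  hc <- data.frame(h = c(1, 1, 1), c = c(0.1, 0.2, 0.3))
  expect_equal(thickness_modulation(hc)$delta, 0)
  # correlated: taller cells at higher curvature -> p = +1
  hc_pos <- data.frame(h = c(1, 1.2, 1.6, 2), c = c(0, 0.1, 0.25, 0.4))
  tm <- thickness_modulation(hc_pos)
  expect_equal(tm$p, 1)
  expect_equal(tm$delta, (2 - 1) / 2 / mean(hc_pos$h), tolerance = 1e-12)
  # anticorrelated -> p = -1, delta < 0
  hc_neg <- hc_pos
  hc_neg$c <- -hc_neg$c
  expect_equal(thickness_modulation(hc_neg)$delta, -tm$delta,
               tolerance = 1e-12)
})

test_that("h(c) fitting recovers exact lines and the collapse transform", {
  cc <- seq(-0.5, 0.5, length.out = 20)
  hc <- data.frame(h = 1.2 + 0.3 * cc, c = cc)
  fit <- hc_fit(hc)
  expect_equal(fit$n, 1.2, tolerance = 1e-12)
  expect_equal(fit$k, 0.3, tolerance = 1e-12)
  # degenerate curvature spread is flagged
  expect_true(hc_fit(data.frame(h = c(1, 2, 3), c = rep(0.2, 3)))$degenerate)
  # the collapse subtracts the flat-epithelium height and rescales c
  ct <- collapse_transform(hc$h, hc$c, alpha = 0.7, beta = 0.5)
  expect_equal(ct$h, hc$h - flat_equilibrium(1.2)$h0, tolerance = 1e-12)
  expect_equal(ct$c, (-0.059 + 0.2 * 0.45) * hc$c, tolerance = 1e-12)
})

test_that("pentagon pair correlation of the dodecahedron is (5, 5, 1)", {
  m <- dodeca_shell()
  g5 <- pair_correlation(m, 5)
  expect_equal(g5$g, c(5, 5, 1))
  expect_equal(sum(g5$g), 12 - 1)  # each other pentagon counted once
  expect_true(all(g5$g >= 0))
  expect_error(pair_correlation(m, 7), "7-gon")
})

test_that("pair-correlation mass balances polygon counts after rearrangement", {
  set.seed(61)
  m <- shell64()
  for (i in 1:25) m <- apply_t1(m, sample(which(t1_legal_all(m)), 1))
  sizes <- lengths(m$cells)
  expect_equal(sum(6 - sizes), 12)
  for (gam in intersect(c(5, 6, 7), unique(sizes))) {
    gt <- pair_correlation(m, gam)
    expect_equal(sum(gt$g), sum(sizes == gam) - 1, tolerance = 1e-9)
  }
})

test_that("gyration-tensor anisometry: square 0, 2:1 rectangle 0.6", {
  sqm <- polygon_face_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                 c(0, 1, 0)))
  expect_equal(anisometry(sqm, 1)$kappa, 0, tolerance = 1e-12)
  rect <- polygon_face_mesh(rbind(c(-1, -0.5, 0), c(1, -0.5, 0),
                                  c(1, 0.5, 0), c(-1, 0.5, 0)))
  an <- anisometry(rect, 1)
  expect_equal(an$kappa, 0.6, tolerance = 1e-12)
  expect_equal(abs(an$long_axis[1]), 1, tolerance = 1e-12)
  # near-planar faces of a real shell: third eigenvalue much smaller
  m <- shell64()
  ev <- anisometry(m, 1)$eigenvalues
  expect_lt(ev[3], 0.2 * ev[2])
})

test_that("morphometrics report bundles consistent fields", {
  sph <- sphere_fixture(64)
  rep <- morphometrics(sph)
  expect_s3_class(rep, "morphometrics_report")
  expect_equal(rep$reduced_volume, reduced_volume(sph))
  expect_false(rep$self_overlap)
  expect_equal(nrow(rep$cells), 64)
  expect_equal(abs(rep$p), 1)
})
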