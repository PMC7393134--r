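# Energy terms and the analytic force field.

test_that("surface energy of a unit cuboid cell follows the tension sum", {
  m <- cube_cell_mesh()
  p <- model_params(alpha = 1, beta = 1, v_lumen = 1)
  # alpha a_a + beta a_b + a_l/2 = 1 + 1 + 4/2
  expect_equal(surface_energy(m, p), 4, tolerance = 1e-12)
  # linearity: doubling all tensions doubles the surface energy
  p2 <- model_params(alpha = 2, beta = 2, v_lumen = 1)
  m2 <- m
  expect_equal(surface_energy(m2, p2) - surface_energy(m, p),
               face_area(m, 1, "apical") + face_area(m, 1, "basal"),
               tolerance = 1e-12)
  pz <- model_params(alpha = 0, beta = 0, v_lumen = 1)
  flat <- m
  flat$basal <- flat$apical  # zero lateral area
  expect_equal(surface_energy(flat, pz), 0)
})

test_that("constraint energy is harmonic in the volume deviations", {
  m <- shell32()
  p <- model_params(1, 1, v_lumen = lumen_volume(m))
  vt <- vapply(seq_along(m$cells), function(i) cell_volume(m, i), numeric(1))
  expect_equal(constraint_energy(m, p, v_cell_target = vt), 0,
               tolerance = 1e-18)
  # lumen off target by 0.1 at K_lumen = 100 contributes (100/2) 0.1^2
  p_off <- model_params(1, 1, v_lumen = lumen_volume(m) + 0.1)
  expect_equal(constraint_energy(m, p_off, v_cell_target = vt), 0.5,
               tolerance = 1e-9)
})

test_that("line-tension energy is gamma (l_a + l_b) summed over junctions", {
  m <- dodeca_shell()
  expect_equal(line_tension_energy(m), 0)
  j <- 4
  u <- m$junctions[j, "u"]
  v <- m$junctions[j, "v"]
  la <- sqrt(sum((m$apical[u, ] - m$apical[v, ])^2))
  lb <- sqrt(sum((m$basal[u, ] - m$basal[v, ])^2))
  m$gamma[j] <- 0.2
  expect_equal(line_tension_energy(m), 0.2 * (la + lb), tolerance = 1e-12)
  # odd in gamma
  m$gamma[j] <- -0.2
  expect_equal(line_tension_energy(m), -0.2 * (la + lb), tolerance = 1e-12)
})

test_that("compiled energy agrees with the plain-R evaluation", {
  set.seed(5)
  m <- shell32()
  m$gamma <- rnorm(nrow(m$junctions), sd = 0.1)
  p <- model_params(1.1, 0.8, v_lumen = lumen_target(32))
  wr <- surface_energy(m, p) + constraint_energy(m, p) +
    line_tension_energy(m)
  expect_equal(total_energy(m, p)$energy, wr, tolerance = 1e-12)
})

test_that("forces are the exact negative energy gradient (finite-difference oracle)", {
  set.seed(6)
  m <- shell32()
  m$gamma <- rnorm(nrow(m$junctions), sd = 0.1)
  # perturb so we are far from any stationary point
  m$apical <- m$apical + 0.01 * matrix(rnorm(length(m$apical)),
                                       nrow(m$apical))
  p <- model_params(1.1, 0.8, v_lumen = lumen_target(32))
  f <- total_force(m, p)
  h <- 1e-6
  idx <- cbind(sample(nrow(f), 40, replace = TRUE),
               sample(3, 40, replace = TRUE))
  nv <- nrow(m$apical)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]
    d <- idx[r, 2]
    bump <- function(s) {
      mm <- m
      if (i <= nv) mm$apical[i, d] <- mm$apical[i, d] + s
      else mm$basal[i - nv, d] <- mm$basal[i - nv, d] + s
      total_energy(mm, p)$energy
    }
    fd <- -(bump(h) - bump(-h)) / (2 * h)
    expect_equal(f[i, d], fd, tolerance = 1e-6)
  }
  # translation invariance of a closed shell: zero net force
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("relaxation drives volumes onto their targets at modulus 100", {
  set.seed(7)
  m <- fixture_shell("small_thomson_dual", n_cells = 32)
  p <- model_params(0.6, 0.6, v_lumen = lumen_target(32), dt = 2e-4)
  tr <- relax_shell(m, p, t_end = 6, log_every = 0)
  vc <- vapply(seq_along(tr$final$cells),
               function(i) cell_volume(tr$final, i), numeric(1))
  expect_true(all(abs(vc - 1) < 0.03))
  # relaxed state: forces are small compared to the initial ones
  f0 <- max(abs(total_force(m, p)))
  f1 <- max(abs(total_force(tr$final, p)))
  expect_lt(f1, 0.05 * f0)
})
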