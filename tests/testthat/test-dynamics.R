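# Schedules, the Euler step, and trajectory-level properties.

test_that("activity schedules follow their temporal profiles", {
  lin <- activity_schedule("linear", 200, t_max = 1000)
  expect_equal(schedule_value(lin, 500), 100)
  expect_equal(schedule_value(lin, 0), 200)
  expect_equal(schedule_value(lin, 1000), 0)
  expect_equal(schedule_value(lin, 1200), 0)  # clipped, never negative
  stp <- activity_schedule("step", 200, t_max = 1000)
  expect_equal(schedule_value(stp, 499.9), 200)
  expect_equal(schedule_value(stp, 500.1), 0)
  cst <- activity_schedule("constant", 7)
  expect_equal(schedule_value(cst, c(0, 123, 1e4)), rep(7, 3))
})

test_that("k_T1 rescaling preserves the per-junction flip probability", {
  # probability k dt / E fixed: k(N) E(300) = k(300) E(N)
  expect_equal(rescale_kt1(200, 300), 200)
  expect_equal(rescale_kt1(200, 64) / (3 * 62), 200 / (3 * 298))
})

test_that("euler_step displaces vertices by force times dt", {
  m <- shell32()
  p <- model_params(1.0, 0.9, v_lumen = lumen_target(32))
  f <- total_force(m, p)
  nv <- nrow(m$apical)
  m2 <- euler_step(m, p, dt = 1e-4)
  expect_equal(m2$apical, m$apical + 1e-4 * f[1:nv, ], tolerance = 1e-14)
  expect_equal(m2$basal, m$basal + 1e-4 * f[nv + 1:nv, ], tolerance = 1e-14)
  expect_equal(m2$time, m$time + 1e-4)
})

test_that("the integrator is first order: two half steps agree to O(dt^2)", {
  m <- shell32()
  p <- model_params(1.0, 0.9, v_lumen = lumen_target(32))
  dt <- 1e-3
  full <- euler_step(m, p, dt = dt)
  half <- euler_step(euler_step(m, p, dt = dt / 2), p, dt = dt / 2)
  dev_full_half <- max(abs(full$apical - half$apical))
  # halving dt again shrinks the disagreement ~4x (second-order difference)
  q1 <- euler_step(m, p, dt = dt / 2)
  q2 <- euler_step(euler_step(m, p, dt = dt / 4), p, dt = dt / 4)
  dev_half_quarter <- max(abs(q1$apical - q2$apical))
  expect_lt(dev_full_half, 1e-3)
  expect_lt(dev_half_quarter, 0.4 * dev_full_half)
})

test_that("a near-equilibrium state barely moves in one step", {
  set.seed(8)
  m <- fixture_shell("small_thomson_dual", n_cells = 32)
  p <- model_params(1.0, 1.0, v_lumen = lumen_target(32), dt = 2e-4)
  rel <- relax_shell(m, p, t_end = 8, log_every = 0)$final
  m2 <- euler_step(rel, p)
  expect_lt(max(abs(m2$apical - rel$apical)), 1e-6)
})

test_that("passive trajectories have non-increasing energy", {
  set.seed(9)
  m <- fixture_shell("small_thomson_dual", n_cells = 32)
  p <- model_params(0.8, 0.7, v_lumen = lumen_target(32), dt = 2e-4)
  tr <- relax_shell(m, p, t_end = 4, log_every = 0.2)
  expect_true(all(diff(tr$energy$w) <= 1e-8))
})

test_that("trajectories are bit-reproducible given the seed", {
  m <- shell32()
  p <- model_params(0.7, 0.5, v_lumen = lumen_target(32))
  sched <- activity_schedule("linear", rescale_kt1(200, 32), t_max = 2)
  run <- function() {
    set.seed(1234)
    run_protocol(m, p, scheme = "threshold", schedule = sched, t_end = 2,
                 pre_relax = 0.2, snapshot_every = 0)
  }
  t1 <- run()
  t2 <- run()
  expect_identical(t1$final$apical, t2$final$apical)
  expect_identical(t1$final$basal, t2$final$basal)
  expect_identical(t1$final$cells, t2$final$cells)
  expect_identical(t1$energy, t2$energy)
  expect_equal(t1$n_t1, t2$n_t1)
})
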