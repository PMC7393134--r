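# T1 legality, the mechanical flip, both selection schemes, and the OU
# tension process.

test_that("random legal T1s preserve every topological invariant", {
  set.seed(31)
  m <- shell64()
  adj_key <- function(mm) sort(paste(pmin(mm$junctions[, 3], mm$junctions[, 4]),
                                     pmax(mm$junctions[, 3], mm$junctions[, 4])))
  for (i in 1:120) {
    legal <- which(t1_legal_all(m))
    j <- sample(legal, 1)
    before <- lengths(m$cells)
    m2 <- apply_t1(m, j)
    dd <- lengths(m2$cells) - before
    expect_equal(sort(dd[dd != 0]), c(-1, -1, 1, 1))
    m <- m2
  }
  v <- validate_mesh(m)
  expect_true(v$ok)
  expect_equal(v$n_junctions, 3 * (64 - 2))
  expect_equal(sum(6 - lengths(m$cells)), 12)  # defect sum rule
})

test_that("a flip followed by the reverse flip restores the adjacency", {
  m <- shell32()
  adj <- function(mm) sort(paste(pmin(mm$junctions[, 3], mm$junctions[, 4]),
                                 pmax(mm$junctions[, 3], mm$junctions[, 4])))
  j <- which(t1_legal_all(m))[3]
  u <- m$junctions[j, "u"]
  v <- m$junctions[j, "v"]
  m2 <- apply_t1(m, j)
  j2 <- which(m2$junctions[, "u"] == min(u, v) &
                m2$junctions[, "v"] == max(u, v))
  m3 <- apply_t1(m2, j2)
  expect_identical(adj(m3), adj(m))
})

test_that("illegal flips are refused: triangles, duplicate adjacencies, dwell", {
  set.seed(32)
  # manufacture a triangular cell by shrinking a 4-sided one
  m <- shell64()
  repeat {
    sizes <- lengths(m$cells)
    quad_junc <- which(t1_legal_all(m) &
                         (sizes[m$junctions[, "cell_uv"]] == 4 |
                            sizes[m$junctions[, "cell_vu"]] == 4))
    if (length(quad_junc) > 0) {
      m <- apply_t1(m, quad_junc[1])
      if (any(lengths(m$cells) == 3)) break
    } else {
      m <- apply_t1(m, sample(which(t1_legal_all(m)), 1))
    }
  }
  tri <- which(lengths(m$cells) == 3)[1]
  on_tri <- which(m$junctions[, "cell_uv"] == tri |
                    m$junctions[, "cell_vu"] == tri)
  expect_true(all(!t1_legal_all(m)[on_tri]))
  expect_error(apply_t1(m, on_tri[1]), "not legal")

  # duplicate-adjacency refusal: flip one edge, then a junction whose
  # gaining pair is the now-adjacent pair must be illegal
  m <- shell32()
  j <- which(t1_legal_all(m))[1]
  m2 <- apply_t1(m, j)
  cd <- attr(m2, "t1_cells")[c("C", "D")]
  vmap <- epivertex:::vertex_cells_map(m2$cells)
  found <- FALSE
  for (jj in seq_len(nrow(m2$junctions))) {
    g <- epivertex:::t1_gaining_cells(m2, jj, vmap)
    if (!any(is.na(g)) && setequal(g, cd) &&
        !setequal(c(m2$junctions[jj, 3:4]), cd)) {
      expect_false(t1_legal(m2, jj))
      found <- TRUE
    }
  }
  # dwell blocking: junctions of dwell-involved cells are ineligible
  dc <- as.integer(m2$junctions[1, 3:4])
  blocked <- which(m2$junctions[, "cell_uv"] %in% dc |
                     m2$junctions[, "cell_vu"] %in% dc)
  lg <- t1_legal_all(m2, dwell_cells = dc)
  expect_true(all(!lg[blocked]))
})

test_that("generic junctions between large cells are flippable", {
  m <- shell64()
  sizes <- lengths(m$cells)
  hex <- which(sizes[m$junctions[, "cell_uv"]] >= 6 &
                 sizes[m$junctions[, "cell_vu"]] >= 6)
  expect_true(any(t1_legal_all(m)[hex]))
})

test_that("threshold selection flips short junctions surely, long ones at rate k/E", {
  set.seed(33)
  m <- shell32()
  p <- model_params(1, 1, v_lumen = lumen_target(32))
  f <- epivertex:::mesh_flat(m)
  mids <- cpp_mid_lengths(f$pos, f$nv, f$junc)
  expect_true(all(mids > p$delta_l))  # fixture has no short junctions
  # k = 0: nothing is selected
  expect_length(active_t1_attempts(m, 0, p), 0)
  # shrink one junction below threshold: always selected
  u <- m$junctions[10, "u"]
  v <- m$junctions[10, "v"]
  mshort <- m
  mid_a <- colMeans(m$apical[c(u, v), ])
  mid_b <- colMeans(m$basal[c(u, v), ])
  shift <- function(x, mid, fr) mid + fr * (x - mid)
  mshort$apical[u, ] <- shift(m$apical[u, ], mid_a, 0.1)
  mshort$apical[v, ] <- shift(m$apical[v, ], mid_a, 0.1)
  mshort$basal[u, ] <- shift(m$basal[u, ], mid_b, 0.1)
  mshort$basal[v, ] <- shift(m$basal[v, ], mid_b, 0.1)
  for (r in 1:5) expect_true(10 %in% active_t1_attempts(mshort, 0, p))
  # long junctions: empirical rate matches k dt / E
  k <- 500
  n_rep <- 2000
  hits <- sum(replicate(n_rep, length(active_t1_attempts(m, k, p))))
  expected <- n_rep * k * p$dt  # E junctions each with prob k dt / E
  expect_lt(abs(hits - expected), 5 * sqrt(expected))
})

test_that("fluctuation-scheme T1s trigger only below the 0.01 length", {
  m <- shell32()
  p <- model_params(1, 1, v_lumen = lumen_target(32))
  expect_length(fluctuation_t1_trigger(m, p), 0)
  squeeze <- function(mm, j, fr) {
    u <- mm$junctions[j, "u"]
    v <- mm$junctions[j, "v"]
    for (surf in c("apical", "basal")) {
      mid <- colMeans(mm[[surf]][c(u, v), ])
      mm[[surf]][u, ] <- mid + fr * (mm[[surf]][u, ] - mid)
      mm[[surf]][v, ] <- mid + fr * (mm[[surf]][v, ] - mid)
    }
    mm
  }
  f <- epivertex:::mesh_flat(m)
  mid0 <- cpp_mid_lengths(f$pos, f$nv, f$junc)[7]
  m_at <- function(target) squeeze(m, 7, target / mid0)
  expect_true(7 %in% fluctuation_t1_trigger(m_at(0.009), p))
  expect_false(7 %in% fluctuation_t1_trigger(m_at(0.011), p))
})

test_that("OU tensions decay deterministically, stay centred, reach variance sigma^2", {
  dt <- 1e-3
  tau <- 1
  # sigma = 0: pure exponential decay within integrator error
  g <- 1
  for (i in 1:1000) g <- ou_update(g, tau, 0, dt)
  expect_equal(g, exp(-1), tolerance = 2e-3)
  # stationary statistics at sigma = 0.15 (long-run variance sigma^2)
  set.seed(34)
  sigma <- 0.15
  n <- 400
  g <- numeric(n)
  burn <- 5000   # 5 tau
  keep <- 20000  # thinned samples below
  samples <- numeric(0)
  for (i in seq_len(burn + keep)) {
    g <- ou_update(g, tau, sigma, dt)
    if (i > burn && i %% 500 == 0) samples <- c(samples, g)
  }
  expect_equal(mean(samples), 0, tolerance = 0.01)
  expect_equal(stats::var(samples), sigma^2, tolerance = 0.1 * sigma^2)
})
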