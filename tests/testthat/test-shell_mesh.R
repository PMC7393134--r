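# Geometry and structural invariants of the paired apical/basal mesh.

test_that("dodecahedral and Thomson-dual shells satisfy the closed-shell counts", {
  m <- dodeca_shell()
  v <- validate_mesh(m)
  expect_true(v$ok)
  expect_equal(v$n_vertices, 20)
  expect_equal(v$n_junctions, 30)
  expect_true(v$euler_ok)

  m32 <- shell32()
  v32 <- validate_mesh(m32)
  expect_true(v32$ok)
  # 3-valent sphere tiling: E = 3(N - 2), V = 2(N - 2)
  expect_equal(v32$n_junctions, 3 * (32 - 2))
  expect_equal(v32$n_vertices, 2 * (32 - 2))
})

test_that("validation names offending vertices of a non-3-valent mesh", {
  # square-pyramid surface: the apex vertex is 4-valent
  pts <- rbind(c(0, 0, 1), c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0),
               c(1, -1, 0))
  cells <- list(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2),
                c(5, 4, 3, 2))
  m <- structure(list(apical = pts, basal = pts * 1.5, cells = cells,
                      junctions = build_junctions(cells),
                      gamma = numeric(8), time = 0),
                 class = "shell_mesh")
  v <- validate_mesh(m)
  expect_false(v$ok)
  expect_true(any(grepl("vertex 1 has valence 4", v$problems)))
})

test_that("face areas match closed forms and the fan-triangle oracle", {
  expect_equal(face_area(cube_cell_mesh(), 1, "apical"), 1)
  expect_equal(face_area(hex_prism_mesh(s = 1), 1, "apical"), 3 * sqrt(3) / 2,
               tolerance = 1e-12)
  # degenerate face: all vertices coincident
  deg <- polygon_face_mesh(matrix(1, 4, 3))
  expect_equal(face_area(deg, 1, "apical"), 0)
  # non-planar quad equals the sum of its four centroid-fan triangle areas
  q <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0.1), c(0, 1, 0))
  g <- colMeans(q)
  tri_area <- function(a, b, c) {
    n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
           (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
           (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    sqrt(sum(n^2)) / 2
  }
  oracle <- sum(sapply(1:4, function(k)
    tri_area(g, q[k, ], q[k %% 4 + 1, ])))
  expect_equal(polygon_area(q), oracle, tolerance = 1e-14)
})

test_that("cell volumes match prism closed forms and flip sign on reversal", {
  expect_equal(cell_volume(cube_cell_mesh(), 1), 1, tolerance = 1e-14)
  # hexagonal prism with unit volume: height 1/a for a = (3 sqrt(3)/2) s^2
  s <- 0.7
  a <- 3 * sqrt(3) / 2 * s^2
  m <- hex_prism_mesh(s = s, h = 1 / a)
  expect_equal(cell_volume(m, 1), 1, tolerance = 1e-12)
  flipped <- m
  flipped$cells[[1]] <- rev(flipped$cells[[1]])
  expect_equal(cell_volume(flipped, 1), -1, tolerance = 1e-12)
})

test_that("lumen volume matches construction and the sphere closed form", {
  set.seed(3)
  m <- build_initial_shell(32, v_lumen = 5)
  expect_equal(lumen_volume(m), 5, tolerance = 1e-9)
  # triangulated sphere of radius r_in encloses (4/3) pi r^3 up to the
  # polyhedral deficit, which shrinks with refinement
  sph <- sphere_fixture(200)
  expect_equal(lumen_volume(sph), 4 / 3 * pi * 2.879^3, tolerance = 0.03)
  # degenerate flat apical surface
  flat <- dodeca_shell()
  flat$apical[, 3] <- 0
  expect_lt(abs(lumen_volume(flat)), 1e-9)
})

test_that("midplane of concentric spheres lies at the mean radius", {
  sph <- sphere_fixture(200)
  mp <- midplane_surface(sph)
  expect_gt(mp$area, 0)
  expect_gt(mp$volume, 0)
  r_mid <- (3 * mp$volume / (4 * pi))^(1 / 3)
  expect_equal(r_mid, (2.879 + 4.573) / 2, tolerance = 0.02)
  # apical == basal => midplane identical to both
  m <- dodeca_shell()
  m$basal <- m$apical
  mp2 <- midplane_surface(m)
  expect_identical(mp2$vertices, m$apical)
})

test_that("topological distance is a BFS metric on the cell adjacency graph", {
  m <- dodeca_shell()
  expect_equal(topological_distance(m, 1, 1), 0)
  nb <- m$junctions[m$junctions[, "cell_uv"] == 1, "cell_vu"][1]
  expect_equal(topological_distance(m, 1, nb), 1)
  d <- sapply(1:12, function(i) topological_distance(m, 1, i))
  expect_equal(max(d), 3)  # antipodal pentagon on the dodecahedron
  expect_equal(sort(unique(d)), 0:3)
})

test_that("self-overlap screen flags pushed-through walls only", {
  m <- shell32()
  expect_false(detect_self_overlap(m))
  bad <- m
  # push one basal vertex through the opposite wall
  bad$basal[1, ] <- -1.2 * bad$basal[1, ]
  expect_true(detect_self_overlap(bad))
})

test_that("enclosed space is conserved and geometry is rigid-motion invariant", {
  m <- shell32()
  vc <- sum(vapply(seq_along(m$cells), function(i) cell_volume(m, i),
                   numeric(1)))
  basal_encl <- sum(vapply(m$cells, function(ids)
    epivertex:::polygon_fan_volume(m$basal[ids, , drop = FALSE]), numeric(1)))
  expect_equal(vc + lumen_volume(m), basal_encl, tolerance = 1e-9)

  mr <- rigid_motion(m, seed = 99)
  expect_equal(face_area(mr, 5, "apical"), face_area(m, 5, "apical"),
               tolerance = 1e-12)
  expect_equal(face_area(mr, 7, "lateral"), face_area(m, 7, "lateral"),
               tolerance = 1e-12)
  expect_equal(cell_volume(mr, 3), cell_volume(m, 3), tolerance = 1e-12)
})
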