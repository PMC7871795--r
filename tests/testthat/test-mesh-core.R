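test_that("mesh construction validates the geometric invariants", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_s3_class(triangle_mesh(v, rbind(c(1, 2, 3))), "triangle_mesh")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 2))), "repeats")
  expect_error(triangle_mesh(rbind(v, c(0.5, -1, 0)), rbind(c(1, 2, 3), c(1, 2, 4))),
               "orientation|non-manifold")
  vz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(triangle_mesh(vz, rbind(c(1, 2, 3))), "zero-area")
})

test_that("vertex areas are a third of incident face areas and sum to the surface area", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  m <- triangle_mesh(v, rbind(c(1, 2, 3)))
  expect_equal(vertex_areas(m), rep(sqrt(3) / 12, 3), tolerance = 1e-12)

  # two disjoint triangles: areas stay local
  v2 <- rbind(v, v + matrix(rep(c(10, 0, 0), each = 3), 3))
  v2[5, ] <- v2[5, ] + c(1, 0, 0)  # second triangle twice as wide
  m2 <- triangle_mesh(v2, rbind(c(1, 2, 3), c(4, 5, 6)))
  a2 <- vertex_areas(m2)
  fa <- face_areas(m2)
  expect_equal(a2[1:3], rep(fa[1] / 3, 3))
  expect_equal(a2[4:6], rep(fa[2] / 3, 3))

  s <- icosphere(3, 1)
  expect_equal(sum(vertex_areas(s)), surface_area(s), tolerance = 1e-12)
  expect_lt(abs(surface_area(s) - 4 * pi) / (4 * pi), 0.01)
})

test_that("cotangent stiffness annihilates constants and matches umbrella weights on a flat grid", {
  for (m in list(icosphere(2, 7), sheet_mesh(30, 24, 3), bumpy_sphere(4))) {
    K <- laplace_operators(m)$stiffness
    expect_lt(max(abs(K %*% rep(1, nrow(m$vertices)))), 1e-12)
  }
  # interior vertex of a unit right-triangle grid: 5-point-like stencil
  m <- sheet_mesh(6, 6, 1)
  K <- as.matrix(laplace_operators(m)$stiffness)
  ctr <- which(m$vertices[, 1] == 3 & m$vertices[, 2] == 3)
  row <- K[ctr, ]
  nb <- which(row != 0)
  expect_equal(unname(row[ctr]), 4)
  off <- m$vertices[setdiff(nb, ctr), 1:2, drop = FALSE] -
    matrix(rep(c(3, 3), each = length(nb) - 1), ncol = 2)
  expect_true(all(rowSums(abs(off)) == 1))        # diagonals carry zero weight
  expect_equal(unname(row[setdiff(nb, ctr)]), rep(-1, 4))
  # linear functions are discrete-harmonic on the flat interior
  lin <- m$vertices[, 1] + 2 * m$vertices[, 2]
  interior <- m$vertices[, 1] > 0 & m$vertices[, 1] < 6 &
    m$vertices[, 2] > 0 & m$vertices[, 2] < 6
  expect_lt(max(abs((K %*% lin)[interior])), 1e-12)
})

test_that("signed mean curvature follows the concave-positive convention", {
  # vertex-transitive sphere: exactly constant -1/r
  m0 <- icosphere(0, 2)
  expect_equal(mean_curvature(m0), rep(-1 / 2, 12), tolerance = 1e-10)
  # subdivided sphere: -1/r up to the valence-5 discretization ripple
  s <- icosphere(3, 10)
  h <- mean_curvature(s)
  a <- vertex_areas(s)
  expect_lt(abs(sum(a * h) / sum(a) + 1 / 10) * 10, 0.02)
  expect_gt(mean(abs(h + 1 / 10) * 10 < 0.05), 0.95)
  # flat sheet: exactly zero, boundary included
  expect_lt(max(abs(mean_curvature(sheet_mesh(30, 24, 3)))), 1e-12)
  # inward dent: positive at the bottom, negative on the rim
  d <- dent_sheet(cbind(40, 30), depths = 5, width = 6)
  hd <- mean_curvature(d$mesh)
  expect_gt(hd[d$centers], 0)
  # a convex rim ring exists around the dent (exact radius depends on the
  # interplay of radial and azimuthal curvature on the steep profile)
  r <- sqrt((d$base$vertices[, 1] - 40)^2 + (d$base$vertices[, 2] - 30)^2)
  expect_lt(min(hd[r > 9 & r < 18]), 0)
})

test_that("graph geodesics match a Floyd-Warshall oracle and the triangle inequality", {
  m <- bumpy_sphere(11, subdivisions = 2)      # 162 vertices
  D <- oracle_floyd_warshall(m)
  for (src in c(1L, 57L, 160L)) {
    d <- geodesic_distance(m, src)
    expect_equal(d, D[src, ], tolerance = 1e-10)
  }
  set.seed(5)
  idx <- matrix(sample.int(nrow(m$vertices), 60, replace = TRUE), ncol = 3)
  expect_true(all(D[idx[, 1:2]] + D[idx[, 2:3]] >=
                  D[idx[, c(1, 3)]] - 1e-9))
  # basics
  expect_equal(geodesic_distance(m, 3)[3], 0)
  # path embedded on a line
  line <- suppressWarnings(triangle_mesh(
    cbind(c(0, 1, 2, 3, 0.5, 1.5, 2.5), c(0, 0, 0, 0, 1, 1, 1), 0),
    rbind(c(1, 2, 5), c(2, 6, 5), c(2, 3, 6), c(3, 7, 6), c(3, 4, 7))))
  expect_equal(geodesic_distance(line, 1)[1:4], 0:3)
  # multiple sources: nearest one wins
  d2 <- geodesic_distance(m, c(1L, 80L))
  expect_equal(d2, pmin(D[1, ], D[80, ]), tolerance = 1e-10)
})

test_that("Fiedler length measures elongation and matches a dense eigen oracle", {
  tu <- tube_mesh(10, 16, r = 5, len = 100)
  ops <- laplace_operators(tu)
  sd_ <- shape_descriptors(tu, ops)
  expect_lt(abs(sd_$fiedler_length - 100) / 100, 0.1)
  expect_equal(sd_$surface_area, surface_area(tu))

  # dense generalized eigendecomposition oracle
  mdiag <- Matrix::diag(ops$mass)
  A <- diag(1 / sqrt(mdiag)) %*% as.matrix(ops$stiffness) %*% diag(1 / sqrt(mdiag))
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam2 <- rev(ev$values)[2]
  fv <- fiedler_vector(tu, ops)
  expect_equal(fv$value, lam2, tolerance = 1e-8)
  # the eigenvector varies along the axis: extrema sit on opposite end rings
  # (vertices within a ring are tied, so compare positions, not indices)
  z_ext <- sort(tu$vertices[c(which.min(fv$vector), which.max(fv$vector)), 3])
  expect_equal(z_ext, c(0, 100), tolerance = 1e-9)
  # sphere: FL close to the antipodal geodesic pi * r
  s <- icosphere(2, 10)
  expect_lt(abs(fiedler_length(s) - pi * 10) / (pi * 10), 0.08)
})

test_that("Fiedler length is invariant under rigid motion and vertex relabeling", {
  tu <- bumpy_sphere(21, subdivisions = 2, amp = 6)   # generic: simple eigenvalue
  fl <- fiedler_length(tu)
  # rigid motion
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tu_rot <- triangle_mesh(tu$vertices %*% Rz + matrix(rep(c(5, -3, 11),
                          each = nrow(tu$vertices)), ncol = 3), tu$faces)
  expect_equal(fiedler_length(tu_rot), fl, tolerance = 1e-9)
  # relabeling
  set.seed(8)
  perm <- sample.int(nrow(tu$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  tu_perm <- triangle_mesh(tu$vertices[perm, ],
                           matrix(inv[tu$faces], ncol = 3))
  expect_equal(fiedler_length(tu_perm), fl, tolerance = 1e-9)
  # disconnected mesh errors
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 0), c(6, 5, 0), c(5, 6, 0))
  m2 <- triangle_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_error(fiedler_vector(m2), "disconnected")
})
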