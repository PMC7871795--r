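# Shared fixtures: small meshes and constructed depth fields.

# open cylinder tube along z, radius r, length len (no caps)
tube_mesh <- function(n_around = 12, n_along = 18, r = 5, len = 100) {
  th <- seq(0, 2 * pi, length.out = n_around + 1)[-(n_around + 1)]
  zs <- seq(0, len, length.out = n_along)
  v <- cbind(rep(r * cos(th), n_along), rep(r * sin(th), n_along),
             rep(zs, each = n_around))
  f <- NULL
  idx <- function(i, j) (j - 1) * n_around + i
  for (j in seq_len(n_along - 1)) {
    for (i in seq_len(n_around)) {
      i2 <- if (i == n_around) 1L else i + 1L
      f <- rbind(f, c(idx(i, j), idx(i2, j), idx(i2, j + 1)),
                 c(idx(i, j), idx(i2, j + 1), idx(i, j + 1)))
    }
  }
  triangle_mesh(v, f)
}

# icosphere with smooth random radial bumps: a generic curved mesh with
# no symmetry, used for oracle-equivalence and invariance checks
bumpy_sphere <- function(seed, subdivisions = 2, radius = 20, amp = 2) {
  set.seed(seed)
  m <- icosphere(subdivisions, radius)
  nb <- 6
  dirs <- matrix(rnorm(3 * nb), nb, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  u <- m$vertices / radius
  bump <- numeric(nrow(u))
  for (k in seq_len(nb))
    bump <- bump + runif(1, -amp, amp) * exp(-(2 * acos(pmin(1, pmax(-1, u %*% dirs[k, ]))))^2)
  triangle_mesh(m$vertices * (1 + bump / radius), m$faces)
}

# smooth random per-vertex field made of a few geodesic Gaussian blobs
random_depth_field <- function(mesh, seed, n_blobs = 4) {
  set.seed(seed)
  nv <- nrow(mesh$vertices)
  g <- sulcalpits:::mesh_graph(mesh)
  f <- numeric(nv)
  for (k in seq_len(n_blobs)) {
    src <- sample.int(nv, 1)
    d <- geodesic_distance(mesh, src, graph = g)
    f <- f + runif(1, 0.5, 3) * exp(-d^2 / (2 * runif(1, 3, 8)^2))
  }
  f + rnorm(nv, 0, 0.01)
}

# flat sheet with an analytic two-peak depth field (Gaussian bumps in
# field value, not geometry): peaks at x-positions xs with heights hs and
# common width w, on a width x height grid
two_peak_sheet <- function(xs, hs, w, width = 60, height = 40, spacing = 2,
                           y = height / 2) {
  m <- sheet_mesh(width, height, spacing)
  v <- m$vertices
  f <- rep(0, nrow(v))
  centers <- integer(length(xs))
  for (i in seq_along(xs)) {
    g2 <- (v[, 1] - xs[i])^2 + (v[, 2] - y)^2
    f <- pmax(f, hs[i] * exp(-g2 / (2 * w^2)))
    centers[i] <- which.min(g2)
  }
  list(mesh = m, field = f, centers = centers)
}

# geometric dent sheet: folds imprinted as inward displacements
dent_sheet <- function(centers_xy, depths, width = 6, dims = c(80, 60),
                       spacing = 3) {
  m <- sheet_mesh(dims[1], dims[2], spacing)
  centers <- vapply(seq_len(nrow(centers_xy)), function(i)
    which.min((m$vertices[, 1] - centers_xy[i, 1])^2 +
              (m$vertices[, 2] - centers_xy[i, 2])^2), integer(1))
  folds <- data.frame(center = centers, depth = depths, width = width)
  fs <- make_folded_surface(m, folds, allow_overlap = TRUE)
  list(mesh = fs$mesh, centers = centers, base = m)
}

mean_edge_length <- function(mesh) mean(sulcalpits:::mesh_edges(mesh)$lengths)

edge_distance <- function(mesh, from, to) {
  g <- sulcalpits:::mesh_graph(mesh)
  min(igraph::distances(g, v = from, to = to))
}
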