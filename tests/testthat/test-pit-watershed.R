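test_that("threshold normalization scales ThD and ThA by brain size, never ThR", {
  def <- thresholds()
  expect_equal(unclass(def)[c("thr", "thd", "tha")],
               list(thr = 1.5, thd = 20, tha = 50))
  # subject exactly at the group mean (left-hemisphere group values)
  th <- normalize_thresholds(def, fl = 231.8, sa = 91616, g_fl = 231.8, g_sa = 91616)
  expect_identical(unclass(th), unclass(def))
  th2 <- normalize_thresholds(def, fl = 2 * 231.8, sa = 91616, g_fl = 231.8, g_sa = 91616)
  expect_equal(c(th2$thr, th2$thd, th2$tha), c(1.5, 40, 50))
  th3 <- normalize_thresholds(def, fl = 231.8, sa = 0.5 * 91616, g_fl = 231.8, g_sa = 91616)
  expect_equal(c(th3$thr, th3$thd, th3$tha), c(1.5, 20, 25))
  expect_error(normalize_thresholds(def, 200, 90000, 0, 91616), "positive")
  expect_error(normalize_thresholds(def, 200, 90000, 231.8, -1), "positive")
})

test_that("a single dent yields one basin with the pit at the dent bottom", {
  # sheet sized so every point lies within ThD of the pit
  d <- dent_sheet(cbind(14, 14), depths = 5, width = 6, dims = c(28, 28), spacing = 2)
  dm <- depth_potential_function(d$mesh)
  res <- extract_pits(d$mesh, dm, thresholds())
  expect_equal(nrow(res$basins), 1L)
  expect_lte(edge_distance(d$mesh, res$basins$pit_vertex, d$centers),
             2 * mean_edge_length(d$mesh))
  # partition and consistency invariants
  expect_true(all(res$vertex_labels == 1L))
  expect_equal(res$basins$pit_depth, max(dm$dpf))
  expect_equal(res$basins$area, surface_area(d$mesh))
})

test_that("the R/D merge rule follows the AND of both conditions", {
  w_far <- 5                                   # ridge ~ 0 at 30 mm separation
  w_near <- sqrt(25 / (2 * log(5 / 4)))        # ridge exactly 4.0 at 10 mm
  # R >= ThR and D >= ThD: two basins
  tp <- two_peak_sheet(c(15, 45), c(5, 4.8), w_far)
  res <- extract_pits(tp$mesh, tp$field, thresholds())
  expect_equal(nrow(res$basins), 2L)
  expect_setequal(res$basins$pit_vertex, tp$centers)
  # R < ThR and D < ThD: merged, pit at the deeper peak
  tp2 <- two_peak_sheet(c(25, 35), c(5, 4.8), w_near)
  res2 <- extract_pits(tp2$mesh, tp2$field, thresholds())
  expect_equal(nrow(res2$basins), 1L)
  expect_equal(res2$basins$pit_vertex, tp2$centers[1])
  # R < ThR but D >= ThD: still two basins
  w_mid <- sqrt(15^2 / (2 * log(5 / 4)))       # ridge 4.0 at 30 mm separation
  tp3 <- two_peak_sheet(c(15, 45), c(5, 4.8), w_mid)
  res3 <- extract_pits(tp3$mesh, tp3$field, thresholds())
  expect_equal(nrow(res3$basins), 2L)
  # D < ThD but R >= ThR: two basins
  tp4 <- two_peak_sheet(c(25, 35), c(5, 4.8), 3)
  res4 <- extract_pits(tp4$mesh, tp4$field, thresholds())
  expect_equal(nrow(res4$basins), 2L)
})

test_that("small basins merge into the longest-boundary neighbour after flooding", {
  # third shallow narrow peak: its basin area falls below ThA
  m <- sheet_mesh(60, 40, 2)
  v <- m$vertices
  f1 <- 5 * exp(-((v[, 1] - 15)^2 + (v[, 2] - 20)^2) / (2 * 5^2))
  f2 <- 4.8 * exp(-((v[, 1] - 45)^2 + (v[, 2] - 20)^2) / (2 * 5^2))
  f3 <- 4.5 * exp(-((v[, 1] - 30)^2 + (v[, 2] - 38)^2) / (2 * 1.2^2))
  fld <- pmax(f1, f2, f3)
  res_lo <- extract_pits(m, fld, thresholds(thr = 1.5, thd = 20, tha = 0))
  expect_equal(nrow(res_lo$basins), 3L)
  res <- extract_pits(m, fld, thresholds())   # ThA = 50 removes the narrow basin
  expect_equal(nrow(res$basins), 2L)
  expect_true(all(res$basins$area >= 50))
})

test_that("watershed equals the brute-force oracle on random meshes", {
  for (seed in 1:12) {
    m <- bumpy_sphere(seed, subdivisions = if (seed %% 2) 1 else 2)
    fld <- random_depth_field(m, 100 + seed)
    set.seed(300 + seed)
    thr <- runif(1, 0.2, 1.5)
    thd <- runif(1, 5, 30)
    tha <- runif(1, 0, 60)
    res <- extract_pits(m, fld, thresholds(thr, thd, tha))
    ora <- oracle_watershed(m, fld, thr, thd, tha)
    expect_identical(res$vertex_labels, ora$labels)
    expect_identical(res$basins$pit_vertex, ora$pits)
  }
})

test_that("raising the ridge threshold never increases the basin count", {
  m <- bumpy_sphere(33, subdivisions = 2)
  fld <- random_depth_field(m, 44, n_blobs = 6)
  counts <- vapply(c(0, 0.3, 0.8, 1.5, 3), function(thr)
    nrow(extract_pits(m, fld, thresholds(thr = thr, thd = 1e6, tha = 0))$basins),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("flooding partitions the mesh into connected basins, invariant to relabeling", {
  m <- bumpy_sphere(7, subdivisions = 2)
  fld <- random_depth_field(m, 70, n_blobs = 5)
  res <- extract_pits(m, fld, thresholds())
  expect_true(all(res$vertex_labels >= 1))
  expect_equal(sort(unique(res$vertex_labels)), res$basins$label)
  g <- sulcalpits:::mesh_graph(m)
  for (b in res$basins$label) {
    sub <- igraph::induced_subgraph(g, which(res$vertex_labels == b))
    expect_equal(igraph::count_components(sub), 1)
  }
  expect_equal(res$basins$pit_depth,
               vapply(res$basins$label,
                      function(b) max(fld[res$vertex_labels == b]), numeric(1)))
  # vertex relabeling leaves the pit set intact
  set.seed(9)
  perm <- sample.int(nrow(m$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mp <- triangle_mesh(m$vertices[perm, ], matrix(inv[m$faces], ncol = 3))
  resp <- extract_pits(mp, fld[perm], thresholds())
  expect_setequal(perm[resp$basins$pit_vertex], res$basins$pit_vertex)
})

test_that("degenerate depth maps are handled explicitly", {
  m <- sheet_mesh(20, 20, 2)
  expect_warning(res <- extract_pits(m, rep(1, nrow(m$vertices)), thresholds()),
                 "constant")
  expect_equal(nrow(res$basins), 1L)
  expect_true(all(res$vertex_labels == 1L))
})

test_that("pit indicator texture marks exactly the pit vertices", {
  m <- sheet_mesh(20, 20, 2)
  fake <- structure(list(
    basins = data.frame(label = 1:2, pit_vertex = c(5L, 10L),
                        pit_depth = c(2, 1), area = c(1, 1), n_vertices = c(1, 1)),
    vertex_labels = rep(1L, nrow(m$vertices)),
    thresholds_used = thresholds()), class = "pit_extraction")
  tex <- pit_indicator_texture(fake, m)
  expect_equal(sum(tex), 2)
  expect_equal(which(tex == 1), c(5L, 10L))
  fake$basins <- fake$basins[0, ]
  expect_equal(sum(pit_indicator_texture(fake, m)), 0)
})
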