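test_that("heat smoothing keeps the peak at one, stays nonnegative, and localizes", {
  m <- sheet_mesh(40, 30, 2)
  z <- numeric(nrow(m$vertices))
  expect_equal(smooth_texture(m, z), z)                     # all-zero stays zero
  tex <- z
  pit <- which(m$vertices[, 1] == 20 & m$vertices[, 2] == 16)
  tex[pit] <- 1
  sm <- smooth_texture(m, tex)
  expect_equal(max(sm), 1)
  expect_true(all(sm >= 0))
  expect_equal(which.max(sm), pit)
  # values decay with graph distance from the pit, ring by ring
  d <- geodesic_distance(m, pit)
  rings <- split(sm, cut(d, breaks = seq(0, 16, by = 2), include.lowest = TRUE))
  ring_max <- vapply(rings, max, numeric(1))
  expect_true(all(diff(ring_max) < 0))
  # near-zero FWHM: essentially the original indicator
  sm0 <- smooth_texture(m, tex, smoothing_params(fwhm = 0.1, n_iter = 60))
  expect_equal(sm0[pit], 1)
  expect_lt(max(sm0[-pit]), 0.01)
  expect_error(smooth_texture(m, tex - 2), "non-negative")
})

test_that("explicit heat steps agree with the dense matrix-exponential oracle", {
  m <- icosphere(2, 10)                        # 162 vertices
  tex <- numeric(nrow(m$vertices))
  tex[50] <- 1
  par <- smoothing_params(fwhm = 5, n_iter = 60)
  sm <- smooth_texture(m, tex, par)
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  ex <- oracle_heat_expm(m, tex, sigma^2 / 2)
  ex <- pmax(ex, 0) / max(ex)
  keep <- ex > 0.01                            # compare where mass is non-negligible
  expect_lt(max(abs(sm[keep] - ex[keep]) / max(ex)), 0.05)
})

test_that("unstable diffusion steps are subdivided automatically", {
  m <- sheet_mesh(40, 30, 2)
  tex <- numeric(nrow(m$vertices)); tex[100] <- 1
  expect_warning(sm <- smooth_texture(m, tex, smoothing_params(fwhm = 30, n_iter = 2)),
                 "subdividing")
  expect_true(all(is.finite(sm)))
  expect_equal(max(sm), 1)
})

test_that("texture projection pulls values through the correspondence", {
  tex <- c(0.2, 0.9, 0, 0.5)
  id <- vertex_correspondence(1:4, 4)
  expect_equal(project_texture(tex, id), tex)
  perm <- vertex_correspondence(c(3, 1, 4, 2), 4)
  expect_equal(project_texture(tex, perm)[c(3, 1, 4, 2)], tex)
  expect_equal(project_texture(rep(0.7, 4), perm), rep(0.7, 4))
  # many-to-one keeps the maximum; uncovered targets are zero
  mto <- vertex_correspondence(c(1, 1, 2, 2), 4)
  expect_equal(project_texture(tex, mto), c(0.9, 0.5, 0, 0))
  expect_error(project_texture(tex[1:3], id), "length")
})

test_that("density maps average textures and stay in [0, 1]", {
  t1 <- c(1, 0, 0, 0)
  t2 <- c(0, 0, 1, 0)
  expect_equal(density_map(list(t1))$values, t1)
  d <- density_map(list(t1, t2))
  expect_equal(d$values, c(0.5, 0, 0.5, 0))
  expect_equal(d$n_subjects, 2L)
  expect_equal(density_map(rep(list(t1), 7))$values, t1)
  expect_error(density_map(list(t1, c(2, 0, 0, 0))), "\\[0, 1\\]")
  expect_error(density_map(list(t1, t2[1:3])), "inconsist")
  expect_error(density_map(list()), "at least one")
})

test_that("group watershed recovers the shared folds of a synthetic cohort", {
  # all-present cohort: every subject contributes a pit to each of 6 folds
  lay <- fold_layout(n_primary = 2L, n_secondary = 2L, n_dimple = 2L,
                     p_secondary_control = 1, p_secondary_case = 1, p_dimple = 1)
  spec <- cohort_spec(n_case = 5, n_control = 5, layout = lay,
                      count_age_slope = 0, seed = 42)
  ch <- make_cohort(spec)
  corr <- identity_correspondence(ch$base$left)
  texs <- lapply(ch$hemis, function(h) {
    dm <- depth_potential_function(h$left$mesh)
    res <- extract_pits(h$left$mesh, dm, thresholds())
    smooth_texture(h$left$mesh, pit_indicator_texture(res, h$left$mesh))
  })
  dens <- density_map(lapply(texs, project_texture, corr = corr))
  cm <- group_watershed(ch$base$left, dens, group_thresholds())
  expect_equal(cm$K, 6L)
  labs_at_centers <- cm$cluster_labels[ch$folds$center]
  expect_setequal(labs_at_centers, 1:6)        # one cluster per true fold
  expect_false(cm$symmetric)
  # every vertex labelled, clusters connected
  expect_true(all(cm$cluster_labels >= 1))
  g <- sulcalpits:::mesh_graph(ch$base$left)
  for (b in seq_len(cm$K))
    expect_equal(igraph::count_components(
      igraph::induced_subgraph(g, which(cm$cluster_labels == b))), 1)
})

test_that("group watershed merges density peaks by the gThR/gThD rule", {
  w_near <- sqrt(25 / (2 * log(0.8 / 0.7)))    # saddle 0.7 at 10 mm separation
  tp <- two_peak_sheet(c(25, 35), c(0.8, 0.78), w_near)
  cm <- group_watershed(tp$mesh, tp$field / max(tp$field) * 0.8, group_thresholds())
  expect_equal(cm$K, 1L)                       # R = 0.08 < 2, D = 10 < 15
  tp2 <- two_peak_sheet(c(15, 45), c(0.8, 0.78), 4)
  cm2 <- group_watershed(tp2$mesh, tp2$field / max(tp2$field) * 0.8, group_thresholds())
  expect_equal(cm2$K, 2L)                      # D = 30 >= gThD
  # single peak
  tp3 <- two_peak_sheet(30, 0.9, 5)
  expect_equal(group_watershed(tp3$mesh, tp3$field, group_thresholds())$K, 1L)
  # all-zero density: single cluster with a warning
  expect_warning(cm0 <- group_watershed(tp3$mesh, rep(0, nrow(tp3$mesh$vertices)),
                                        group_thresholds()), "zero")
  expect_equal(cm0$K, 1L)
})

test_that("symmetric parcellation pools both hemispheres on one template", {
  lay <- fold_layout(n_primary = 2L, n_secondary = 2L, n_dimple = 2L,
                     p_secondary_control = 1, p_secondary_case = 1, p_dimple = 1)
  spec <- cohort_spec(n_case = 4, n_control = 4, layout = lay,
                      count_age_slope = 0, seed = 11)
  ch <- make_cohort(spec)
  corr <- identity_correspondence(ch$base$left)
  tex_of <- function(mesh) {
    dm <- depth_potential_function(mesh)
    res <- extract_pits(mesh, dm, thresholds())
    smooth_texture(mesh, pit_indicator_texture(res, mesh))
  }
  lt <- lapply(ch$hemis, function(h) tex_of(h$left$mesh))
  rt <- lapply(ch$hemis, function(h) tex_of(h$right$mesh))
  cm <- build_symmetric_parcellation(lt, rt, corr, corr, ch$base$left,
                                     group_thresholds())
  expect_true(cm$symmetric)
  expect_equal(cm$K, 6L)                       # per-hemisphere fold count
  # identical left and right textures: density equals the common texture
  d_same <- density_map(c(lapply(lt, project_texture, corr = corr),
                          lapply(lt, project_texture, corr = corr)))
  expect_equal(d_same$values, density_map(lapply(lt, project_texture, corr = corr))$values)
  # right textures all zero: density halves, clusters unchanged
  zeros <- lapply(rt, function(x) x * 0)
  cm_half <- build_symmetric_parcellation(lt, zeros, corr, corr, ch$base$left,
                                          group_thresholds())
  expect_equal(cm_half$K, cm$K)
  expect_error(build_symmetric_parcellation(lt, rt, corr_left = corr,
                                            template = ch$base$left), "correspondence")
})
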