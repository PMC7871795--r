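#' Icosphere mesh
#'
#' Geodesic sphere obtained by midpoint subdivision of an icosahedron
#' with projection to the sphere; the closed test surface for operator
#' and invariance checks (subdivision 4 gives 2562 vertices). Note that
#' the subdivision-0 icosahedral sphere is vertex-transitive, so its
#' discrete mean curvature is exactly constant; subdivided levels carry
#' a small curvature ripple at the twelve valence-5 vertices.
#'
#' @param subdivisions number of subdivision rounds (>= 0).
#' @param radius sphere radius in mm.
#' @param hemisphere hemisphere tag for the resulting mesh.
#' @return a \code{triangle_mesh}.
#' @export
icosphere <- function(subdivisions = 4L, radius = 60, hemisphere = "none") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    keys <- (pmin(e[, 1], e[, 2]) - 1) * as.double(nv) + pmax(e[, 1], e[, 2])
    ukeys <- unique(keys)
    mid_idx <- nv + match(keys, ukeys)
    ue <- e[!duplicated(keys), , drop = FALSE]
    v <- rbind(v, (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2)
    nf <- nrow(f)
    m12 <- mid_idx[seq_len(nf)]
    m23 <- mid_idx[nf + seq_len(nf)]
    m31 <- mid_idx[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  triangle_mesh(v, f, hemisphere = hemisphere)
}

#' Flat rectangular sheet mesh
#'
#' Open planar patch triangulated on a regular grid — the generator's
#' default hemisphere domain. A flat sheet has exactly zero discrete
#' mean curvature everywhere (including the boundary), so imprinted
#' folds are the only curvature sources and the depth map's background
#' is clean; open boundaries get the natural (Neumann) treatment in all
#' operators.
#'
#' @param width,height sheet extent in mm.
#' @param spacing grid spacing in mm.
#' @param hemisphere hemisphere tag.
#' @return a \code{triangle_mesh} in the z = 0 plane with outward
#'   normals +z.
#' @export
sheet_mesh <- function(width, height, spacing = 3, hemisphere = "none") {
  xs <- seq(0, width, by = spacing)
  ys <- seq(0, height, by = spacing)
  nx <- length(xs)
  ny <- length(ys)
  if (nx < 2 || ny < 2) stop("sheet too small for the requested spacing")
  v <- cbind(rep(xs, ny), rep(ys, each = nx), 0)
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- (j - 1) * nx + i
  f <- rbind(cbind(a, a + 1L, a + nx + 1L),
             cbind(a, a + nx + 1L, a + nx))
  triangle_mesh(v, f, hemisphere = hemisphere)
}

#' Mirror a mesh across the sagittal (x = 0) plane
#'
#' Produces the opposite hemisphere with identical topology (faces are
#' re-wound to preserve outward orientation), so the identity map is an
#' exact interhemispheric correspondence.
#'
#' @param mesh a \code{triangle_mesh}.
#' @export
mirror_mesh <- function(mesh) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  hemi <- switch(mesh$hemisphere, left = "right", right = "left", "none")
  triangle_mesh(v, mesh$faces[, c(1, 3, 2)], hemisphere = hemi)
}

#' Choose well-separated fold centers on a mesh
#'
#' Greedy farthest-point sampling over graph geodesics, seeded at a
#' given start vertex; errors if the requested number of centers cannot
#' keep the required pairwise separation.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param n number of centers.
#' @param min_sep minimum pairwise geodesic separation (mm).
#' @param start index of the first center.
#' @return integer vector of vertex indices.
#' @export
place_fold_centers <- function(mesh, n, min_sep, start = 1L) {
  g <- mesh_graph(mesh)
  centers <- as.integer(start)
  dmin <- geodesic_distance(mesh, centers, graph = g)
  while (length(centers) < n) {
    nxt <- which.max(dmin)
    if (dmin[nxt] < min_sep)
      stop(sprintf("cannot place %d centers with separation >= %g mm on this mesh", n, min_sep))
    centers <- c(centers, as.integer(nxt))
    dmin <- pmin(dmin, geodesic_distance(mesh, nxt, graph = g))
  }
  centers
}

#' Sheet base with a rectangular grid of fold sites
#'
#' Builds the flat sheet and the fold-center vertices used by the
#' cohort generator: n sites on a fully tiled rows-by-columns grid with
#' the given spacing, surrounded by a margin. The geometry is chosen so
#' that (a) sites are pairwise separated by at least 3x the fold width
#' (folds do not interact), (b) site spacing exceeds the watershed
#' distance threshold ThD = 20 mm (adjacent designed basins never
#' merge), and (c) every sheet point, corners included, lies within ThD
#' of a site, so that any shallow spurious catchment that forms on the
#' background is absorbed into a designed basin during flooding.
#'
#' @param n number of fold sites.
#' @param spacing site spacing in mm (default 22).
#' @param margin border around the outer sites in mm (default 9).
#' @param mesh_spacing grid resolution of the sheet in mm (default 3).
#' @param rows number of site rows; the default picks the largest
#'   divisor of n not exceeding sqrt(n) (a compact rectangle). A single
#'   row gives an elongated strip whose Fiedler length is pinned by the
#'   long axis and therefore very stable across subjects.
#' @return list with \code{base} (the sheet \code{triangle_mesh}) and
#'   \code{centers} (site vertex indices).
#' @export
fold_grid <- function(n, spacing = 22, margin = 9, mesh_spacing = 3, rows = NULL) {
  if (is.null(rows)) {
    divs <- which(n %% seq_len(n) == 0)
    nrow_ <- max(divs[divs <= sqrt(n)])
  } else {
    nrow_ <- as.integer(rows)
    if (n %% nrow_ != 0) stop("rows must divide the number of sites")
  }
  i <- (seq_len(n) - 1L) %% (n / nrow_)
  j <- (seq_len(n) - 1L) %/% (n / nrow_)
  sites <- cbind(i * spacing, j * spacing) + margin
  dims <- apply(sites, 2, max) + margin
  base <- sheet_mesh(dims[1], dims[2], mesh_spacing, hemisphere = "left")
  centers <- apply(sites, 1, function(p)
    which.min((base$vertices[, 1] - p[1])^2 + (base$vertices[, 2] - p[2])^2))
  list(base = base, centers = as.integer(centers))
}

#' Default fold layout for a synthetic hemisphere
#'
#' Three depth tiers on a shared sheet base: deep primary folds present
#' in every subject of both groups (as primary sulci are), intermediate
#' secondary folds whose presence probability carries the case-control
#' count effect, and shallow dimples with equal variable presence in
#' both groups. Depth amplitudes are ordered primary > secondary >
#' dimple.
#'
#' @param n_primary,n_secondary,n_dimple folds per tier (defaults 3/4/2).
#' @param p_secondary_control,p_secondary_case secondary-fold presence
#'   probability per group (defaults 0.9 / 0.7).
#' @param p_dimple dimple presence probability, both groups (default 0.6).
#' @param depth_effects case-minus-control depth shift in mm, recycled
#'   over folds (default 0).
#' @param width Gaussian sd of the inward displacement, mm (default 6).
#' @param depths depth amplitude per tier, mm (primary, secondary, dimple).
#' @param spacing,margin,mesh_spacing,rows geometry of
#'   \code{\link{fold_grid}}. The default is a single-row strip at 26 mm
#'   spacing: the strip keeps the subject-wise Fiedler length (and hence
#'   the normalized distance threshold) stable, and the spacing exceeds
#'   any realized ThD so designed folds never merge with each other,
#'   while every sheet point stays within ThD of a fold so background
#'   catchments are absorbed during flooding.
#' @return list with \code{base} (left-hemisphere sheet) and
#'   \code{folds} (data frame: fold_id, tier, center, depth, width,
#'   p_control, p_case, depth_effect).
#' @export
fold_layout <- function(n_primary = 3L, n_secondary = 4L, n_dimple = 2L,
                        p_secondary_control = 0.9, p_secondary_case = 0.7,
                        p_dimple = 0.6, depth_effects = 0,
                        width = 6, depths = c(8, 5, 2.5),
                        spacing = 26, margin = 9, mesh_spacing = 3, rows = 1L) {
  n <- n_primary + n_secondary + n_dimple
  if (spacing < 3 * width)
    stop("site spacing must be at least 3x the fold width (well-separated folds)")
  fg <- fold_grid(n, spacing = spacing, margin = margin,
                  mesh_spacing = mesh_spacing, rows = rows)
  tier <- rep(c("primary", "secondary", "dimple"),
              times = c(n_primary, n_secondary, n_dimple))
  depth <- depths[match(tier, c("primary", "secondary", "dimple"))]
  p_ctrl <- ifelse(tier == "primary", 1,
                   ifelse(tier == "secondary", p_secondary_control, p_dimple))
  p_case <- ifelse(tier == "primary", 1,
                   ifelse(tier == "secondary", p_secondary_case, p_dimple))
  list(base = fg$base,
       folds = data.frame(fold_id = seq_len(n), tier = tier,
                          center = fg$centers, depth = depth, width = width,
                          p_control = p_ctrl, p_case = p_case,
                          depth_effect = rep_len(depth_effects, n),
                          stringsAsFactors = FALSE))
}

#' Imprint Gaussian folds on a base mesh
#'
#' Displaces vertices inward along the outward vertex normals by
#' depth * exp(-g^2 / (2 width^2)), g being the graph-geodesic distance
#' to the fold center. Topology is shared with the base; the true pit of
#' each fold is its center vertex. Fold centers must be pairwise
#' separated by at least 3x the widest fold (the well-separated regime)
#' unless overlap is explicitly allowed.
#'
#' @param base a \code{triangle_mesh}.
#' @param folds data frame with columns \code{center} (vertex index),
#'   \code{depth} (mm) and \code{width} (Gaussian sd, mm).
#' @param allow_overlap bypass the separation check.
#' @param geo_fields optional named list of precomputed geodesic fields
#'   keyed by center vertex (as character), for reuse across a cohort.
#' @return list with \code{mesh} (the folded surface) and
#'   \code{true_pits} (the fold center vertices).
#' @export
make_folded_surface <- function(base, folds, allow_overlap = FALSE, geo_fields = NULL) {
  stopifnot_mesh(base)
  if (nrow(folds) == 0L) return(list(mesh = base, true_pits = integer(0)))
  if (any(folds$width <= 0) || any(folds$depth < 0)) stop("fold depth/width out of range")
  g <- mesh_graph(base)
  get_field <- function(cv) {
    key <- as.character(cv)
    if (!is.null(geo_fields) && !is.null(geo_fields[[key]])) return(geo_fields[[key]])
    geodesic_distance(base, cv, graph = g)
  }
  if (!allow_overlap && nrow(folds) > 1L) {
    min_sep <- 3 * max(folds$width)
    for (i in seq_len(nrow(folds) - 1L)) {
      gi <- get_field(folds$center[i])
      if (any(gi[folds$center[-seq_len(i)]] < min_sep))
        stop("fold centers closer than 3x the maximum width; pass allow_overlap = TRUE to force")
    }
  }
  disp <- numeric(nrow(base$vertices))
  for (i in seq_len(nrow(folds))) {
    gd <- get_field(folds$center[i])
    disp <- disp + folds$depth[i] * exp(-gd^2 / (2 * folds$width[i]^2))
  }
  n <- vertex_normals(base)
  v <- base$vertices - disp * n
  list(mesh = triangle_mesh(v, base$faces, hemisphere = base$hemisphere),
       true_pits = as.integer(folds$center))
}

#' Cohort specification for the synthetic generator
#'
#' Encodes the study conditions of a two-group cohort: group sizes, a
#' uniform age range, the fold layout (tiers, presence probabilities and
#' depth effects), a linear age effect on fold counts, and measurement
#' noise on realized fold depth. Everything is reproducible from the
#' seed.
#'
#' @param n_case,n_control subjects per group (>= 1).
#' @param age_range min/max age in years (default 7-14).
#' @param layout a \code{\link{fold_layout}} (default built lazily by
#'   \code{\link{make_cohort}}).
#' @param count_age_slope expected change in a subject's total pit count
#'   per year of age (default -0.1: counts decline slightly as shallow
#'   folds consolidate with age); spread over the variable-presence
#'   folds of both hemispheres.
#' @param noise_sd Gaussian sd of realized fold depth in mm (default 0.5).
#' @param seed RNG seed.
#' @export
cohort_spec <- function(n_case = 10L, n_control = 10L, age_range = c(7, 14),
                        layout = NULL, count_age_slope = -0.1, noise_sd = 0.5,
                        seed = 1L) {
  if (n_case < 1L || n_control < 1L) stop("need at least one subject per group")
  if (length(age_range) != 2L || age_range[1] <= 0 || diff(age_range) < 0)
    stop("invalid age range")
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 age_range = as.numeric(age_range), layout = layout,
                 count_age_slope = count_age_slope, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Per-fold presence probability for one subject-hemisphere, with the age
# adjustment spread over the variable folds of both hemispheres; clipped
# to [0, 1] (the cohort generator warns once when clipping occurs).
fold_presence_prob <- function(folds, group, age, age_mid, count_age_slope) {
  p <- if (group == "case") folds$p_case else folds$p_control
  variable <- p < 1
  n_var <- sum(variable)
  if (n_var > 0 && count_age_slope != 0) {
    adj <- count_age_slope * (age - age_mid) / (2 * n_var)
    p[variable] <- pmin(pmax(p[variable] + adj, 0), 1)
  }
  p
}

# would any subject-fold presence probability leave [0, 1]?
presence_clipped <- function(folds, ages, age_range, count_age_slope) {
  n_var <- sum(pmax(folds$p_case, folds$p_control) < 1)
  if (n_var == 0L || count_age_slope == 0) return(FALSE)
  adj <- count_age_slope * (ages - mean(age_range)) / (2 * n_var)
  p <- c(outer(folds$p_case[folds$p_case < 1], adj, `+`),
         outer(folds$p_control[folds$p_control < 1], adj, `+`))
  any(p < 0 | p > 1)
}

#' Generate a synthetic two-group cohort of folded surfaces
#'
#' For every subject: an age drawn uniformly from the requested range, a
#' subtype for cases (combined/inattentive, 65/35), and per hemisphere a
#' realization of each fold — present with its group's (age-adjusted)
#' presence probability, with realized depth = amplitude + group depth
#' effect (cases) + Gaussian noise. Hemispheres are mirrored copies of
#' the base sheet sharing topology, so the identity map is the
#' interhemispheric correspondence. Fully deterministic given the seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param build_meshes if FALSE only the ground-truth tables are
#'   generated (fast path for count-level simulations).
#' @return list with \code{subjects} (id, group, age, subtype),
#'   \code{base} (left/right base meshes), \code{hemis} (per subject,
#'   per hemisphere: folded mesh + true pit vertices; NULL when
#'   \code{build_meshes = FALSE}), \code{truth} (long data frame of fold
#'   realizations), \code{folds} and \code{spec}.
#' @export
make_cohort <- function(spec, build_meshes = TRUE) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  set.seed(spec$seed)
  layout <- spec$layout
  if (is.null(layout)) layout <- fold_layout()
  base_left <- layout$base
  folds <- layout$folds
  n <- spec$n_case + spec$n_control
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("case", "control"), c(spec$n_case, spec$n_control)),
    age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
    stringsAsFactors = FALSE)
  subjects$subtype <- ifelse(
    subjects$group == "case",
    ifelse(stats::runif(n) < 0.65, "combined", "inattentive"),
    "none")
  age_mid <- mean(spec$age_range)
  if (presence_clipped(folds, subjects$age, spec$age_range, spec$count_age_slope))
    warning("presence probability clipped to [0, 1] after age adjustment")

  truth <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (hemi in c("left", "right")) {
      p <- fold_presence_prob(folds, subjects$group[i], subjects$age[i],
                              age_mid, spec$count_age_slope)
      present <- stats::runif(nrow(folds)) < p
      depth <- folds$depth +
        (if (subjects$group[i] == "case") folds$depth_effect else 0) +
        stats::rnorm(nrow(folds), 0, spec$noise_sd)
      depth <- pmax(depth, 0.1)
      k <- k + 1L
      truth[[k]] <- data.frame(subject_id = subjects$subject_id[i],
                               hemisphere = hemi,
                               fold_id = folds$fold_id,
                               tier = folds$tier,
                               center = folds$center,
                               present = present,
                               depth_realized = depth,
                               stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)

  base <- list(left = base_left, right = mirror_mesh(base_left))
  hemis <- NULL
  if (build_meshes) {
    g <- mesh_graph(base_left)
    geo_fields <- lapply(folds$center, function(cv)
      geodesic_distance(base_left, cv, graph = g))
    names(geo_fields) <- as.character(folds$center)
    hemis <- vector("list", n)
    names(hemis) <- subjects$subject_id
    for (i in seq_len(n)) {
      hemis[[i]] <- list()
      for (hemi in c("left", "right")) {
        tr <- truth[truth$subject_id == subjects$subject_id[i] &
                    truth$hemisphere == hemi & truth$present, , drop = FALSE]
        realized <- data.frame(center = tr$center, depth = tr$depth_realized,
                               width = folds$width[match(tr$fold_id, folds$fold_id)])
        fs <- make_folded_surface(base[[hemi]], realized, geo_fields = geo_fields)
        hemis[[i]][[hemi]] <- list(mesh = fs$mesh, true_pits = fs$true_pits,
                                   fold_id = tr$fold_id, tier = tr$tier)
      }
    }
  }
  list(subjects = subjects, base = base, hemis = hemis, truth = truth,
       folds = folds, spec = spec)
}

#' Simulate per-class pit counts (count channel only)
#'
#' Draws the fold-presence realizations of \code{\link{make_cohort}}
#' without building any geometry and tallies each subject's pits per
#' tier across both hemispheres — the fast path for statistical
#' calibration of the count analyses.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return data frame: subject_id, group, age, subtype, primary,
#'   secondary, dimple, total.
#' @export
simulate_pit_counts <- function(spec) {
  ch <- make_cohort(spec, build_meshes = FALSE)
  agg <- stats::aggregate(present ~ subject_id + tier, data = ch$truth, FUN = sum)
  wide <- stats::reshape(agg, idvar = "subject_id", timevar = "tier",
                         direction = "wide")
  names(wide) <- sub("^present\\.", "", names(wide))
  for (cl in c("primary", "secondary", "dimple"))
    if (is.null(wide[[cl]])) wide[[cl]] <- 0L
  out <- merge(ch$subjects, wide, by = "subject_id", sort = TRUE)
  out$total <- out$primary + out$secondary + out$dimple
  out[order(out$subject_id), ]
}

#' Simulate a subject-by-cluster deepest-pit depth table
#'
#' Measurement-level emulation of the subject-by-cluster table feeding
#' the per-cluster statistics: each cell is base depth + per-cluster
#' case effect + Gaussian noise, present with a fixed probability (NA
#' otherwise). Used for calibration and power/recovery checks of the
#' statistics without running the geometry pipeline.
#'
#' @param n_case,n_control group sizes.
#' @param n_clusters number of clusters (columns).
#' @param depth_effects case-minus-control shift per cluster (recycled).
#' @param base_depths control-group mean depth per cluster (recycled).
#' @param presence probability a subject has a pit in a cluster.
#' @param noise_sd measurement noise sd (mm).
#' @param age_range uniform age range.
#' @param seed RNG seed.
#' @return list with \code{table} (matrix with NAs) and \code{records}.
#' @export
simulate_cluster_depths <- function(n_case = 60L, n_control = 60L, n_clusters = 1L,
                                    depth_effects = 0, base_depths = 5,
                                    presence = 1, noise_sd = 0.5,
                                    age_range = c(7, 14), seed = 1L) {
  set.seed(seed)
  n <- n_case + n_control
  records <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("case", "control"), c(n_case, n_control)),
    age = stats::runif(n, age_range[1], age_range[2]),
    stringsAsFactors = FALSE)
  eff <- rep_len(depth_effects, n_clusters)
  base <- rep_len(base_depths, n_clusters)
  tab <- matrix(NA_real_, n, n_clusters,
                dimnames = list(records$subject_id, as.character(seq_len(n_clusters))))
  for (j in seq_len(n_clusters)) {
    have <- stats::runif(n) < presence
    val <- base[j] + eff[j] * (records$group == "case") + stats::rnorm(n, 0, noise_sd)
    tab[have, j] <- val[have]
  }
  list(table = tab, records = records)
}

#' Export a cohort as plain files
#'
#' Writes each subject-hemisphere surface as GIFTI, the subject table
#' and identity correspondence as CSV, the ground truth as JSON, and a
#' manifest CSV listing every file with its MD5 checksum.
#'
#' @param cohort result of \code{\link{make_cohort}} (with meshes).
#' @param dir output directory (created if needed).
#' @return the manifest data frame (file, md5), also written to
#'   \code{manifest.csv}.
#' @export
export_fixtures <- function(cohort, dir) {
  if (is.null(cohort$hemis)) stop("cohort was built without meshes")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create directory '%s'", dir))
  files <- character(0)
  for (sid in names(cohort$hemis)) {
    for (hemi in c("left", "right")) {
      fn <- file.path(dir, sprintf("%s_%s.surf.gii", sid, hemi))
      write_gifti_surface(cohort$hemis[[sid]][[hemi]]$mesh, fn)
      files <- c(files, fn)
    }
  }
  fn <- file.path(dir, "subjects.csv")
  utils::write.csv(cohort$subjects, fn, row.names = FALSE)
  files <- c(files, fn)
  nv <- nrow(cohort$base$left$vertices)
  fn <- file.path(dir, "correspondence_identity.csv")
  utils::write.csv(data.frame(source_vertex = seq_len(nv) - 1L,
                              target_vertex = seq_len(nv) - 1L),
                   fn, row.names = FALSE)
  files <- c(files, fn)
  fn <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(folds = cohort$folds, truth = cohort$truth,
                            seed = cohort$spec$seed),
                       fn, digits = NA, auto_unbox = TRUE)
  files <- c(files, fn)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
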