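#' Heat-equation smoothing parameters
#'
#' FWHM of the equivalent Gaussian kernel (mm) and the number of explicit
#' heat-equation iterations. Defaults: 5 mm, 60 iterations, the values
#' used to smooth individual pit textures before averaging.
#'
#' @param fwhm full-width half-maximum in mm (> 0).
#' @param n_iter number of explicit diffusion steps (>= 1).
#' @export
smoothing_params <- function(fwhm = 5, n_iter = 60L) {
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) stop("n_iter must be >= 1")
  list(fwhm = fwhm, n_iter = n_iter)
}

#' Smooth a per-vertex texture by heat diffusion
#'
#' Diffuses the texture on the mesh for total time
#' t = (fwhm / (2 sqrt(2 ln 2)))^2 / 2 (the variance-time relation of the
#' Gaussian heat kernel, sigma = fwhm/2.355, t = sigma^2/2), split into
#' \code{n_iter} explicit Euler steps of the lumped-mass cotangent
#' Laplacian. If the step exceeds the explicit-stability bound it is
#' automatically subdivided (with a warning). Negative undershoots are
#' clamped to zero and the result is rescaled globally so its maximum is
#' one (the peak value is maintained at one); an all-zero input stays
#' all-zero.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param texture non-negative per-vertex field (e.g. a pit indicator).
#' @param params a \code{\link{smoothing_params}} list.
#' @param ops optional precomputed operators.
#' @return smoothed per-vertex field with max 1 (if input nonzero).
#' @export
smooth_texture <- function(mesh, texture, params = smoothing_params(), ops = NULL) {
  stopifnot_mesh(mesh)
  texture <- vertex_field(texture, mesh)
  if (any(texture < 0)) stop("texture must be non-negative")
  if (all(texture == 0)) return(texture)
  if (is.null(ops)) ops <- laplace_operators(mesh)
  sigma <- params$fwhm / (2 * sqrt(2 * log(2)))
  t_total <- sigma^2 / 2
  dt <- t_total / params$n_iter
  m <- Matrix::diag(ops$mass)
  # Gershgorin bound on lambda_max(M^-1 K); explicit Euler needs dt < 2/lambda
  k_diag <- Matrix::diag(ops$stiffness)
  lam_bound <- max(2 * abs(k_diag) / m)
  n_sub <- 1L
  if (dt >= 1.8 / lam_bound) {
    n_sub <- ceiling(dt / (0.9 * 2 / lam_bound))
    warning(sprintf("diffusion step exceeds stability bound; subdividing each step into %d", n_sub))
  }
  u <- texture
  K <- ops$stiffness
  step <- dt / n_sub
  for (i in seq_len(params$n_iter * n_sub)) {
    u <- u - step * as.vector(K %*% u) / m
  }
  u[u < 0] <- 0
  mx <- max(u)
  if (mx > 0) u <- u / mx
  u
}

#' Vertex correspondence between two meshes
#'
#' A total map giving, for every source vertex, one target vertex index.
#' Stands in for spherical / interhemispheric registration, which is an
#' external preprocessing step: correspondences are inputs here (the
#' identity for synthetic cohorts whose hemispheres share topology).
#'
#' @param mapping integer vector: \code{mapping[i]} is the target vertex
#'   for source vertex i (1-based).
#' @param n_target number of vertices on the target mesh.
#' @export
vertex_correspondence <- function(mapping, n_target) {
  mapping <- as.integer(mapping)
  if (anyNA(mapping) || any(mapping < 1L) || any(mapping > n_target))
    stop("correspondence must map every source vertex to a valid target vertex")
  structure(list(mapping = mapping, n_target = as.integer(n_target)),
            class = "vertex_correspondence")
}

#' Identity correspondence for meshes sharing topology
#' @param mesh the (shared-topology) mesh.
#' @export
identity_correspondence <- function(mesh) {
  nv <- nrow(mesh$vertices)
  vertex_correspondence(seq_len(nv), nv)
}

#' Project a texture to a template through a vertex correspondence
#'
#' Each target vertex takes the value of the source vertex mapped to it;
#' if several source vertices map to one target the maximum is kept
#' (preserving the unit peak of pit textures); target vertices receiving
#' nothing are 0.
#'
#' @param texture per-vertex field on the source mesh.
#' @param corr a \code{\link{vertex_correspondence}}.
#' @return per-vertex field on the target mesh.
#' @export
project_texture <- function(texture, corr) {
  if (!inherits(corr, "vertex_correspondence")) stop("corr must be a vertex_correspondence")
  texture <- as.numeric(texture)
  if (length(texture) != length(corr$mapping))
    stop("texture length does not match the correspondence's source mesh")
  out <- numeric(corr$n_target)
  agg <- tapply(texture, corr$mapping, max)
  out[as.integer(names(agg))] <- as.vector(agg)
  out
}

#' Group pit density map
#'
#' Vertex-wise arithmetic mean of the subjects' (smoothed, projected)
#' pit textures on the common template: the probability of a pit at each
#' location.
#'
#' @param projected_textures list of per-vertex fields on the template,
#'   each with values in [0, 1].
#' @return object of class \code{density_map}: list with \code{values}
#'   and \code{n_subjects}.
#' @export
density_map <- function(projected_textures) {
  if (length(projected_textures) < 1L) stop("at least one texture required")
  lens <- vapply(projected_textures, length, integer(1))
  if (length(unique(lens)) != 1L) stop("textures have inconsistent lengths")
  mat <- do.call(cbind, projected_textures)
  if (any(mat < 0) || any(mat > 1)) stop("texture values must lie in [0, 1]")
  structure(list(values = rowMeans(mat), n_subjects = length(projected_textures)),
            class = "density_map")
}

#' Group watershed: parcellate the density map into clusters
#'
#' Runs the same filtered-watershed machinery as subject-level pit
#' extraction, with the density map as the depth field and the group
#' thresholds (no subject-wise normalization). Returns connected
#' clusters covering every template vertex.
#'
#' @param template the template \code{triangle_mesh}.
#' @param density a \code{\link{density_map}} (or per-vertex numeric field).
#' @param gth a \code{\link{group_thresholds}} object.
#' @param symmetric logical flag recorded on the result.
#' @return object of class \code{group_cluster_map}: list with
#'   \code{cluster_labels} (per-vertex label 1..K), \code{K},
#'   \code{clusters} (data frame with peak vertex, peak density, area)
#'   and \code{symmetric}.
#' @export
group_watershed <- function(template, density, gth = group_thresholds(),
                            symmetric = FALSE) {
  vals <- if (inherits(density, "density_map")) density$values else density
  vals <- vertex_field(vals, template)
  all_zero <- all(vals == 0)
  if (all_zero) warning("all-zero density map; the result is a single cluster")
  ws <- if (all_zero) {
    suppressWarnings(watershed_partition(template, vals, gth$thr, gth$thd, gth$tha))
  } else {
    watershed_partition(template, vals, gth$thr, gth$thd, gth$tha)
  }
  clusters <- ws$basins
  names(clusters)[names(clusters) == "pit_vertex"] <- "peak_vertex"
  names(clusters)[names(clusters) == "pit_depth"] <- "peak_density"
  structure(list(cluster_labels = ws$labels,
                 K = nrow(clusters),
                 clusters = clusters,
                 symmetric = symmetric),
            class = "group_cluster_map")
}

#' @export
print.group_cluster_map <- function(x, ...) {
  cat(sprintf("group_cluster_map: K=%d clusters%s\n", x$K,
              if (x$symmetric) " (symmetric)" else ""))
  invisible(x)
}

#' Symmetric (interhemispheric) parcellation
#'
#' Pools the smoothed pit textures of both hemispheres of every subject
#' on one template side through interhemispheric correspondences,
#' averages them into a single density map, and parcellates it with the
#' group watershed. Used for asymmetry analyses, where left and right
#' measurements must live in the same cluster space.
#'
#' @param left_textures,right_textures lists (one per subject) of
#'   smoothed pit textures on the left / right subject meshes.
#' @param corr_left,corr_right correspondences from each hemisphere to
#'   the symmetric template.
#' @param template the symmetric template mesh.
#' @param gth group thresholds.
#' @return a \code{group_cluster_map} with \code{symmetric = TRUE}.
#' @export
build_symmetric_parcellation <- function(left_textures, right_textures,
                                         corr_left, corr_right,
                                         template, gth = group_thresholds()) {
  if (length(left_textures) != length(right_textures))
    stop("need one left and one right texture per subject")
  if (missing(corr_left) || missing(corr_right) ||
      !inherits(corr_left, "vertex_correspondence") ||
      !inherits(corr_right, "vertex_correspondence"))
    stop("interhemispheric correspondences are required for both hemispheres")
  proj <- c(lapply(left_textures, project_texture, corr = corr_left),
            lapply(right_textures, project_texture, corr = corr_right))
  dens <- density_map(proj)
  group_watershed(template, dens, gth, symmetric = TRUE)
}
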