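#' Construct a triangle mesh
#'
#' A triangle mesh of one cortical hemisphere (or any surface patch):
#' vertex coordinates in millimetres and faces as 1-based vertex-index
#' triples. Construction validates the invariants every downstream
#' operation relies on: all face indices valid, no face repeating a
#' vertex, no (numerically) zero-area face, every edge shared by at most
#' two faces, and a consistent orientation across shared edges.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param hemisphere one of \code{"none"}, \code{"left"}, \code{"right"}.
#' @return an object of class \code{triangle_mesh} with elements
#'   \code{vertices}, \code{faces}, \code{hemisphere}.
#' @export
triangle_mesh <- function(vertices, faces, hemisphere = c("none", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z)")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  nv <- nrow(vertices)
  if (any(faces < 1L) || any(faces > nv)) stop("face index out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]))
    stop("face repeats a vertex")
  mesh <- structure(list(vertices = vertices, faces = faces, hemisphere = hemisphere),
                    class = "triangle_mesh")
  fa <- face_areas(mesh)
  if (any(fa <= .Machine$double.eps * 100))
    stop("mesh contains zero-area (degenerate) faces")
  # Directed edges: a consistently oriented manifold mesh uses each
  # directed edge at most once, and each undirected edge in at most 2 faces.
  he <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- (he[, 1] - 1) * as.double(nv) + he[, 2]
  if (anyDuplicated(key)) stop("inconsistent orientation or non-manifold edge (repeated directed edge)")
  ukey <- (pmin(he[, 1], he[, 2]) - 1) * as.double(nv) + pmax(he[, 1], he[, 2])
  if (any(table(ukey) > 2L)) stop("non-manifold edge (shared by more than 2 faces)")
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, hemisphere=%s\n",
              nrow(x$vertices), nrow(x$faces), x$hemisphere))
  invisible(x)
}

stopifnot_mesh <- function(mesh) {
  if (!inherits(mesh, "triangle_mesh")) stop("expected a 'triangle_mesh' object")
  invisible(mesh)
}

face_corners <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(p1 = v[f[, 1], , drop = FALSE],
       p2 = v[f[, 2], , drop = FALSE],
       p3 = v[f[, 3], , drop = FALSE])
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Face areas and normals
#'
#' @param mesh a \code{triangle_mesh}.
#' @return \code{face_areas}: numeric vector of triangle areas (mm^2).
#' @export
face_areas <- function(mesh) {
  p <- face_corners(mesh)
  cr <- cross3(p$p2 - p$p1, p$p3 - p$p1)
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(mesh) {
  p <- face_corners(mesh)
  cr <- cross3(p$p2 - p$p1, p$p3 - p$p1)
  cr / sqrt(rowSums(cr^2))
}

#' Outward vertex normals (area-weighted average of incident face normals).
#' @param mesh a \code{triangle_mesh}.
#' @return numeric matrix, one unit normal per vertex.
#' @export
vertex_normals <- function(mesh) {
  stopifnot_mesh(mesh)
  nv <- nrow(mesh$vertices)
  p <- face_corners(mesh)
  cr <- cross3(p$p2 - p$p1, p$p3 - p$p1) # area-weighted face normal (x2)
  n <- matrix(0, nv, 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (d in 1:3) n[, d] <- n[, d] + as.vector(Matrix::sparseMatrix(
      i = idx, j = rep(1L, length(idx)), x = cr[, d], dims = c(nv, 1)))
  }
  n / sqrt(rowSums(n^2))
}

#' Per-vertex (lumped/barycentric) areas
#'
#' Each vertex receives one third of the area of every incident face, so
#' the vertex areas sum exactly to the total surface area. These are the
#' diagonal entries of the lumped mass operator.
#'
#' @param mesh a \code{triangle_mesh}.
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  stopifnot_mesh(mesh)
  nv <- nrow(mesh$vertices)
  fa <- face_areas(mesh)
  a <- numeric(nv)
  for (k in 1:3) {
    a <- a + as.vector(Matrix::sparseMatrix(i = mesh$faces[, k],
                                            j = rep(1L, nrow(mesh$faces)),
                                            x = fa / 3, dims = c(nv, 1)))
  }
  a
}

#' Total surface area of the mesh (mm^2)
#' @param mesh a \code{triangle_mesh}.
#' @export
surface_area <- function(mesh) sum(face_areas(mesh))

#' Cotangent stiffness and lumped mass operators
#'
#' The standard linear finite-element pair on a triangle mesh: the
#' cotangent-weighted stiffness matrix K (symmetric, positive
#' semi-definite, rows summing to zero) and the diagonal lumped mass
#' matrix M built from \code{\link{vertex_areas}}. Open boundaries get the
#' natural (Neumann) treatment. These drive the depth potential function,
#' heat smoothing and the Fiedler vector.
#'
#' @param mesh a \code{triangle_mesh}.
#' @return list with sparse matrices \code{stiffness} and \code{mass}.
#' @export
laplace_operators <- function(mesh) {
  stopifnot_mesh(mesh)
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  p <- face_corners(mesh)
  cot_at <- function(a, b, c) {
    # cotangent of the angle at corner a, opposite edge (b, c)
    u <- b - a
    v <- c - a
    cr <- cross3(u, v)
    rowSums(u * v) / sqrt(rowSums(cr^2))
  }
  c1 <- cot_at(p$p1, p$p2, p$p3) # opposite edge (2,3)
  c2 <- cot_at(p$p2, p$p3, p$p1) # opposite edge (3,1)
  c3 <- cot_at(p$p3, p$p1, p$p2) # opposite edge (1,2)
  if (!all(is.finite(c(c1, c2, c3))))
    stop("degenerate geometry produced non-finite cotangent weights")
  ii <- c(f[, 2], f[, 3], f[, 1])
  jj <- c(f[, 3], f[, 1], f[, 2])
  ww <- c(c1, c2, c3) / 2
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(nv, nv))
  K <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  M <- Matrix::Diagonal(x = vertex_areas(mesh))
  list(stiffness = Matrix::drop0(K), mass = M)
}

#' Signed mean curvature per vertex
#'
#' Discrete mean curvature from the cotangent Laplacian applied to the
#' coordinates, projected on the outward vertex normal. Sign convention:
#' positive in concave regions (sulcal fundi), negative on convex crowns,
#' so that depth measures derived from it are positive inside sulci. A
#' sphere of radius r with outward normals gives -1/r everywhere.
#'
#' @param mesh a \code{triangle_mesh} with consistent outward orientation.
#' @param ops optional precomputed \code{\link{laplace_operators}}.
#' @return numeric vector of per-vertex mean curvature (1/mm).
#' @export
mean_curvature <- function(mesh, ops = NULL) {
  stopifnot_mesh(mesh)
  if (is.null(ops)) ops <- laplace_operators(mesh)
  a <- Matrix::diag(ops$mass)
  lapx <- as.matrix(ops$stiffness %*% mesh$vertices) / a # = -Laplace-Beltrami(x)
  n <- vertex_normals(mesh)
  -0.5 * rowSums(lapx * n)
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = len)
}

mesh_adjacency <- function(mesh) {
  nv <- nrow(mesh$vertices)
  ed <- mesh_edges(mesh)$edges
  adj <- vector("list", nv)
  sp1 <- split(ed[, 2], ed[, 1])
  sp2 <- split(ed[, 1], ed[, 2])
  for (nm in names(sp1)) adj[[as.integer(nm)]] <- sp1[[nm]]
  for (nm in names(sp2)) {
    i <- as.integer(nm)
    adj[[i]] <- c(adj[[i]], sp2[[nm]])
  }
  lapply(adj, function(x) sort(unique(x)))
}

mesh_graph <- function(mesh) {
  ed <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::E(g)$weight <- ed$lengths
  g
}

#' Geodesic distance along the mesh edge graph
#'
#' Shortest distance from each vertex to the nearest source vertex along
#' mesh edges weighted by Euclidean length (Dijkstra on the edge graph,
#' not the exact polyhedral geodesic). Vertices unreachable from every
#' source get \code{Inf}.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param sources integer vector of source vertex indices (1-based).
#' @param graph optional precomputed edge graph (internal reuse).
#' @return numeric vector of distances (mm), one per vertex.
#' @export
geodesic_distance <- function(mesh, sources, graph = NULL) {
  stopifnot_mesh(mesh)
  sources <- as.integer(sources)
  if (length(sources) < 1L) stop("at least one source vertex required")
  if (any(sources < 1L | sources > nrow(mesh$vertices))) stop("source index out of range")
  if (is.null(graph)) graph <- mesh_graph(mesh)
  d <- igraph::distances(graph, v = sources, mode = "all")
  if (length(sources) == 1L) as.vector(d) else apply(d, 2, min)
}

#' Fiedler vector of the mesh Laplace operator
#'
#' First nontrivial eigenvector of the generalized problem
#' K v = lambda M v (cotangent stiffness, lumped mass), computed in
#' shift-inverted symmetric form with ARPACK (Lanczos) and a sparse
#' Cholesky factorization. Robust to the near-degenerate low eigenvalue
#' clusters of almost-symmetric shapes (a sphere's first nontrivial
#' eigenvalue is a triplet). Deterministic: the Lanczos start vector is
#' fixed.
#'
#' @param mesh a \code{triangle_mesh} (must be connected).
#' @param ops optional precomputed operators.
#' @return list with \code{vector} (length n, M-normalized) and
#'   \code{value} (the eigenvalue).
#' @export
fiedler_vector <- function(mesh, ops = NULL) {
  stopifnot_mesh(mesh)
  if (is.null(ops)) ops <- laplace_operators(mesh)
  K <- ops$stiffness
  m <- Matrix::diag(ops$mass)
  nv <- length(m)
  g <- mesh_graph(mesh)
  if (igraph::count_components(g) > 1L) stop("mesh is disconnected; Fiedler vector undefined")
  # symmetric shift-invert: eigenvectors of C = M^-1/2 K M^-1/2 via
  # y = M^-1/2 (K + sigma M)^-1 M^1/2 x; largest of the inverse = smallest of C
  sigma <- 1e-6 * sum(Matrix::diag(K)) / sum(m)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(K + sigma * ops$mass), LDL = FALSE)
  sqm <- sqrt(m)
  fn <- function(x, extra = NULL) {
    sqm * as.vector(Matrix::solve(ch, sqm * x))
  }
  res <- tryCatch(
    igraph::arpack(fn, sym = TRUE,
                   options = list(n = nv, nev = 2L, ncv = min(nv, 12L),
                                  which = "LM", maxiter = 3000L,
                                  start = sin(seq_len(nv)))),
    error = function(e) stop(sprintf("Fiedler eigen-solver failed: %s",
                                     conditionMessage(e))))
  lam <- 1 / res$values - sigma              # back-transformed eigenvalues of C
  ord <- order(lam)
  u <- res$vectors[, ord[2]]                 # skip the constant (smallest) mode
  if (lam[ord[2]] <= 1e-12 * max(lam))
    stop("Fiedler eigenvalue numerically zero; is the mesh connected?")
  v <- u / sqm
  v <- v / sqrt(sum(m * v^2))
  list(vector = v, value = lam[ord[2]])
}

#' Shape descriptors: Fiedler length and surface area
#'
#' The Fiedler length FL is the geodesic distance between the vertices
#' attaining the minimum and the maximum of the first nontrivial
#' Laplace eigenvector — a proxy for overall mesh elongation used to
#' normalize the watershed distance/area thresholds by brain size.
#' Ties in the extrema break to the lowest vertex index.
#'
#' @param mesh a connected \code{triangle_mesh}.
#' @param ops optional precomputed operators.
#' @return list with \code{fiedler_length} (mm) and \code{surface_area} (mm^2).
#' @export
shape_descriptors <- function(mesh, ops = NULL) {
  fv <- fiedler_vector(mesh, ops = ops)
  v <- fv$vector
  i_min <- which.min(v)
  i_max <- which.max(v)
  d <- geodesic_distance(mesh, i_min)
  list(fiedler_length = d[i_max], surface_area = surface_area(mesh))
}

#' @rdname shape_descriptors
#' @export
fiedler_length <- function(mesh, ops = NULL) shape_descriptors(mesh, ops)$fiedler_length

#' Bind a per-vertex scalar field to a mesh (validation helper)
#' @param values numeric vector, one finite value per vertex.
#' @param mesh the mesh the field lives on.
#' @return the validated numeric vector.
#' @export
vertex_field <- function(values, mesh) {
  stopifnot_mesh(mesh)
  values <- as.numeric(values)
  if (length(values) != nrow(mesh$vertices))
    stop("field length does not match vertex count")
  if (!all(is.finite(values))) stop("field contains non-finite values")
  values
}
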