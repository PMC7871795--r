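#' Watershed thresholds
#'
#' The three merging thresholds of the filtered watershed: \code{thr}
#' (ridge height, DPF units), \code{thd} (geodesic pit-to-pit distance,
#' mm) and \code{tha} (minimum basin area, mm^2). Defaults are the
#' published values calibrated on a healthy adult population.
#'
#' @param thr ridge-height threshold (default 1.5).
#' @param thd pit distance threshold in mm (default 20).
#' @param tha basin area threshold in mm^2 (default 50).
#' @export
thresholds <- function(thr = 1.5, thd = 20, tha = 50) {
  if (any(!is.finite(c(thr, thd, tha))) || any(c(thr, thd, tha) < 0))
    stop("thresholds must be finite and non-negative")
  structure(list(thr = thr, thd = thd, tha = tha), class = "pit_thresholds")
}

#' Group-watershed thresholds (density parcellation defaults)
#' @param gthr ridge threshold in density units (default 2).
#' @param gthd distance threshold in mm (default 15).
#' @param gtha area threshold in mm^2 (default 100).
#' @export
group_thresholds <- function(gthr = 2, gthd = 15, gtha = 100) {
  th <- thresholds(gthr, gthd, gtha)
  names(th) <- c("thr", "thd", "tha")
  th
}

#' Normalize watershed thresholds by brain size
#'
#' The distance and area thresholds scale with the subject's overall
#' size relative to the group: ThD' = ThD * FL/G(FL) and
#' ThA' = ThA * SA/G(SA), where FL is the subject's mesh Fiedler length,
#' SA its surface area, and G(.) the group means. The ridge-height
#' threshold ThR is not size-normalized.
#'
#' @param defaults a \code{\link{thresholds}} object.
#' @param fl subject Fiedler length (mm).
#' @param sa subject surface area (mm^2).
#' @param g_fl,g_sa group mean Fiedler length / surface area (> 0).
#' @return a \code{thresholds} object with scaled thd and tha.
#' @export
normalize_thresholds <- function(defaults, fl, sa, g_fl, g_sa) {
  if (!inherits(defaults, "pit_thresholds")) stop("defaults must be a thresholds() object")
  vals <- c(fl = fl, sa = sa, g_fl = g_fl, g_sa = g_sa)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("FL, SA and their group means must be positive and finite")
  thresholds(thr = defaults$thr,
             thd = defaults$thd * fl / g_fl,
             tha = defaults$tha * sa / g_sa)
}

# ---------------------------------------------------------------------------
# Core filtered-watershed machinery, shared by subject-level pit extraction
# (depth = DPF) and the group watershed (depth = pit density).
#
# Flooding visits vertices in decreasing depth order (ties to the lower
# index). A vertex with no labelled neighbour seeds a new basin (it is the
# basin's pit). A vertex touching two or more basins is a ridge point: for
# each shallower basin b against the deepest adjacent basin, the ridge
# height R = pit_depth(b) - depth(ridge vertex); if R < thr AND the
# geodesic distance D between the two pits < thd the basins merge (the
# deeper pit is kept); the vertex always joins the deepest adjacent basin.
# Equal-depth plateaus are processed as a unit: tied vertices adjacent to
# existing basins are absorbed first (iterated sweeps in index order), then
# each remaining connected tied component seeds one basin at its
# lowest-index vertex. After flooding, any basin with area < tha is merged
# into the neighbour sharing the longest boundary (sum of crossing edge
# lengths), iterating smallest-area-first until none remains; boundary ties
# break to the deeper-pit neighbour.
# ---------------------------------------------------------------------------

watershed_partition <- function(mesh, depth, thr, thd, tha) {
  stopifnot_mesh(mesh)
  depth <- vertex_field(depth, mesh)
  nv <- length(depth)
  if (nv == 0L) stop("empty mesh")
  adj <- mesh_adjacency(mesh)
  graph <- mesh_graph(mesh)
  av <- vertex_areas(mesh)

  if (diff(range(depth)) == 0) {
    warning("depth map is constant; returning a single basin")
    pit <- 1L
    return(finalize_basins(mesh, rep(1L, nv), pit, depth[pit], av,
                           thr, thd, tha, run_area_merge = FALSE))
  }

  label <- integer(nv)              # 0 = unassigned; otherwise basin id
  parent <- integer(0)              # union-find over basin ids
  pit_of <- integer(0)              # pit vertex per basin id
  pit_depth_of <- numeric(0)
  geo_cache <- new.env(parent = emptyenv())

  uf_find <- function(b) {
    while (parent[b] != b) {
      parent[b] <<- parent[parent[b]]
      b <- parent[b]
    }
    b
  }
  new_basin <- function(v) {
    b <- length(parent) + 1L
    parent[b] <<- b
    pit_of[b] <<- v
    pit_depth_of[b] <<- depth[v]
    label[v] <<- b
    b
  }
  pit_dist <- function(p_from, p_to) {
    key <- as.character(p_from)
    d <- geo_cache[[key]]
    if (is.null(d)) {
      key2 <- as.character(p_to)
      d2 <- geo_cache[[key2]]
      if (!is.null(d2)) return(d2[p_from])
      d <- as.vector(igraph::distances(graph, v = p_from, mode = "all"))
      geo_cache[[key]] <- d
    }
    d[p_to]
  }
  assign_vertex <- function(v) {
    labs <- label[adj[[v]]]
    roots <- unique(vapply(labs[labs > 0L], uf_find, integer(1)))
    if (length(roots) == 0L) {
      new_basin(v)
      return(invisible())
    }
    if (length(roots) > 1L) {
      ord <- order(-pit_depth_of[roots], pit_of[roots])
      roots <- roots[ord]
    }
    target <- roots[1L]
    if (length(roots) > 1L) {
      for (b in roots[-1L]) {
        r_height <- pit_depth_of[b] - depth[v]
        if (r_height < thr &&
            pit_dist(pit_of[target], pit_of[b]) < thd) {
          parent[b] <<- target      # target keeps the deeper pit
        }
      }
    }
    label[v] <<- target
    invisible()
  }

  ord <- order(-depth, seq_len(nv))
  i <- 1L
  while (i <= nv) {
    j <- i
    while (j < nv && depth[ord[j + 1L]] == depth[ord[i]]) j <- j + 1L
    if (j == i) {
      assign_vertex(ord[i])
    } else {
      plateau <- sort(ord[i:j])
      in_plateau <- logical(nv)
      in_plateau[plateau] <- TRUE
      pending <- plateau
      repeat {
        touch <- pending[vapply(pending, function(v) any(label[adj[[v]]] > 0L), logical(1))]
        if (length(touch) == 0L) break
        for (v in touch) assign_vertex(v)
        pending <- setdiff(pending, touch)
        if (length(pending) == 0L) break
      }
      # remaining tied vertices: one seed per connected component
      while (length(pending) > 0L) {
        seed <- pending[1L]
        b <- new_basin(seed)
        comp <- seed
        frontier <- seed
        unvisited <- rep(FALSE, nv)
        unvisited[pending] <- TRUE
        unvisited[seed] <- FALSE
        while (length(frontier) > 0L) {
          nxt <- unique(unlist(adj[frontier], use.names = FALSE))
          nxt <- nxt[unvisited[nxt]]
          unvisited[nxt] <- FALSE
          label[nxt] <- b
          comp <- c(comp, nxt)
          frontier <- nxt
        }
        pending <- setdiff(pending, comp)
      }
    }
    i <- j + 1L
  }

  roots <- vapply(label, uf_find, integer(1))
  uroots <- unique(roots)
  uroots <- uroots[order(-pit_depth_of[uroots], pit_of[uroots])]
  relab <- match(roots, uroots)
  finalize_basins(mesh, relab, pit_of[uroots], pit_depth_of[uroots], av,
                  thr, thd, tha, run_area_merge = TRUE, graph = graph)
}

finalize_basins <- function(mesh, labels, pits, pit_depths, av,
                            thr, thd, tha, run_area_merge = TRUE, graph = NULL) {
  ed <- mesh_edges(mesh)
  areas <- vapply(seq_along(pits), function(b) sum(av[labels == b]), numeric(1))

  if (run_area_merge && length(pits) > 1L) {
    repeat {
      small <- which(areas < tha)
      if (length(small) == 0L || length(pits) <= 1L) break
      b <- small[order(areas[small], small)][1L]
      l1 <- labels[ed$edges[, 1]]
      l2 <- labels[ed$edges[, 2]]
      cross <- which(l1 != l2 & (l1 == b | l2 == b))
      if (length(cross) == 0L) break   # isolated (should not happen on connected meshes)
      other <- ifelse(l1[cross] == b, l2[cross], l1[cross])
      blen <- tapply(ed$lengths[cross], other, sum)
      cand <- as.integer(names(blen))
      best <- cand[order(-as.vector(blen), -pit_depths[cand], pits[cand])]
      tgt <- best[1L]
      # keep the deeper pit of the merged pair
      if (pit_depths[b] > pit_depths[tgt] ||
          (pit_depths[b] == pit_depths[tgt] && pits[b] < pits[tgt])) {
        pits[tgt] <- pits[b]
        pit_depths[tgt] <- pit_depths[b]
      }
      areas[tgt] <- areas[tgt] + areas[b]
      labels[labels == b] <- tgt
      keep <- setdiff(seq_along(pits), b)
      remap <- integer(length(pits))
      remap[keep] <- seq_along(keep)
      labels <- remap[labels]
      pits <- pits[keep]
      pit_depths <- pit_depths[keep]
      areas <- areas[keep]
    }
  }

  ord <- order(-pit_depths, pits)
  remap <- integer(length(pits))
  remap[ord] <- seq_along(ord)
  labels <- remap[labels]
  pits <- pits[ord]
  pit_depths <- pit_depths[ord]
  areas <- areas[ord]
  list(labels = labels,
       basins = data.frame(label = seq_along(pits),
                           pit_vertex = pits,
                           pit_depth = pit_depths,
                           area = areas,
                           n_vertices = as.vector(table(factor(labels, levels = seq_along(pits))))))
}

#' Extract sulcal pits and basins from a depth map
#'
#' Filtered watershed on the depth map: flooding in decreasing depth
#' order with basin merging controlled by ridge height (thr), geodesic
#' pit-to-pit distance (thd) and, after flooding, basin area (tha). See
#' \code{\link{thresholds}} and \code{\link{normalize_thresholds}} for
#' the subject-wise threshold scaling.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param depth a \code{depth_map} or numeric per-vertex depth field
#'   (larger = deeper).
#' @param th a \code{\link{thresholds}} object (already normalized).
#' @return an object of class \code{pit_extraction}: list with
#'   \code{basins} (data frame label / pit_vertex / pit_depth / area /
#'   n_vertices), \code{vertex_labels} (per-vertex basin label) and
#'   \code{thresholds_used}.
#' @export
extract_pits <- function(mesh, depth, th = thresholds()) {
  if (!inherits(th, "pit_thresholds")) stop("th must be a thresholds() object")
  depth <- as_depth_values(depth, mesh)
  ws <- watershed_partition(mesh, depth, th$thr, th$thd, th$tha)
  structure(list(basins = ws$basins,
                 vertex_labels = ws$labels,
                 thresholds_used = th),
            class = "pit_extraction")
}

#' @export
print.pit_extraction <- function(x, ...) {
  cat(sprintf("pit_extraction: %d basins (thr=%.3g, thd=%.3g, tha=%.3g)\n",
              nrow(x$basins), x$thresholds_used$thr, x$thresholds_used$thd,
              x$thresholds_used$tha))
  invisible(x)
}

#' Binary pit indicator texture
#'
#' Per-vertex field equal to 1 at each basin's pit vertex and 0
#' elsewhere; the input to pit-texture smoothing and the group density
#' map.
#'
#' @param result a \code{pit_extraction}.
#' @param mesh the mesh the extraction was run on.
#' @return numeric per-vertex 0/1 vector.
#' @export
pit_indicator_texture <- function(result, mesh) {
  stopifnot_mesh(mesh)
  if (!inherits(result, "pit_extraction")) stop("result must be a pit_extraction")
  tex <- numeric(nrow(mesh$vertices))
  tex[result$basins$pit_vertex] <- 1
  tex
}
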