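#' Mean depth per group cluster
#'
#' For each cluster (column of the subject-by-cluster deepest-pit depth
#' table), the mean over the subjects that have a pit there; missing
#' cells are excluded. Clusters with no observation at all are dropped
#' with a warning (they cannot be classified).
#'
#' @param depth_table numeric matrix, rows = subjects, columns = clusters,
#'   cells = deepest-pit depth or NA.
#' @return named numeric vector of per-cluster mean depths.
#' @export
cluster_mean_depth <- function(depth_table) {
  depth_table <- as.matrix(depth_table)
  if (length(depth_table) == 0L) stop("empty depth table")
  if (is.null(colnames(depth_table)))
    colnames(depth_table) <- as.character(seq_len(ncol(depth_table)))
  means <- colMeans(depth_table, na.rm = TRUE)
  empty <- !is.finite(means)
  if (any(empty)) {
    warning(sprintf("%d cluster(s) with no observations excluded from classification",
                    sum(empty)))
    means <- means[!empty]
  }
  means
}

#' Classify folds into primary sulci, secondary sulci and dimples
#'
#' One-dimensional k-means (default k = 3, 100 seeded restarts, best
#' within-class sum of squares kept) on the per-cluster mean depths.
#' Class names are assigned by descending centroid: the deepest class is
#' "primary", then "secondary", the shallowest "dimple". For k other
#' than 3 classes are named class1 (deepest) .. classk.
#'
#' @param cluster_depths named numeric vector from
#'   \code{\link{cluster_mean_depth}}.
#' @param k number of classes (default 3).
#' @param replicates number of random restarts (default 100).
#' @param seed RNG seed making the restarts reproducible.
#' @return object of class \code{sulcal_class_map}: list with
#'   \code{classes} (named character vector per cluster),
#'   \code{centroids} (depth per class, descending) and the parameters.
#' @export
classify_sulci <- function(cluster_depths, k = 3L, replicates = 100L, seed = 1L) {
  k <- as.integer(k)
  replicates <- as.integer(replicates)
  if (k < 2L) stop("k must be >= 2")
  if (replicates < 1L) stop("replicates must be >= 1")
  x <- as.numeric(cluster_depths)
  if (length(unique(x)) < k) stop("fewer than k distinct depth values; cannot classify")
  if (length(x) == k) {
    # one value per class: the optimal partition is trivially each alone
    km <- list(cluster = seq_along(x), centers = matrix(x, ncol = 1))
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    km <- stats::kmeans(x, centers = k, nstart = replicates, iter.max = 100L)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  ord <- order(-as.vector(km$centers))
  class_names <- if (k == 3L) c("primary", "secondary", "dimple")
                 else paste0("class", seq_len(k))
  cls <- class_names[match(km$cluster, ord)]
  names(cls) <- names(cluster_depths)
  centroids <- as.vector(km$centers)[ord]
  names(centroids) <- class_names
  structure(list(classes = cls, centroids = centroids,
                 k = k, replicates = replicates, seed = seed),
            class = "sulcal_class_map")
}

#' @export
print.sulcal_class_map <- function(x, ...) {
  cat("sulcal_class_map:\n")
  print(table(factor(x$classes, levels = names(x$centroids))))
  cat("centroids:", paste(sprintf("%s=%.3g", names(x$centroids), x$centroids),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Count a subject's pits per sulcal class
#'
#' Each pit of the subject is carried to the template through the
#' hemisphere's correspondence, assigned the group cluster at its
#' template vertex and then that cluster's class. Returns the counts for
#' primary, secondary and dimple classes plus the total; pits landing on
#' a cluster absent from the class map (or on an unassigned vertex) go
#' to a diagnostic "unassigned" bucket, included in the total.
#'
#' @param hemi_results list of \code{pit_extraction} objects (one per
#'   hemisphere of the subject).
#' @param corrs list of \code{vertex_correspondence} objects aligned with
#'   \code{hemi_results}.
#' @param cmaps list of \code{group_cluster_map} objects aligned with
#'   \code{hemi_results} (the same map repeated for a symmetric template).
#' @param classes a \code{sulcal_class_map} whose names are cluster
#'   labels of the corresponding cluster map, prefixed by hemisphere for
#'   multi-map use (see \code{\link{run_pipeline}}) or plain labels when a
#'   single map is used.
#' @param cluster_prefixes optional character vector, one per hemisphere,
#'   prepended to cluster labels before lookup in \code{classes} (used
#'   when left and right parcellations were classified jointly).
#' @return named integer vector: primary, secondary, dimple, unassigned,
#'   total.
#' @export
count_pits <- function(hemi_results, corrs, cmaps, classes,
                       cluster_prefixes = NULL) {
  if (!inherits(classes, "sulcal_class_map")) stop("classes must be a sulcal_class_map")
  n_h <- length(hemi_results)
  if (length(corrs) != n_h || length(cmaps) != n_h)
    stop("hemi_results, corrs and cmaps must be aligned lists")
  if (is.null(cluster_prefixes)) cluster_prefixes <- rep("", n_h)
  counts <- c(primary = 0L, secondary = 0L, dimple = 0L, unassigned = 0L)
  for (h in seq_len(n_h)) {
    res <- hemi_results[[h]]
    pits <- res$basins$pit_vertex
    if (length(pits) == 0L) next
    tmpl_v <- corrs[[h]]$mapping[pits]
    labs <- cmaps[[h]]$cluster_labels[tmpl_v]
    keys <- paste0(cluster_prefixes[h], labs)
    cls <- unname(classes$classes[keys])
    cls[is.na(labs) | is.na(cls)] <- "unassigned"
    for (cl in cls) {
      if (cl %in% names(counts)) counts[cl] <- counts[cl] + 1L
      else counts["unassigned"] <- counts["unassigned"] + 1L
    }
  }
  if (counts["unassigned"] > 0L)
    warning(sprintf("%d pit(s) fell outside the classified clusters", counts["unassigned"]))
  c(counts, total = sum(counts))
}
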