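#' Pipeline configuration
#'
#' All tunable parameters of the sulcal-pits pipeline with their
#' published defaults: subject watershed thresholds (ThR = 1.5,
#' ThD = 20, ThA = 50), group watershed thresholds (gThR = 2, gThD = 15,
#' gThA = 100), texture smoothing (FWHM 5 mm, 60 iterations), DPF
#' regularization alpha = 0.03, fold classification (k = 3,
#' 100 k-means replicates) and significance level 0.05. Every value can
#' be overridden; validation happens here, before any computation.
#'
#' @param pit_thresholds subject-level \code{\link{thresholds}}.
#' @param g_thresholds \code{\link{group_thresholds}} for the parcellation.
#' @param smoothing \code{\link{smoothing_params}}.
#' @param dpf_alpha DPF regularization constant.
#' @param k,replicates fold-classification parameters.
#' @param alpha_level significance level for all tests.
#' @param min_pit_depth basins whose pit depth is at or below this DPF
#'   value are not treated as sulcal pits in the counting and depth
#'   tables (default 0: the DPF sign convention puts sulci at positive
#'   values, so a non-positive "pit" sits on a gyral crown or flat
#'   background, not in a fold).
#' @param cohort a \code{\link{cohort_spec}} describing the synthetic
#'   cohort to run on (real-data runs pass surfaces directly to the
#'   stage functions).
#' @param seed seed for the analysis stages (classification restarts).
#' @export
pipeline_config <- function(pit_thresholds = thresholds(),
                            g_thresholds = group_thresholds(),
                            smoothing = smoothing_params(),
                            dpf_alpha = 0.03,
                            k = 3L, replicates = 100L,
                            alpha_level = 0.05,
                            min_pit_depth = 0,
                            cohort = cohort_spec(),
                            seed = 1L) {
  if (!inherits(pit_thresholds, "pit_thresholds") ||
      !inherits(g_thresholds, "pit_thresholds"))
    stop("pit_thresholds and g_thresholds must be thresholds objects")
  if (!is.list(smoothing) || is.null(smoothing$fwhm) || is.null(smoothing$n_iter))
    stop("smoothing must come from smoothing_params()")
  smoothing <- smoothing_params(smoothing$fwhm, smoothing$n_iter) # re-validate
  if (!is.finite(dpf_alpha) || dpf_alpha <= 0) stop("dpf_alpha must be positive")
  if (!is.finite(alpha_level) || alpha_level <= 0 || alpha_level >= 1)
    stop("alpha_level must be in (0, 1)")
  if (!inherits(cohort, "cohort_spec")) stop("cohort must be a cohort_spec")
  if (!is.finite(min_pit_depth)) stop("min_pit_depth must be finite")
  structure(list(pit_thresholds = pit_thresholds, g_thresholds = g_thresholds,
                 smoothing = smoothing, dpf_alpha = dpf_alpha,
                 k = as.integer(k), replicates = as.integer(replicates),
                 alpha_level = alpha_level, min_pit_depth = min_pit_depth,
                 cohort = cohort, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Restrict an extraction to sulcal basins
#'
#' Drops basins whose pit depth does not exceed \code{min_depth} from
#' the basin table (their vertices keep their labels in
#' \code{vertex_labels}; they are simply not counted as sulcal pits).
#' With the package's sign convention, depth 0 separates sulcal from
#' gyral/background catchments.
#'
#' @param result a \code{pit_extraction}.
#' @param min_depth minimum pit depth (exclusive), default 0.
#' @return a \code{pit_extraction} with the filtered basin table.
#' @export
sulcal_basins <- function(result, min_depth = 0) {
  if (!inherits(result, "pit_extraction")) stop("result must be a pit_extraction")
  result$basins <- result$basins[result$basins$pit_depth > min_depth, , drop = FALSE]
  result
}

#' Subject-by-cluster deepest-pit depth table
#'
#' For every subject, carries each pit to the template through the
#' hemisphere's correspondence and records, per group cluster, the DPF
#' of the deepest pit falling in it (NA when the subject has no pit
#' there) — the table feeding all per-cluster statistics.
#'
#' @param results list of \code{pit_extraction} objects, one per subject.
#' @param corrs list of \code{\link{vertex_correspondence}} objects
#'   aligned with \code{results}.
#' @param cmap the \code{group_cluster_map} on the template.
#' @param subject_ids row names for the table.
#' @return numeric matrix subjects x clusters with NAs.
#' @export
cluster_depth_table <- function(results, corrs, cmap, subject_ids) {
  build_depth_table(results, corrs, cmap, subject_ids)
}

# subject-by-cluster deepest-pit depth table on a template parcellation
build_depth_table <- function(results, corrs, cmap, subject_ids) {
  K <- cmap$K
  tab <- matrix(NA_real_, length(results), K,
                dimnames = list(subject_ids, as.character(seq_len(K))))
  for (i in seq_along(results)) {
    res <- results[[i]]
    if (nrow(res$basins) == 0L) next
    tv <- corrs[[i]]$mapping[res$basins$pit_vertex]
    labs <- cmap$cluster_labels[tv]
    for (b in seq_along(labs)) {
      j <- labs[b]
      if (is.na(j)) next
      d <- res$basins$pit_depth[b]
      if (is.na(tab[i, j]) || d > tab[i, j]) tab[i, j] <- d
    }
  }
  tab
}

#' Run the full sulcal-pits analysis on a synthetic cohort
#'
#' Executes every stage in order: cohort generation, per-hemisphere DPF
#' depth maps, shape descriptors and subject-normalized thresholds, pit
#' extraction, pit-texture smoothing and projection, group density maps
#' and watershed parcellations (per-hemisphere and symmetric), depth
#' tiers by k-means, per-subject pit counts, and the full statistical
#' battery (count and age regressions, per-cluster depth tests with
#' BH-FDR over both hemispheres, AI group tests and within-group
#' hemispheric RM-ANOVAs on the symmetric parcellation).
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir optional directory; when given, tidy CSV outputs and a
#'   JSON run log are written there.
#' @return a result bundle (list); see the elements in the examples of
#'   the package vignette.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  set.seed(config$seed)
  stage <- "cohort generation"
  bundle <- try({
    cohort <- make_cohort(config$cohort)
    subjects <- cohort$subjects
    n <- nrow(subjects)
    hemis <- c("left", "right")

    stage <- "depth mapping and pit extraction"
    per <- list(left = vector("list", n), right = vector("list", n))
    desc <- list(left = matrix(NA_real_, n, 2), right = matrix(NA_real_, n, 2))
    for (h in hemis) {
      for (i in seq_len(n)) {
        mesh <- cohort$hemis[[i]][[h]]$mesh
        ops <- laplace_operators(mesh)
        dm <- depth_potential_function(mesh, alpha = config$dpf_alpha, ops = ops)
        sd_ <- shape_descriptors(mesh, ops = ops)
        per[[h]][[i]] <- list(mesh = mesh, ops = ops, depth = dm, desc = sd_)
        desc[[h]][i, ] <- c(sd_$fiedler_length, sd_$surface_area)
      }
    }
    g_fl <- lapply(desc, function(m) mean(m[, 1]))
    g_sa <- lapply(desc, function(m) mean(m[, 2]))

    log_rows <- list()
    for (h in hemis) {
      for (i in seq_len(n)) {
        p <- per[[h]][[i]]
        th <- normalize_thresholds(config$pit_thresholds,
                                   fl = p$desc$fiedler_length,
                                   sa = p$desc$surface_area,
                                   g_fl = g_fl[[h]], g_sa = g_sa[[h]])
        res <- sulcal_basins(extract_pits(p$mesh, p$depth, th),
                             config$min_pit_depth)
        tex <- smooth_texture(p$mesh, pit_indicator_texture(res, p$mesh),
                              config$smoothing, ops = p$ops)
        per[[h]][[i]]$pits <- res
        per[[h]][[i]]$texture <- tex
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          subject_id = subjects$subject_id[i], hemisphere = h,
          fl = p$desc$fiedler_length, sa = p$desc$surface_area,
          thr = th$thr, thd = th$thd, tha = th$tha,
          n_pits = nrow(res$basins), stringsAsFactors = FALSE)
      }
    }
    threshold_log <- do.call(rbind, log_rows)

    stage <- "group parcellation"
    corr_id <- identity_correspondence(cohort$base$left)
    cmaps <- list()
    for (h in hemis) {
      proj <- lapply(per[[h]], function(p) project_texture(p$texture, corr_id))
      dens <- density_map(proj)
      cmaps[[h]] <- group_watershed(cohort$base[[h]], dens, config$g_thresholds)
    }
    cmap_sym <- build_symmetric_parcellation(
      lapply(per$left, `[[`, "texture"), lapply(per$right, `[[`, "texture"),
      corr_id, corr_id, cohort$base$left, config$g_thresholds)

    stage <- "depth tables"
    tabs <- list(
      left = build_depth_table(lapply(per$left, `[[`, "pits"),
                               rep(list(corr_id), n), cmaps$left, subjects$subject_id),
      right = build_depth_table(lapply(per$right, `[[`, "pits"),
                                rep(list(corr_id), n), cmaps$right, subjects$subject_id),
      sym_left = build_depth_table(lapply(per$left, `[[`, "pits"),
                                   rep(list(corr_id), n), cmap_sym, subjects$subject_id),
      sym_right = build_depth_table(lapply(per$right, `[[`, "pits"),
                                    rep(list(corr_id), n), cmap_sym, subjects$subject_id))

    stage <- "fold classification"
    depths_l <- cluster_mean_depth(tabs$left)
    depths_r <- cluster_mean_depth(tabs$right)
    joint <- c(stats::setNames(depths_l, paste0("L", names(depths_l))),
               stats::setNames(depths_r, paste0("R", names(depths_r))))
    class_map <- classify_sulci(joint, k = config$k,
                                replicates = config$replicates, seed = config$seed)

    stage <- "pit counting"
    counts <- t(vapply(seq_len(n), function(i) {
      count_pits(list(per$left[[i]]$pits, per$right[[i]]$pits),
                 list(corr_id, corr_id), list(cmaps$left, cmaps$right),
                 class_map, cluster_prefixes = c("L", "R"))
    }, numeric(5)))
    counts <- data.frame(subject_id = subjects$subject_id, counts,
                         stringsAsFactors = FALSE)

    stage <- "statistics"
    count_group <- do.call(rbind, lapply(c("primary", "secondary", "dimple", "total"),
      function(cl) cbind(class = cl, group_age_regression(counts[[cl]], subjects))))
    count_age <- do.call(rbind, lapply(c("primary", "secondary", "dimple", "total"),
      function(cl) cbind(class = cl, age_regression(counts[[cl]], subjects))))

    fam_asym <- cmaps$left$K + cmaps$right$K
    depth_stats <- rbind(
      cbind(hemisphere = "left",
            per_cluster_tests(tabs$left, subjects, family_size = fam_asym,
                              alpha = config$alpha_level)),
      cbind(hemisphere = "right",
            per_cluster_tests(tabs$right, subjects, family_size = fam_asym,
                              alpha = config$alpha_level)))
    # one BH family across both hemispheres
    depth_stats$q <- bh_adjust(depth_stats$p, fam_asym)
    depth_stats$significant <- !is.na(depth_stats$q) & depth_stats$q < config$alpha_level

    ai_stats <- ai_group_tests(tabs$sym_left, tabs$sym_right, subjects,
                               family_size = cmap_sym$K, alpha = config$alpha_level)
    hemi_stats <- list(
      control = within_group_hemisphere_test(tabs$sym_left, tabs$sym_right, subjects,
                                             group = "control",
                                             family_size = cmap_sym$K,
                                             alpha = config$alpha_level),
      case = within_group_hemisphere_test(tabs$sym_left, tabs$sym_right, subjects,
                                          group = "case",
                                          family_size = cmap_sym$K,
                                          alpha = config$alpha_level))

    list(subjects = subjects, cohort = cohort,
         cluster_maps = list(left = cmaps$left, right = cmaps$right, sym = cmap_sym),
         class_map = class_map, counts = counts,
         depth_tables = tabs,
         stats = list(count_group = count_group, count_age = count_age,
                      depth = depth_stats, ai = ai_stats, hemisphere = hemi_stats),
         log = list(config = unclass(config), group_means = list(fl = g_fl, sa = g_sa),
                    thresholds = threshold_log))
  }, silent = TRUE)
  if (inherits(bundle, "try-error"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 attr(bundle, "condition")$message))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  utils::write.csv(bundle$counts, file.path(out_dir, "pit_counts.csv"), row.names = FALSE)
  utils::write.csv(bundle$stats$count_group, file.path(out_dir, "count_group_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$stats$count_age, file.path(out_dir, "count_age_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$stats$depth, file.path(out_dir, "depth_cluster_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$stats$ai, file.path(out_dir, "ai_cluster_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$stats$hemisphere$control,
                   file.path(out_dir, "hemi_rmanova_control.csv"), row.names = FALSE)
  utils::write.csv(bundle$stats$hemisphere$case,
                   file.path(out_dir, "hemi_rmanova_case.csv"), row.names = FALSE)
  utils::write.csv(bundle$log$thresholds, file.path(out_dir, "thresholds_log.csv"),
                   row.names = FALSE)
  cls <- data.frame(cluster = names(bundle$class_map$classes),
                    class = unname(bundle$class_map$classes),
                    stringsAsFactors = FALSE)
  utils::write.csv(cls, file.path(out_dir, "cluster_classes.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$log, file.path(out_dir, "run_log.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(out_dir)
}
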