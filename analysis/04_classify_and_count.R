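#!/usr/bin/env Rscript
# Stage 4 — depth-tier classification and pit-number statistics.
#
# Builds the subject-by-cluster deepest-pit depth tables on the
# per-hemisphere parcellations, averages them per cluster, classifies
# the clusters into primary sulci / secondary sulci / dimples with 1-D
# k-means (k = 3, 100 replicates), counts each subject's pits per class
# across both hemispheres, and runs the group (age-adjusted) and simple
# age regressions on the counts.

suppressMessages(library(sulcalpits))

subjects <- read.csv("results/cohort/subjects.csv")
basins <- read.csv("results/pit_basins.csv")
template <- read_surface("results/cohort/S001_left.surf.gii")
corr <- read_correspondence("results/cohort/correspondence_identity.csv",
                            nrow(template$vertices))

as_extraction <- function(df) structure(list(
  basins = data.frame(label = seq_len(nrow(df)), pit_vertex = df$pit_vertex,
                      pit_depth = df$pit_depth, area = df$area,
                      n_vertices = df$n_vertices),
  vertex_labels = integer(0), thresholds_used = thresholds()),
  class = "pit_extraction")
results <- function(hemi) lapply(subjects$subject_id, function(sid)
  as_extraction(basins[basins$subject_id == sid & basins$hemisphere == hemi, ]))

cmap <- function(hemi) {
  labs <- as.integer(round(read_gifti_shape(
    sprintf("results/clusters_%s.shape.gii", hemi))))
  structure(list(cluster_labels = labs, K = max(labs),
                 clusters = read.csv(sprintf("results/clusters_%s.csv", hemi)),
                 symmetric = FALSE), class = "group_cluster_map")
}
cm <- list(left = cmap("left"), right = cmap("right"))
corrs <- rep(list(corr), nrow(subjects))

res <- list(left = results("left"), right = results("right"))
tabs <- lapply(c(left = "left", right = "right"), function(h)
  cluster_depth_table(res[[h]], corrs, cm[[h]], subjects$subject_id))
write.csv(cbind(subject_id = rownames(tabs$left), as.data.frame(tabs$left)),
          "results/depth_table_left.csv", row.names = FALSE)
write.csv(cbind(subject_id = rownames(tabs$right), as.data.frame(tabs$right)),
          "results/depth_table_right.csv", row.names = FALSE)

joint <- c(setNames(cluster_mean_depth(tabs$left),
                    paste0("L", colnames(tabs$left))),
           setNames(cluster_mean_depth(tabs$right),
                    paste0("R", colnames(tabs$right))))
classes <- classify_sulci(joint, k = 3, replicates = 100, seed = 1)
write.csv(data.frame(cluster = names(classes$classes),
                     class = unname(classes$classes)),
          "results/cluster_classes.csv", row.names = FALSE)
cat("cluster classes (both hemispheres):\n")
print(classes)

counts <- t(vapply(seq_len(nrow(subjects)), function(i) {
  count_pits(list(res$left[[i]], res$right[[i]]),
             list(corr, corr), list(cm$left, cm$right), classes,
             cluster_prefixes = c("L", "R"))
}, numeric(5)))
counts <- data.frame(subject_id = subjects$subject_id, counts)
write.csv(counts, "results/pit_counts.csv", row.names = FALSE)

cls <- c("primary", "secondary", "dimple", "total")
count_group <- do.call(rbind, lapply(cls, function(cl)
  cbind(class = cl, group_age_regression(counts[[cl]], subjects))))
count_age <- do.call(rbind, lapply(cls, function(cl)
  cbind(class = cl, age_regression(counts[[cl]], subjects))))
write.csv(count_group, "results/count_group_stats.csv", row.names = FALSE)
write.csv(count_age, "results/count_age_stats.csv", row.names = FALSE)

cat("\npit-number group effects (case - control, age-adjusted):\n")
print(count_group, digits = 3)
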