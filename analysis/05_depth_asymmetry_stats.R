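#!/usr/bin/env Rscript
# Stage 5 — per-cluster depth, asymmetry and hemispheric statistics.
#
# Runs the age-adjusted group comparison of deepest-pit depth in every
# cluster of both hemispheres (one BH-FDR family across all clusters),
# the group comparison of the asymmetry index AI = (L-R)/(L+R) on the
# symmetric parcellation, and the within-group hemisphere RM-ANOVAs.

suppressMessages(library(sulcalpits))

subjects <- read.csv("results/cohort/subjects.csv")
basins <- read.csv("results/pit_basins.csv")
template <- read_surface("results/cohort/S001_left.surf.gii")
corr <- read_correspondence("results/cohort/correspondence_identity.csv",
                            nrow(template$vertices))
corrs <- rep(list(corr), nrow(subjects))

as_extraction <- function(df) structure(list(
  basins = data.frame(label = seq_len(nrow(df)), pit_vertex = df$pit_vertex,
                      pit_depth = df$pit_depth, area = df$area,
                      n_vertices = df$n_vertices),
  vertex_labels = integer(0), thresholds_used = thresholds()),
  class = "pit_extraction")
results <- function(hemi) lapply(subjects$subject_id, function(sid)
  as_extraction(basins[basins$subject_id == sid & basins$hemisphere == hemi, ]))

tab_l <- as.matrix(read.csv("results/depth_table_left.csv", row.names = 1))
tab_r <- as.matrix(read.csv("results/depth_table_right.csv", row.names = 1))
colnames(tab_l) <- sub("^X", "", colnames(tab_l))
colnames(tab_r) <- sub("^X", "", colnames(tab_r))

# depth comparisons: one FDR family over all clusters of both hemispheres
fam <- ncol(tab_l) + ncol(tab_r)
depth_stats <- rbind(
  cbind(hemisphere = "left", per_cluster_tests(tab_l, subjects, family_size = fam)),
  cbind(hemisphere = "right", per_cluster_tests(tab_r, subjects, family_size = fam)))
depth_stats$q <- bh_adjust(depth_stats$p, fam)
depth_stats$significant <- !is.na(depth_stats$q) & depth_stats$q < 0.05
write.csv(depth_stats, "results/depth_cluster_stats.csv", row.names = FALSE)
cat(sprintf("depth comparisons: %d of %d clusters significant after FDR\n",
            sum(depth_stats$significant), fam))

# symmetric parcellation: AI group tests and hemisphere RM-ANOVAs
sym_labs <- as.integer(round(read_gifti_shape("results/clusters_sym.shape.gii")))
cm_sym <- structure(list(cluster_labels = sym_labs, K = max(sym_labs),
                         clusters = read.csv("results/clusters_sym.csv"),
                         symmetric = TRUE), class = "group_cluster_map")
sym_l <- cluster_depth_table(results("left"), corrs, cm_sym, subjects$subject_id)
sym_r <- cluster_depth_table(results("right"), corrs, cm_sym, subjects$subject_id)

ai_stats <- ai_group_tests(sym_l, sym_r, subjects, family_size = cm_sym$K)
write.csv(ai_stats, "results/ai_cluster_stats.csv", row.names = FALSE)
cat(sprintf("AI comparisons: %d of %d symmetric clusters significant after FDR\n",
            sum(ai_stats$significant, na.rm = TRUE), cm_sym$K))

for (grp in c("control", "case")) {
  hs <- within_group_hemisphere_test(sym_l, sym_r, subjects, group = grp,
                                     family_size = cm_sym$K)
  write.csv(hs, sprintf("results/hemi_rmanova_%s.csv", grp), row.names = FALSE)
  cat(sprintf("hemisphere RM-ANOVA (%s): %d significant clusters\n",
              grp, sum(hs$significant, na.rm = TRUE)))
}
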