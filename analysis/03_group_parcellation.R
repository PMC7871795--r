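#!/usr/bin/env Rscript
# Stage 3 — group density maps and watershed parcellations.
#
# Averages the smoothed pit textures across subjects into per-hemisphere
# density maps, parcellates each with the group watershed (gThR = 2,
# gThD = 15, gThA = 100), and builds the symmetric parcellation by
# pooling both hemispheres of every subject on the left template through
# the interhemispheric correspondence. Writes cluster label fields and
# cluster summary tables.

suppressMessages(library(sulcalpits))

subjects <- read.csv("results/cohort/subjects.csv")
template <- list(
  left = read_surface("results/cohort/S001_left.surf.gii", hemisphere = "left"),
  right = read_surface("results/cohort/S001_right.surf.gii", hemisphere = "right"))
# parcellation runs on the shared-topology template; use the base
# connectivity of any subject (topology is identical across the cohort)
corr <- read_correspondence("results/cohort/correspondence_identity.csv",
                            nrow(template$left$vertices))

tex <- function(sid, hemi)
  read_gifti_shape(sprintf("results/textures/%s_%s.shape.gii", sid, hemi))

cmaps <- list()
for (hemi in c("left", "right")) {
  proj <- lapply(subjects$subject_id,
                 function(sid) project_texture(tex(sid, hemi), corr))
  dens <- density_map(proj)
  cmaps[[hemi]] <- group_watershed(template[[hemi]], dens, group_thresholds())
  write_gifti_shape(cmaps[[hemi]]$cluster_labels,
                    sprintf("results/clusters_%s.shape.gii", hemi))
  write.csv(cmaps[[hemi]]$clusters,
            sprintf("results/clusters_%s.csv", hemi), row.names = FALSE)
}
cm_sym <- build_symmetric_parcellation(
  lapply(subjects$subject_id, tex, hemi = "left"),
  lapply(subjects$subject_id, tex, hemi = "right"),
  corr, corr, template$left, group_thresholds())
write_gifti_shape(cm_sym$cluster_labels, "results/clusters_sym.shape.gii")
write.csv(cm_sym$clusters, "results/clusters_sym.csv", row.names = FALSE)

cat(sprintf("parcellation: %d clusters left, %d right, %d symmetric\n",
            cmaps$left$K, cmaps$right$K, cm_sym$K))
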