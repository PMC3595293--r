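#!/usr/bin/env Rscript
# Distance-matrix analyses of the synthetic survey: community similarity
# between habitats, geographic distances, permutation Mantel tests
# (community vs geography; habitat-type/pH vs geography), PCA on the
# detection matrix, and occurrence-similarity clustering of the probes.
# Outputs: results/mantel.json, results/pca_scores.tsv,
# results/pca_loadings.tsv, results/probe_clusters.tsv

suppressPackageStartupMessages(library(limnodiv))
seed <- 1L

scores <- read_score_table("results/synthetic/scores.tsv")
habitats <- read_habitat_table("results/synthetic/habitats.tsv")
b <- binarize(scores)

cs <- community_similarity(b, method = "simple-matching")
geo <- geo_distance(habitats, method = "great-circle")
dph <- env_delta_matrix(habitats, "ph")

m_geo <- mantel(cs$distance, geo, n_permutations = 10000L,
                tail = "one-sided-positive", seed = seed)
m_ph <- mantel(dph, geo, n_permutations = 10000L,
               tail = "one-sided-positive", seed = seed + 1L)
cat("Community dissimilarity vs geographic distance: ")
print(m_geo)
cat("Habitat-type (delta pH) vs geographic distance: ")
print(m_ph)
jsonlite::write_json(
  list(community_vs_geography = unclass(m_geo)[c("r", "p", "n_permutations",
                                                 "tail")],
       ph_vs_geography = unclass(m_ph)[c("r", "p", "n_permutations",
                                         "tail")]),
  "results/mantel.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

pca <- pca_binary(b)
cat(sprintf("PCA axes 1+2 explain %.1f%% of detection variability\n",
            100 * sum(pca$explained_fraction[1:2])))
utils::write.table(data.frame(habitat_id = rownames(pca$scores),
                              round(pca$scores[, 1:4], 4)),
                   "results/pca_scores.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(data.frame(probe = rownames(pca$loadings),
                              round(pca$loadings[, 1:4], 4)),
                   "results/pca_loadings.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cl <- cluster_probes(b, k = 4L)
clusters <- data.frame(probe = names(cl$assignment),
                       cluster = unname(cl$assignment))
utils::write.table(clusters, "results/probe_clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Probe clusters (occurrence similarity, average linkage, k = 4):\n")
for (k in sort(unique(clusters$cluster))) {
  cat(sprintf("  cluster %d: %s\n", k,
              paste(clusters$probe[clusters$cluster == k], collapse = ", ")))
}
if (length(cl$unplaced) > 0) {
  cat("  unplaced (no occurrence variance):",
      paste(cl$unplaced, collapse = ", "), "\n")
}
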