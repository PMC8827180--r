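#!/usr/bin/env Rscript
# Stage 2: z-score the eight symptom subscales, choose the number of
# clusters with the gap statistic, cut the Ward tree, and report internal
# validity indices.

suppressPackageStartupMessages(library(transdx))

seed <- 20260927
out <- "results/analysis"
cohort <- read_subject_table(file.path(out, "cohort.csv"))

fm <- zscore(cohort, symptom_columns())
gap <- gap_statistic(fm, k_max = 15, B = 100,
                     seed = child_seed(seed, "gap"))
cat("Gap statistic selects k =", gap$selected_k, "\n")
utils::write.csv(gap$table, file.path(out, "02_gap_curve.csv"),
                 row.names = FALSE)
ggplot2::ggsave(file.path(out, "02_gap_curve.png"), plot_gap_curve(gap),
                width = 6, height = 4, dpi = 150)

k <- max(gap$selected_k, 2)
solution <- hierarchical_cluster(fm, k = k)
idx <- internal_indices(fm, solution$labels)
cat(sprintf("Internal indices at k = %d: silhouette %.2f, CH %.2f, Dunn %.2f\n",
            k, idx$silhouette, idx$calinski_harabasz, idx$dunn))

png(file.path(out, "02_dendrogram.png"), width = 900, height = 500)
plot(solution$tree, labels = FALSE, hang = -1,
     main = "Ward dendrogram of symptom z-scores", xlab = "", sub = "")
dev.off()

utils::write.csv(data.frame(subject_id = fm$subjects,
                            cluster = solution$labels),
                 file.path(out, "02_cluster_labels.csv"), row.names = FALSE)
utils::write.csv(as.data.frame(idx),
                 file.path(out, "02_internal_indices.csv"),
                 row.names = FALSE)
cat("Wrote gap curve, dendrogram, labels and indices under", out, "\n")
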