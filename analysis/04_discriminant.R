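#!/usr/bin/env Rscript
# Stage 4: linear discriminant validation of the clusters — confusion
# table and accuracy (resubstitution and 5-fold CV), and a 3-component PCA
# projection for visualization.

suppressPackageStartupMessages(library(transdx))

seed <- 20260927
out <- "results/analysis"
cohort <- read_subject_table(file.path(out, "cohort.csv"))
labels <- utils::read.csv(file.path(out, "02_cluster_labels.csv"))$cluster

fm <- zscore(cohort, symptom_columns())
model <- fit_lda(fm, labels)
conf <- confusion_and_accuracy(labels, predict_lda(model, fm))
cv <- cv_lda_accuracy(fm, labels, folds = 5,
                      seed = child_seed(seed, "cv"))
cat(sprintf("LDA accuracy: %.1f%% resubstitution, %.1f%% 5-fold CV\n",
            100 * conf$accuracy, 100 * cv))
print(conf$counts)

utils::write.csv(as.data.frame(conf$counts),
                 file.path(out, "04_confusion.csv"), row.names = FALSE)
pca <- pca_project(fm, 3)
proj <- data.frame(subject_id = fm$subjects, cluster = labels,
                   pca$scores)
utils::write.csv(proj, file.path(out, "04_pca_projection.csv"),
                 row.names = FALSE)
plt <- ggplot2::ggplot(proj, ggplot2::aes(PC1, PC2,
                                          colour = factor(cluster))) +
  ggplot2::geom_point() +
  ggplot2::labs(colour = "cluster") +
  ggplot2::theme_minimal()
ggplot2::ggsave(file.path(out, "04_pca_scatter.png"), plt,
                width = 6, height = 4.5, dpi = 150)
cat(sprintf("PCA explained variance: %s\n",
            paste(round(100 * pca$explained, 1), collapse = "% / ")))
cat("Wrote confusion table and PCA projection under", out, "\n")
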