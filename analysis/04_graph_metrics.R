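#!/usr/bin/env Rscript
# Stage 4: what do trophic levels capture topologically?
#
# For each subject's GEC: out/in strength ratio, directed weighted
# clustering, mean path length and betweenness; OLS of z-scored trophic
# levels on the four z-scored metrics, pooled across subjects, plus the
# directedness-vs-asymmetry association.

suppressMessages(library(trophicbrain))

cohort_dir <- "results/cohort"
gec_dir <- "results/gec"
hier_dir <- "results/hierarchy"
out_dir <- "results/graph_metrics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta <- read.delim(file.path(cohort_dir, "metadata.tsv"))
levels_tab <- read.delim(file.path(hier_dir, "trophic_levels.tsv"))
glob <- read.delim(file.path(hier_dir, "global_metrics.tsv"))

metric_list <- lapply(meta$subject, function(s) {
  C <- as.matrix(read.delim(file.path(gec_dir, paste0(s, ".tsv"))))
  suppressWarnings(compute_metrics(C))
})
# a layered anatomical support has no triangles, so clustering can be
# identically zero; keep only metrics informative for every subject
usable <- Reduce(`&`, lapply(metric_list, function(m)
  vapply(m, function(x) all(is.finite(x)) && sd(x) > 0, logical(1))))
cat("Metrics used:", paste(names(usable)[usable], collapse = ", "), "\n")
res <- do.call(rbind, lapply(seq_along(metric_list), function(i) {
  m <- metric_list[[i]][, usable, drop = FALSE]
  h <- as.numeric(levels_tab[i, -1])
  fit <- suppressWarnings(regress_trophic_on_metrics(h, m))
  data.frame(subject = meta$subject[i], t(fit$coefficients),
             r_squared = fit$r_squared, t(fit$r))
}))
names(res) <- sub("\\.1$", "_r", names(res))
write.table(res, file.path(out_dir, "trophic_metric_regression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Mean within-subject R^2 of trophic ~ four metrics:",
    round(mean(res$r_squared), 3), "\n")
r_cols <- grep("_r$", names(res), value = TRUE)
cat("Mean per-metric correlations with trophic level:\n")
print(round(colMeans(res[r_cols]), 3))

# directedness against the Frobenius asymmetry of the same GECs
ct <- cor.test(glob$directedness, glob$asymmetry)
cat(sprintf("directedness vs asymmetry: r = %.3f (p = %.2g)\n",
            ct$estimate, ct$p.value))
write.table(data.frame(r = ct$estimate, p = ct$p.value),
            file.path(out_dir, "directedness_asymmetry.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
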