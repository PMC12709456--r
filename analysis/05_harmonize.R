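#!/usr/bin/env Rscript
# Stage 5: multi-site harmonization of the derived measures.
#
# Regional trophic levels, directedness and the regional biomarkers carry
# planted additive/multiplicative site effects only insofar as the
# acquisition noise differs; here ComBat removes between-site differences
# in the regional measures while preserving age and diagnosis effects.
# Applied separately per measure at the regional level, before network
# averaging.

suppressMessages(library(trophicbrain))

cohort_dir <- "results/cohort"
hier_dir <- "results/hierarchy"
out_dir <- "results/harmonized"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta <- read.delim(file.path(cohort_dir, "metadata.tsv"))
levels_tab <- read.delim(file.path(hier_dir, "trophic_levels.tsv"))
glob <- read.delim(file.path(hier_dir, "global_metrics.tsv"))
map <- read.delim(file.path(cohort_dir, "network_map.tsv"))

keep <- filter_unique_sites(meta)
meta_k <- meta[keep$kept, ]
if (nrow(keep$excluded)) {
  cat("Excluded", nrow(keep$excluded), "subjects with unique sites\n")
}
cov_df <- data.frame(age = meta_k$age, gender = meta_k$gender,
                     education = meta_k$education,
                     diagnosis = factor(meta_k$group))

harmonize_one <- function(Y, label) {
  model <- fit_combat(Y, meta_k$site, cov_df)
  Yh <- apply_combat(model, Y, meta_k$site, cov_df)
  rep <- check_harmonization(Y, Yh, meta_k$site, meta_k$group, meta_k$age,
                             n_perm = 300, seed = 7)
  cat(sprintf("%s: %d/%d features site-free after harmonization\n", label,
              sum(rep$site_p_post > 0.05), ncol(Y)))
  Yh
}

measures <- list(
  trophic = as.matrix(levels_tab[keep$kept, -1]),
  amyloid = as.matrix(read.delim(
    file.path(cohort_dir, "biomarkers_amyloid.tsv"))[keep$kept, -1]),
  tau = as.matrix(read.delim(
    file.path(cohort_dir, "biomarkers_tau.tsv"))[keep$kept, -1]),
  gmv = as.matrix(read.delim(
    file.path(cohort_dir, "biomarkers_gmv.tsv"))[keep$kept, -1]))

for (nm in names(measures)) {
  Yh <- harmonize_one(measures[[nm]], nm)
  write.table(cbind(subject = meta_k$subject, as.data.frame(Yh)),
              file.path(out_dir, paste0(nm, "_regional.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # network-level means AFTER regional harmonization
  nw <- t(apply(Yh, 1, network_average, mapping = map$network))
  write.table(cbind(subject = meta_k$subject, as.data.frame(nw)),
              file.path(out_dir, paste0(nm, "_network.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# directedness is a single global feature; harmonize alongside F0
gl <- as.matrix(glob[keep$kept, c("F0", "directedness", "asymmetry")])
glh <- harmonize_one(gl, "global")
write.table(cbind(subject = meta_k$subject, as.data.frame(glh)),
            file.path(out_dir, "global_harmonized.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
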