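#!/usr/bin/env Rscript
# Stage 6: inferential statistics on the harmonized measures.
#
# (i) Covariate-adjusted permutation tests (age, gender, education) for
#     each group contrast on directedness and on network trophic levels,
#     FDR-corrected;
# (ii) mixed-effects ridge regression of network trophic levels on the
#      ATN biomarkers with a random subject intercept;
# (iii) multiple linear regressions predicting cognition from network
#       trophic levels, adjusting for age, gender, education and APOE-e4.

suppressMessages(library(trophicbrain))

cohort_dir <- "results/cohort"
harm_dir <- "results/harmonized"
out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

meta <- read.delim(file.path(cohort_dir, "metadata.tsv"))
glh <- read.delim(file.path(harm_dir, "global_harmonized.tsv"))
meta <- meta[match(glh$subject, meta$subject), ]
nets <- read.delim(file.path(harm_dir, "trophic_network.tsv"))
amy <- read.delim(file.path(harm_dir, "amyloid_network.tsv"))
tau <- read.delim(file.path(harm_dir, "tau_network.tsv"))
gmv <- read.delim(file.path(harm_dir, "gmv_network.tsv"))
cogn <- read.delim(file.path(cohort_dir, "cognition.tsv"))
cogn <- cogn[match(glh$subject, cogn$subject), ]

cov_df <- meta[, c("age", "gender", "education")]
contrasts <- list(c("HCneg", "HCpos"), c("HCneg", "MCIpos"),
                  c("MCIpos", "ADpos"), c("HCneg", "ADpos"))

## (i) group contrasts on directedness and network levels
rows <- list()
for (ct in contrasts) {
  sel <- meta$group %in% ct
  g <- droplevels(factor(meta$group[sel], levels = ct))
  for (feat in c("directedness", names(nets)[-1])) {
    y <- if (feat == "directedness") glh$directedness[sel] else
      nets[sel, feat]
    r <- permutation_group_test(y, g, cov_df[sel, ], n_perm = 5000,
                                seed = 11)
    rows[[length(rows) + 1]] <- data.frame(
      contrast = paste(ct, collapse = "_vs_"), feature = feat,
      t = r$statistic, p = r$p_value)
  }
}
tests <- do.call(rbind, rows)
adj <- fdr_bh(tests$p)
tests$p_adj <- adj$adjusted
tests$significant <- adj$rejected
write.table(tests, file.path(out_dir, "group_contrasts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Significant contrasts after FDR:\n")
print(tests[tests$significant, c("contrast", "feature", "p_adj")],
      row.names = FALSE)

## (ii) ATN biomarkers -> network trophic levels (long format)
nw_names <- names(nets)[-1]
long <- do.call(rbind, lapply(nw_names, function(nw) {
  data.frame(subject = glh$subject, network = nw,
             trophic = nets[[nw]], A = amy[[nw]], T = tau[[nw]],
             N = gmv[[nw]],
             age = meta$age, gender = meta$gender,
             education = meta$education, apoe4 = meta$apoe4)
}))
ridge <- ridge_mixed_fit(long, "trophic", c("A", "T", "N"),
                         covariates = c("age", "gender", "education",
                                        "apoe4"),
                         n_perm = 500, seed = 13)
cat(sprintf("Ridge-mixed betas (penalty %.3g): A=%.3f T=%.3f N=%.3f\n",
            ridge$penalty, ridge$betas[["A"]], ridge$betas[["T"]],
            ridge$betas[["N"]]))
cat("Permutation p:", paste(names(ridge$p_values),
                            signif(ridge$p_values, 3), collapse = ", "),
    "\n")
write.table(data.frame(predictor = names(ridge$betas),
                       beta = ridge$betas,
                       p = ridge$p_values[match(names(ridge$betas),
                                                names(ridge$p_values))]),
            file.path(out_dir, "ridge_atn.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## (iii) cognition from network trophic levels
cg <- cognition_regression(cogn[, c("mmse", "adas13", "cdr_sb", "moca")],
                           nets[, -1],
                           data.frame(age = meta$age, gender = meta$gender,
                                      education = meta$education,
                                      apoe4 = meta$apoe4))
write.table(cg, file.path(out_dir, "cognition_regressions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Cognition models: %d of %d (score, network) pairs significant after FDR\n",
            sum(cg$significant), nrow(cg)))
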