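#!/usr/bin/env Rscript
# Stage 5 - interpretation: SHAP attributions and the clinical screen.
#
# Exact linear SHAP contributions of the combined classifier on the test
# rows of each step (which feature families carry the decision), and the
# Spearman correlation screen of the 13 clinical features against grade.

suppressPackageStartupMessages(library(habicat))
seed <- 20260922L

if (!file.exists("results/run/run.rds"))
  stop("run analysis/03_features_harmonize.R first")
run <- readRDS("results/run/run.rds")

for (stp in c("model1", "model2")) {
  mod <- run$models[[stp]]
  tb <- run$wide[[stp]]
  test_rows <- tb[tb$subject_id %in% mod$split$test, , drop = FALSE]
  sh <- shap_linear(mod$classifiers$total, test_rows)
  cat("\ntop 10 features by mean |SHAP|,", stp, "combined classifier:\n")
  print(head(sh$summary, 10), row.names = FALSE)
  top <- head(sh$summary, 10)$feature
  cat(sprintf("habitat-derived features in the top 10: %d\n",
              sum(grepl("^H[12]_", top))))
  write.csv(sh$summary, file.path("results/run", paste0("shap_", stp, ".csv")),
            row.names = FALSE)
}

cat("\nclinical Spearman screen (rho, p):\n")
print(transform(run$clinical_screen, rho = round(rho, 3),
                p_value = signif(p_value, 3)), row.names = FALSE)
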