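#!/usr/bin/env Rscript
# Step 4: the statistical studies.
#   (a) single-predictor logistic mixed models over the time baseline, per
#       metric (which predictor helps most on its own?);
#   (b) AIC-forward-selected full models (do the effects survive mutual
#       control?);
#   (c) the same analyses after excluding function words;
#   (d) correct-vs-predicted error analyses per metric.
# All models: hit ~ fixed effects + (1 | corpus) + (1 + time | word).

suppressPackageStartupMessages(library(distboot))

run <- readRDS("scratch/run.rds")
candidates <- c("log_diversity", "avg_cond_prob", "log_frequency", "median_ig")

all_rows <- list()
for (metric in c("cosine", "numeric_overlap")) {
  for (excl in c(FALSE, TRUE)) {
    label <- paste0(metric, ifelse(excl, "_content_only", "_all_words"))
    res <- analyze_study(run, metric = metric, exclude_function_words = excl,
                         candidates = candidates, nAGQ = 0)
    # single-predictor table (AIC-ranked) and the selected full model
    for (nm in names(res$selection$single)) {
      ct <- coef_table(res$selection$single[[nm]])
      if (is.null(ct)) next
      ct$model <- paste0("single_", nm)
      ct$dataset <- label
      all_rows[[length(all_rows) + 1L]] <- ct
    }
    ct <- coef_table(res$selection$final)
    ct$model <- paste0("full[", paste(res$selection$selected, collapse = "+"), "]")
    ct$dataset <- label
    all_rows[[length(all_rows) + 1L]] <- ct
    base <- res$selection$baseline
    cat(sprintf("\n== %s ==\n", label))
    cat(sprintf("baseline AIC %.1f; selected terms: %s (AIC %.1f, mr2 %.4f, cr2 %.4f)\n",
                base$aic, paste(res$selection$selected, collapse = ", "),
                res$selection$final$aic, res$selection$final$marginal_r2,
                res$selection$final$conditional_r2))
    print(res$selection$final$terms, digits = 3)
    if (!excl) {
      ea <- res$errors
      write.csv(ea$observed, sprintf("results/04_errors_observed_%s.csv", metric))
      write.csv(round(ea$residuals, 3),
                sprintf("results/04_errors_residuals_%s.csv", metric))
      diag_ok <- all(diag(ea$flags) == "positive")
      cat(sprintf("error analysis: all diagonal cells positive-significant: %s\n",
                  diag_ok))
    }
  }
}
coefs <- do.call(rbind, all_rows)
write.csv(coefs, "results/04_model_coefficients.csv", row.names = FALSE)
cat("\nCoefficient tables written to results/04_model_coefficients.csv\n")
cat("The headline pattern: contextual diversity carries a positive effect and\n")
cat("average conditional probability a negative one in the cosine full model;\n")
cat("see the vignette for how this relates to the predictability account.\n")
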