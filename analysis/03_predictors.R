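#!/usr/bin/env Rscript
# Step 3: the distributional predictors. Summarize log frequency, log
# contextual diversity, average conditional probability given contexts, and
# median information gain across the analysis vocabulary, and their
# correlation structure (all four are collinear to some degree; the models in
# step 4 address this by comparing single-predictor and full fits).

suppressPackageStartupMessages(library(distboot))

run <- readRDS("scratch/run.rds")
outcomes <- run$outcomes[run$outcomes$metric == "cosine", ]
tab <- assemble_table(outcomes, run$predictors)
write.csv(tab, "results/03_analysis_table.csv", row.names = FALSE)

vars <- c("log_frequency", "log_diversity", "avg_cond_prob", "median_ig")
summ <- do.call(rbind, lapply(vars, function(v) data.frame(
  predictor = v,
  mean = round(mean(tab[[v]]), 4),
  sd = round(sd(tab[[v]]), 4),
  min = round(min(tab[[v]]), 4),
  max = round(max(tab[[v]]), 4)
)))
write.csv(summ, "results/03_predictor_summary.csv", row.names = FALSE)
cors <- round(cor(tab[, c(vars, "hit")]), 3)
write.csv(cors, "results/03_predictor_correlations.csv")

cat(sprintf(
  "Analysis table: %d observations over %d words shared by all %d corpora\n",
  nrow(tab), length(unique(tab$word_id)), length(unique(tab$corpus_id))))
cat("(words present in every corpus's 50% prefix, frequency-1 observations dropped).\n\n")
print(summ, row.names = FALSE)
cat("\nPredictor correlations (note the strong frequency-diversity collinearity):\n")
print(cors)
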