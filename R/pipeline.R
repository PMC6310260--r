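#' Run the longitudinal categorization experiment over a set of corpora
#'
#' For each corpus: assigns homograph-distinct word keys, builds the seven
#' cumulative time slices, accumulates the word-context co-occurrence matrix
#' at each slice, runs leave-one-out 1-NN categorization under each requested
#' metric, and computes the distributional predictors. Corpora are processed
#' independently and in order; all randomness derives from `seed`.
#'
#' @param corpora list of `tagged_corpus` objects (or a study from
#'   [generate_study()], whose corpora are used).
#' @param metrics distance metrics to run (`"cosine"`, `"numeric_overlap"`).
#' @param seed master seed; the tie-break RNG of each (corpus, slice, metric)
#'   run is derived from it deterministically.
#' @param ig_weighting forwarded to [compute_predictors()].
#' @param out_dir optional directory: outcome and predictor CSVs plus a
#'   machine-readable manifest are written there.
#' @return a `study_run`: list with `outcomes` (rows over corpora, slices,
#'   metrics), `predictors` (rows over corpora and slices), `seed`, `metrics`.
#' @export
run_study <- function(corpora,
                      metrics = c("cosine", "numeric_overlap"),
                      seed = 1L,
                      ig_weighting = "token",
                      out_dir = NULL) {
  if (!is.null(corpora$corpora)) corpora <- corpora$corpora
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(length(corpora) >= 1)
  outcome_parts <- list()
  predictor_parts <- list()
  for (ci in seq_along(corpora)) {
    corpus <- assign_word_keys(corpora[[ci]])
    events <- context_events(corpus)
    schedule <- slice_schedule(n_utterances(corpus))
    for (si in seq_len(nrow(schedule))) {
      slice <- schedule[si, ]
      mat <- build_cooccurrence(corpus, slice, events = events)
      for (mi in seq_along(metrics)) {
        cfg <- categorizer_config(
          metric = metrics[mi],
          rng_seed = (seed + 1009L * ci + 101L * si + mi) %% .Machine$integer.max
        )
        outcome_parts[[length(outcome_parts) + 1L]] <- run_categorization(mat, cfg)
      }
      predictor_parts[[length(predictor_parts) + 1L]] <-
        compute_predictors(mat, ig_weighting = ig_weighting)
    }
  }
  run <- structure(list(
    outcomes = do.call(rbind, outcome_parts),
    predictors = do.call(rbind, predictor_parts),
    seed = seed, metrics = metrics
  ), class = "study_run")
  if (!is.null(out_dir)) write_study_run(run, out_dir)
  run
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf("<study_run: %d outcome rows, %d predictor rows, metrics: %s, seed %d>\n",
              nrow(x$outcomes), nrow(x$predictors),
              paste(x$metrics, collapse = ", "), x$seed))
  invisible(x)
}

write_study_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(outcomes = "outcomes.csv", predictors = "predictors.csv")
  write.csv(run$outcomes, file.path(out_dir, files["outcomes"]), row.names = FALSE)
  write.csv(run$predictors, file.path(out_dir, files["predictors"]), row.names = FALSE)
  params <- list(seed = run$seed, metrics = run$metrics)
  manifest <- list(
    parameters = params,
    config_hash = config_hash(params),
    files = unname(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

config_hash <- function(params) {
  # dependency-light stable hash: sum of byte values of the serialized params
  s <- paste(deparse(params), collapse = "")
  sprintf("%08x", sum(as.integer(charToRaw(s)) * seq_along(charToRaw(s))) %%
            .Machine$integer.max)
}

#' Fit the full statistical analysis for one metric
#'
#' Assembles the filtered analysis table for one distance metric, fits the
#' Study-1-style single-predictor models and the forward-selected full model,
#' and computes the correct-vs-predicted error analysis on the filtered
#' outcomes.
#'
#' @param run a `study_run` from [run_study()].
#' @param metric which metric's outcomes to analyze.
#' @param exclude_function_words drop FUNCT words before modelling.
#' @param candidates candidate predictor columns for selection.
#' @param nAGQ forwarded to the model fits.
#' @return list with `table`, `selection` (see [forward_select()]), and
#'   `errors` (an `error_analysis`).
#' @export
analyze_study <- function(run, metric = "cosine",
                          exclude_function_words = FALSE,
                          candidates = c("log_diversity", "avg_cond_prob",
                                         "log_frequency", "median_ig"),
                          nAGQ = 1L) {
  outcomes <- run$outcomes[run$outcomes$metric == metric, ]
  if (nrow(outcomes) == 0) stop("no outcomes for metric: ", metric)
  tab <- assemble_table(outcomes, run$predictors,
                        exclude_function_words = exclude_function_words)
  selection <- forward_select(tab, candidates, nAGQ = nAGQ)
  keys <- paste(tab$corpus_id, tab$time_index, tab$word_id)
  out_keys <- paste(outcomes$corpus_id, outcomes$time_index,
                    paste(outcomes$wordform, outcomes$fine_tag, sep = "."))
  errors <- error_analysis(outcomes[out_keys %in% keys, ])
  list(table = tab, selection = selection, errors = errors)
}
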