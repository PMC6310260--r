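#' Assemble the filtered analysis table
#'
#' Joins categorization outcomes to predictor records and applies the
#' analysis filters: keep only words (identified across corpora by
#' wordform + fine tag) that occur in *every* sub-corpus of the run; that are
#' already present in the first 50% prefix of each sub-corpus (so all seven
#' time points carry a measurement, or close to it); drop individual
#' observations with token frequency 1 (a single occurrence fully determines
#' diversity, creating a perfect correlation between two predictors); and
#' optionally drop all function words.
#'
#' @param outcomes data.frame from [run_categorization()] (rows over corpora
#'   and slices, a single metric).
#' @param predictors data.frame from [compute_predictors()] (same coverage).
#' @param require_all_corpora keep only words present in every corpus.
#' @param require_first_half keep only words already seen in each corpus's 50%
#'   prefix (time index 1).
#' @param drop_freq1 drop observations with frequency 1 at that slice.
#' @param exclude_function_words drop FUNCT-tagged words.
#' @return data.frame of analysis rows: hit (0/1), corpus_id, word_id,
#'   time_index, log_frequency, log_diversity, avg_cond_prob, median_ig,
#'   frequency, coarse_tag.
#' @export
assemble_table <- function(outcomes, predictors,
                           require_all_corpora = TRUE,
                           require_first_half = TRUE,
                           drop_freq1 = TRUE,
                           exclude_function_words = FALSE) {
  key_cols <- c("corpus_id", "time_index", "word_key")
  tab <- merge(
    outcomes[, c(key_cols, "wordform", "fine_tag", "coarse_tag", "hit")],
    predictors[, c(key_cols, "frequency", "log_frequency", "log_diversity",
                   "avg_cond_prob", "median_ig")],
    by = key_cols
  )
  if (nrow(tab) != nrow(outcomes))
    stop("outcomes and predictors are not keyed identically")
  # cross-corpus word identity: wordform + fine tag (homograph sense indices
  # are assigned per corpus and need not align)
  tab$word_id <- paste(tab$wordform, tab$fine_tag, sep = ".")
  n_corpora <- length(unique(tab$corpus_id))

  if (require_all_corpora) {
    cover <- tapply(tab$corpus_id, tab$word_id, function(x) length(unique(x)))
    keep <- names(cover)[cover == n_corpora]
    tab <- tab[tab$word_id %in% keep, ]
  }
  if (require_first_half) {
    half <- tab[tab$time_index == 1, ]
    cover <- tapply(half$corpus_id, half$word_id, function(x) length(unique(x)))
    keep <- names(cover)[cover == n_corpora]
    tab <- tab[tab$word_id %in% keep, ]
  }
  if (drop_freq1) tab <- tab[tab$frequency > 1, ]
  if (exclude_function_words) tab <- tab[tab$coarse_tag != "FUNCT", ]
  rownames(tab) <- NULL
  tab[, c("hit", "corpus_id", "word_id", "time_index", "coarse_tag",
          "frequency", "log_frequency", "log_diversity", "avg_cond_prob",
          "median_ig")]
}

#' Fit a logistic mixed-effects model of categorization accuracy
#'
#' `hit ~ fixed terms + (1 | corpus) + (1 + time | word)`: by-corpus random
#' intercepts plus by-word random intercepts and slopes over time (the slopes
#' absorb the autocorrelation between outcomes for the same word at successive
#' time points). Time enters the fixed part as a numeric 0-6 term; predictors
#' enter unstandardized on their stated scales. Convergence problems are
#' flagged in the result, never silently ignored.
#'
#' @param table analysis rows from [assemble_table()].
#' @param fixed_terms character vector of fixed-effect column names
#'   (typically starting with `"time_index"`).
#' @param random_spec right-hand-side random structure, as a string.
#' @param nAGQ integration setting passed to [lme4::glmer()]; `0` (penalized
#'   quasi-likelihood at the posterior mode) is markedly faster on large
#'   tables and is used by the pipeline's repeated-seed checks, `1` (Laplace)
#'   for final estimates.
#' @return a `regression_result`: list with `formula`, `terms` (data.frame of
#'   term, beta, se, z), `aic`, `marginal_r2`, `conditional_r2`, `converged`,
#'   `messages`, and the fitted `model`.
#' @export
fit_logistic_mixed <- function(table,
                               fixed_terms = c("time_index"),
                               random_spec = "(1 | corpus_id) + (1 + time_index | word_id)",
                               nAGQ = 1L) {
  stopifnot(all(fixed_terms %in% names(table)))
  if (length(unique(table$corpus_id)) < 2 || length(unique(table$word_id)) < 2)
    stop("need at least 2 corpora and 2 words to fit the random structure")
  rhs <- paste(c(fixed_terms, random_spec), collapse = " + ")
  fml <- stats::as.formula(paste("hit ~", rhs))
  if (length(unique(table$hit)) < 2) {
    return(structure(list(
      formula = deparse(fml), terms = NULL, aic = NA_real_,
      marginal_r2 = NA_real_, conditional_r2 = NA_real_,
      converged = FALSE,
      messages = "constant response (complete separation): model not estimable",
      model = NULL), class = "regression_result"))
  }
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(fml, data = table, family = stats::binomial(),
                  nAGQ = nAGQ,
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      error = function(e) e
    ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  if (inherits(fit, "error")) {
    return(structure(list(
      formula = deparse(fml), terms = NULL, aic = NA_real_,
      marginal_r2 = NA_real_, conditional_r2 = NA_real_,
      converged = FALSE, messages = c(msgs, conditionMessage(fit)),
      model = NULL), class = "regression_result"))
  }
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  msgs <- c(msgs, conv_msgs)
  converged <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge|unable to evaluate|degenerate",
               msgs, ignore.case = TRUE))
  cf <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(cf), beta = cf[, "Estimate"],
                      se = cf[, "Std. Error"], z = cf[, "z value"],
                      row.names = NULL, stringsAsFactors = FALSE)
  r2 <- tryCatch(nakagawa_r2_merMod(fit), error = function(e) c(NA_real_, NA_real_))
  structure(list(
    formula = deparse(fml), terms = terms, aic = AIC(fit),
    marginal_r2 = r2[[1]], conditional_r2 = r2[[2]],
    converged = converged, messages = msgs, model = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result>", x$formula, "\n")
  cat(sprintf("  AIC %.1f  mr2 %.4f  cr2 %.4f  converged %s\n",
              x$aic, x$marginal_r2, x$conditional_r2, x$converged))
  if (!is.null(x$terms)) print(x$terms, digits = 4)
  invisible(x)
}

# Marginal / conditional r2 for a logistic merMod: fixed-effect variance over
# fixed + random + distribution-specific variance (pi^2/3 on the logit scale).
# The random-effect variance averages diag(Z Lambda Lambda' Z') over
# observations, which handles random slopes.
nakagawa_r2_merMod <- function(fit) {
  X <- lme4::getME(fit, "X")
  beta <- lme4::fixef(fit)
  var_f <- var(as.vector(X %*% beta))
  Z <- lme4::getME(fit, "Z")
  Lambda <- lme4::getME(fit, "Lambda")
  zl <- Z %*% Lambda
  var_r <- mean(Matrix::rowSums(zl^2))
  denom <- var_f + var_r + pi^2 / 3
  c(marginal_r2 = var_f / denom, conditional_r2 = (var_f + var_r) / denom)
}

#' Marginal and conditional r-squared of a fitted model
#'
#' @param result a converged `regression_result`.
#' @return named numeric vector `marginal_r2`, `conditional_r2`.
#' @export
nakagawa_r2 <- function(result) {
  if (!isTRUE(result$converged) || is.null(result$model))
    stop("r-squared undefined for a non-converged fit")
  nakagawa_r2_merMod(result$model)
}

#' Single-predictor fits and AIC-based forward selection
#'
#' First fits each candidate alone on top of the baseline (the Study-1 style
#' analysis) and ranks candidates by AIC. Then builds the full model forward:
#' at each step the candidate with the greatest AIC reduction is added;
#' selection stops when no candidate reduces the AIC or the augmented model
#' fails to converge. Fit errors for individual candidates are recorded, not
#' fatal.
#'
#' @param table analysis rows from [assemble_table()].
#' @param candidate_terms character vector of candidate predictor columns.
#' @param baseline_terms fixed terms always present (default time).
#' @param nAGQ forwarded to [fit_logistic_mixed()].
#' @return list with `baseline`, `single` (list of `regression_result`, AIC
#'   ranked), `path` (results of each accepted step), `final` (last accepted
#'   model), `selected` (character vector of terms added, in order).
#' @export
forward_select <- function(table, candidate_terms,
                           baseline_terms = c("time_index"), nAGQ = 1L) {
  if (length(intersect(candidate_terms, baseline_terms)) > 0)
    stop("candidates must be disjoint from baseline terms")
  safe_fit <- function(terms) {
    tryCatch(fit_logistic_mixed(table, terms, nAGQ = nAGQ),
             error = function(e) structure(list(
               formula = paste(terms, collapse = "+"), terms = NULL,
               aic = NA_real_, marginal_r2 = NA_real_, conditional_r2 = NA_real_,
               converged = FALSE, messages = conditionMessage(e), model = NULL),
               class = "regression_result"))
  }
  baseline <- safe_fit(baseline_terms)
  single <- lapply(candidate_terms, function(tm) safe_fit(c(baseline_terms, tm)))
  names(single) <- candidate_terms
  single <- single[order(vapply(single, function(r)
    ifelse(is.na(r$aic), Inf, r$aic), numeric(1)))]

  current <- baseline
  current_terms <- baseline_terms
  remaining <- candidate_terms
  path <- list()
  selected <- character(0)
  while (length(remaining) > 0 && !is.na(current$aic)) {
    fits <- lapply(remaining, function(tm) safe_fit(c(current_terms, tm)))
    aics <- vapply(fits, function(r) ifelse(is.na(r$aic), Inf, r$aic), numeric(1))
    best <- which.min(aics)
    if (aics[best] >= current$aic) break
    if (!isTRUE(fits[[best]]$converged)) break
    current <- fits[[best]]
    current_terms <- c(current_terms, remaining[best])
    selected <- c(selected, remaining[best])
    path[[length(path) + 1L]] <- current
    remaining <- remaining[-best]
  }
  list(baseline = baseline, single = single, path = path,
       final = current, selected = selected)
}

#' Correct-vs-predicted error analysis
#'
#' Cross-tabulates correct against predicted coarse tags, computes expected
#' counts under independence and standardized Pearson residuals, and flags
#' each cell as positive-significant, negative-significant, or n.s. at
#' `|residual| > 1.96` (conventional mosaic-plot shading; no multiplicity
#' correction).
#'
#' @param outcomes data.frame with `coarse_tag` and `predicted_coarse` columns
#'   (e.g. from [run_categorization()]).
#' @param levels category levels for both axes.
#' @return an `error_analysis`: list with matrices `observed`, `expected`,
#'   `residuals`, and character matrix `flags`.
#' @export
error_analysis <- function(outcomes, levels = COARSE_TAGS) {
  if (nrow(outcomes) == 0) stop("no outcomes to analyze")
  obs <- table(factor(outcomes$coarse_tag, levels = levels),
               factor(outcomes$predicted_coarse, levels = levels))
  obs <- unclass(obs)
  names(dimnames(obs)) <- c("correct", "predicted")
  total <- sum(obs)
  rs <- rowSums(obs); cs <- colSums(obs)
  expected <- outer(rs, cs) / total
  # standardized Pearson residuals: (O - E) / sqrt(E (1 - r/n)(1 - c/n))
  denom <- sqrt(expected * outer(1 - rs / total, 1 - cs / total))
  residuals <- ifelse(denom > 0, (obs - expected) / denom, 0)
  flags <- matrix("n.s.", nrow(obs), ncol(obs), dimnames = dimnames(obs))
  flags[residuals > 1.96] <- "positive"
  flags[residuals < -1.96] <- "negative"
  structure(list(observed = obs, expected = expected,
                 residuals = residuals, flags = flags),
            class = "error_analysis")
}

#' @export
print.error_analysis <- function(x, ...) {
  cat("<error_analysis> observed counts:\n")
  print(x$observed)
  cat("standardized Pearson residuals:\n")
  print(round(x$residuals, 2))
  invisible(x)
}

#' Tidy coefficient table of a regression result
#'
#' @param result a `regression_result`.
#' @return data.frame of terms with beta, se, z, plus aic/r2 columns repeated.
#' @export
coef_table <- function(result) {
  if (is.null(result$terms)) return(NULL)
  out <- result$terms
  out$aic <- result$aic
  out$marginal_r2 <- result$marginal_r2
  out$conditional_r2 <- result$conditional_r2
  out$converged <- result$converged
  out
}
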