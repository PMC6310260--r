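# hand-built outcomes/predictors covering three corpora and three time points,
# with known filter fates for each word
toy_join <- function() {
  words <- list(
    # word_id = wordform.fine_tag; present_in: corpora; first-half: all
    dog = list(wf = "dog", ft = "n", tag = "N", corpora = 1:3),
    cat = list(wf = "cat", ft = "n", tag = "N", corpora = 1:2), # fails all-corpora
    the = list(wf = "the", ft = "det", tag = "FUNCT", corpora = 1:3)
  )
  rows <- list()
  for (w in names(words)) {
    info <- words[[w]]
    for (co in info$corpora) for (t in 0:2) {
      # "rare" pattern: dog has frequency 1 at t=0 in corpus 1 (row dropped)
      freq <- if (w == "dog" && co == 1 && t == 0) 1L else 2L + t
      rows[[length(rows) + 1L]] <- data.frame(
        corpus_id = paste0("c", co), time_index = t, word_key = w,
        wordform = info$wf, fine_tag = info$ft, coarse_tag = info$tag,
        hit = (t %% 2) == 0, frequency = freq,
        log_frequency = log(freq), log_diversity = log(freq + 1),
        avg_cond_prob = 0.5, median_ig = 0.1, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  list(outcomes = tab[, c("corpus_id", "time_index", "word_key", "wordform",
                          "fine_tag", "coarse_tag", "hit")],
       predictors = tab[, c("corpus_id", "time_index", "word_key", "frequency",
                            "log_frequency", "log_diversity", "avg_cond_prob",
                            "median_ig")])
}

test_that("the analysis filters keep exactly the hand-enumerated rows", {
  fx <- toy_join()
  tab <- assemble_table(fx$outcomes, fx$predictors)
  # cat is absent from corpus 3: all its rows are gone
  expect_false("cat.n" %in% tab$word_id)
  # dog loses only its frequency-1 observation (corpus 1, t = 0)
  dog <- tab[tab$word_id == "dog.n", ]
  expect_equal(nrow(dog), 3 * 3 - 1)
  expect_false(any(dog$corpus_id == "c1" & dog$time_index == 0))
  # the function word survives unless excluded
  expect_equal(nrow(tab), 8 + 9)
  tab2 <- assemble_table(fx$outcomes, fx$predictors, exclude_function_words = TRUE)
  expect_equal(unique(tab2$word_id), "dog.n")
  # with filters off, everything survives
  tab3 <- assemble_table(fx$outcomes, fx$predictors,
                         require_all_corpora = FALSE,
                         require_first_half = FALSE, drop_freq1 = FALSE)
  expect_equal(nrow(tab3), nrow(fx$outcomes))
})

test_that("the first-half presence filter uses the 50% slice", {
  fx <- toy_join()
  # remove dog's time-1 rows in corpus 2: it was not seen in that 50% prefix
  miss <- with(fx$outcomes, word_key == "dog" & corpus_id == "c2" & time_index == 1)
  outcomes <- fx$outcomes[!miss, ]
  predictors <- fx$predictors[!(fx$predictors$word_key == "dog" &
                                  fx$predictors$corpus_id == "c2" &
                                  fx$predictors$time_index == 1), ]
  tab <- assemble_table(outcomes, predictors)
  expect_false("dog.n" %in% tab$word_id)
  tab2 <- assemble_table(outcomes, predictors, require_first_half = FALSE)
  expect_true("dog.n" %in% tab2$word_id)
})

test_that("mismatched outcome and predictor keys raise a join error", {
  fx <- toy_join()
  expect_error(assemble_table(fx$outcomes, fx$predictors[-1, ]),
               "not keyed identically")
})

test_that("planted fixed effects are recovered within 3 standard errors", {
  tab <- simulate_glmm_table(1)
  truth <- attr(tab, "truth")
  fit <- fit_logistic_mixed(tab, c("time_index", "log_diversity", "avg_cond_prob"))
  expect_true(fit$converged)
  est <- stats::setNames(fit$terms$beta, fit$terms$term)
  se <- stats::setNames(fit$terms$se, fit$terms$term)
  for (term in c("log_diversity", "avg_cond_prob")) {
    expect_lt(abs(est[[term]] - truth[[term]]), 3 * se[[term]])
  }
  expect_gt(est[["log_diversity"]], 0)
  expect_lt(est[["avg_cond_prob"]], 0)
  expect_true(is.finite(fit$aic))
  expect_true(fit$marginal_r2 <= fit$conditional_r2 &&
                fit$conditional_r2 <= 1)
})

test_that("a pure-noise predictor does not improve the AIC in expectation", {
  imp <- vapply(101:103, function(seed) {
    tab <- simulate_glmm_table(seed, n_words = 60, n_corpora = 5)
    base <- fit_logistic_mixed(tab, c("time_index", "log_diversity",
                                      "avg_cond_prob"), nAGQ = 0)
    noisy <- fit_logistic_mixed(tab, c("time_index", "log_diversity",
                                       "avg_cond_prob", "x_noise"), nAGQ = 0)
    base$aic - noisy$aic
  }, numeric(1))
  expect_lt(mean(imp), 2)
})

test_that("a constant response is reported as non-convergence, not a crash", {
  tab <- simulate_glmm_table(2, n_words = 30, n_corpora = 3)
  tab$hit <- 1L
  fit <- fit_logistic_mixed(tab, "time_index")
  expect_false(fit$converged)
  expect_match(fit$messages[1], "separation")
  expect_true(is.na(fit$aic))
  expect_error(nakagawa_r2(fit), "non-converged")
})

test_that("forward selection finds the planted predictor and stops correctly", {
  tab <- simulate_glmm_table(42, n_words = 60, n_corpora = 5,
                             b_div = 1.0, b_acp = 0)
  # log_diversity is the only real effect among the candidates
  sel <- forward_select(tab, c("log_diversity", "x_noise", "avg_cond_prob"),
                        nAGQ = 0)
  expect_equal(sel$selected[1], "log_diversity")
  expect_equal(names(sel$single)[1], "log_diversity") # best single-predictor AIC
  expect_lt(sel$single[["log_diversity"]]$aic, sel$baseline$aic)
  # a collinear duplicate never enters after the original
  tab$x_dup <- tab$log_diversity
  sel2 <- forward_select(tab, c("log_diversity", "x_dup"), nAGQ = 0)
  expect_equal(sel2$selected, "log_diversity")
  # no predictive candidates: selection stops at the baseline
  sel3 <- forward_select(tab, c("x_noise"), nAGQ = 0)
  expect_length(sel3$selected, 0)
  expect_equal(sel3$final$aic, sel3$baseline$aic)
  expect_error(forward_select(tab, c("time_index")), "disjoint")
})

test_that("r-squared components match their construction", {
  # near-zero random-effect variances: marginal ~ conditional
  tab <- simulate_glmm_table(3, sd_corpus = 0, sd_word = 0.01, sd_slope = 0)
  fit <- fit_logistic_mixed(tab, c("time_index", "log_diversity",
                                   "avg_cond_prob"), nAGQ = 0)
  r2 <- nakagawa_r2(fit)
  expect_lt(r2[["conditional_r2"]] - r2[["marginal_r2"]], 0.02)
  # no fixed variation: marginal 0
  tab2 <- simulate_glmm_table(4, b_time = 0, b_div = 0, b_acp = 0)
  fit2 <- fit_logistic_mixed(tab2, character(0), nAGQ = 0)
  expect_equal(fit2$marginal_r2, 0, tolerance = 1e-10)
  expect_gt(fit2$conditional_r2, 0)
  # planted variance components recover the closed-form ratio
  tab3 <- simulate_glmm_table(5, n_words = 200, n_corpora = 12,
                              sd_corpus = 0.6, sd_word = 0.9, sd_slope = 0)
  fit3 <- fit_logistic_mixed(tab3, c("time_index", "log_diversity",
                                     "avg_cond_prob"))
  truth <- attr(tab3, "truth")
  eta_f <- truth[["(Intercept)"]] + truth[["time_index"]] * tab3$time_index +
    truth[["log_diversity"]] * tab3$log_diversity +
    truth[["avg_cond_prob"]] * tab3$avg_cond_prob
  vf <- var(eta_f); vr <- 0.6^2 + 0.9^2
  expect_equal(nakagawa_r2(fit3)[["marginal_r2"]], vf / (vf + vr + pi^2 / 3),
               tolerance = 0.05)
})

test_that("error-analysis residuals match the chi-square oracle", {
  # hand-built 3x3 table, cross-checked against chisq.test's stdres
  counts <- matrix(c(30, 5, 2, 4, 25, 6, 1, 3, 20), 3, 3, byrow = TRUE,
                   dimnames = list(c("N", "V", "ADJ"), c("N", "V", "ADJ")))
  outcomes <- data.frame(
    coarse_tag = rep(rep(rownames(counts), each = 3), as.vector(t(counts))),
    predicted_coarse = rep(rep(colnames(counts), 3), as.vector(t(counts))))
  ea <- error_analysis(outcomes, levels = c("N", "V", "ADJ"))
  expect_equal(ea$observed, counts, ignore_attr = TRUE)
  oracle <- suppressWarnings(chisq.test(counts))
  expect_equal(ea$expected, oracle$expected, ignore_attr = TRUE)
  expect_equal(ea$residuals, unclass(oracle$stdres), ignore_attr = TRUE)
  expect_equal(sum(ea$expected), sum(ea$observed))
})

test_that("diagonal association and independence are flagged correctly", {
  # perfectly diagonal outcomes: diagonal positive-significant
  diag_out <- data.frame(coarse_tag = rep(COARSE_TAGS, times = c(40, 35, 25, 20, 30)))
  diag_out$predicted_coarse <- diag_out$coarse_tag
  ea <- error_analysis(diag_out)
  expect_true(all(diag(ea$flags) == "positive"))
  # counts proportional to independence: everything n.s.
  rows <- c(N = 40, V = 20); cols <- c(N = 30, V = 30)
  indep <- expand.grid(coarse_tag = names(rows), predicted_coarse = names(cols),
                       stringsAsFactors = FALSE)
  n_rep <- as.vector(outer(rows, cols)) / sum(rows)
  indep <- indep[rep(seq_len(4), n_rep), ]
  ea2 <- error_analysis(indep, levels = c("N", "V"))
  expect_true(all(ea2$flags == "n.s."))
  expect_equal(max(abs(ea2$residuals)), 0, tolerance = 1e-12)
  expect_error(error_analysis(diag_out[0, ]), "no outcomes")
})
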