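# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a cooccurrence_matrix by hand from a dense count matrix.
make_matrix <- function(counts, tags, freq = NULL, time_index = 0L,
                        corpus_id = "fixture") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("w", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  if (is.null(freq)) freq <- rep(1L, nrow(counts))
  words <- rownames(counts)
  structure(list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    word_freq = stats::setNames(as.integer(freq), words),
    context_freq = colSums(counts),
    word_table = data.frame(word_key = words, wordform = words,
                            fine_tag = tolower(tags), coarse_tag = tags,
                            stringsAsFactors = FALSE),
    slice = list(time_index = time_index, fraction = 1, n_utterances = NA_integer_),
    corpus_id = corpus_id
  ), class = "cooccurrence_matrix")
}

# The squirrel configuration: one target plus ten neighbours at the same
# distance from it (under both metrics by construction of the frequencies:
# cosine equidistance via equal angles). Frequencies 6 x 1, 1 x 5, 3 x 10;
# the three most frequent neighbours are two nouns and an adjective.
squirrel_matrix <- function() {
  theta <- seq(0.1, pi / 2 - 0.1, length.out = 10)
  neigh <- cbind(1, sqrt(3) * cos(theta), sqrt(3) * sin(theta))
  counts <- rbind(c(1, 0, 0), neigh)
  rownames(counts) <- c("squirrel", "mouse", "tree", "brown",
                        paste0("filler", 1:7))
  tags <- c("N", "N", "N", "ADJ", "V", "ADJ", "ADV", "FUNCT", "V", "N", "ADV")
  freq <- c(4L, 10L, 10L, 10L, 5L, 1L, 1L, 1L, 1L, 1L, 1L)
  make_matrix(counts, tags, freq)
}

# Independent brute-force categorizer: all pairwise distances via the scalar
# distance functions on dense rows, then the same tie cascade, consuming a
# seeded RNG in row order. Kept deliberately naive (double loops).
naive_categorize <- function(matrix, config) {
  m <- as.matrix(matrix$counts)
  n <- nrow(m)
  words <- rownames(m)
  ranges <- NULL
  if (config$metric == "numeric_overlap") {
    ranges <- list(max = apply(m, 2, max), min = apply(m, 2, min))
    ranges$range <- ranges$max - ranges$min
  }
  set.seed(config$rng_seed)
  out <- list()
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- if (config$metric == "cosine") {
        cosine_distance(m[i, ], m[j, ])
      } else {
        numeric_overlap_distance(m[i, ], m[j, ], ranges)
      }
      d <- c(d, stats::setNames(dij, words[j]))
    }
    dmin <- min(d)
    tied <- which(d - dmin <= config$distance_tie_tol * pmax(pmax(d, dmin), 1e-300))
    freq <- matrix$word_freq[names(d)]
    if (length(tied) > 1) tied <- tied[freq[tied] == max(freq[tied])]
    pick <- if (length(tied) > 1) tied[sample.int(length(tied), 1L)] else tied[1L]
    out[[i]] <- data.frame(word_key = words[i], neighbor_key = names(d)[pick],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Random sparse non-negative count matrix whose rows all have >= 1 nonzero.
random_count_matrix <- function(n_words, n_contexts, density = 0.08) {
  m <- matrix(0L, n_words, n_contexts)
  nnz <- max(1L, round(density * n_words * n_contexts))
  idx <- sample.int(n_words * n_contexts, nnz)
  m[idx] <- sample(1:8, nnz, replace = TRUE)
  empty <- which(rowSums(m) == 0)
  for (i in empty) m[i, sample.int(n_contexts, 1)] <- sample(1:8, 1)
  tags <- sample(COARSE_TAGS, n_words, replace = TRUE)
  freq <- sample(1:30, n_words, replace = TRUE)
  make_matrix(m, tags, freq)
}

# Small synthetic study for fast pipeline tests.
small_spec <- function(seed = 7L, ...) {
  args <- list(
    n_corpora = 3L, n_utterances = 250L,
    vocab_size = c(N = 40L, V = 30L, ADJ = 15L, ADV = 12L, FUNCT = 20L),
    n_templates = c(N = 3L, V = 3L, ADJ = 2L, ADV = 2L),
    n_idiosyncratic = 2L, rng_seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_spec, args)
}

# Analysis table simulated from a logistic mixed model with known
# coefficients and variance components (for parameter-recovery checks).
simulate_glmm_table <- function(seed, n_words = 120, n_corpora = 8,
                                b0 = -0.5, b_time = 0.05,
                                b_div = 0.6, b_acp = -1.5,
                                sd_corpus = 0.5, sd_word = 0.8,
                                sd_slope = 0.15) {
  set.seed(seed)
  g <- expand.grid(word_id = paste0("w", seq_len(n_words)),
                   corpus_id = paste0("c", seq_len(n_corpora)),
                   time_index = 0:6, stringsAsFactors = FALSE)
  uc <- stats::setNames(rnorm(n_corpora, 0, sd_corpus), paste0("c", seq_len(n_corpora)))
  uw <- stats::setNames(rnorm(n_words, 0, sd_word), paste0("w", seq_len(n_words)))
  us <- stats::setNames(rnorm(n_words, 0, sd_slope), paste0("w", seq_len(n_words)))
  g$log_diversity <- rnorm(nrow(g))
  g$avg_cond_prob <- runif(nrow(g))
  g$x_noise <- rnorm(nrow(g))
  eta <- b0 + b_time * g$time_index + b_div * g$log_diversity +
    b_acp * g$avg_cond_prob + uc[g$corpus_id] + uw[g$word_id] +
    us[g$word_id] * g$time_index
  g$hit <- rbinom(nrow(g), 1, stats::plogis(eta))
  attr(g, "truth") <- c(`(Intercept)` = b0, time_index = b_time,
                        log_diversity = b_div, avg_cond_prob = b_acp)
  g
}

# Corpus written to a temp file in the tsv dialect.
write_fixture_corpus <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
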