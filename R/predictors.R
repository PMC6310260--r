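#' Average conditional probability of a unit given its co-occurring units
#'
#' For each co-occurring unit, the co-occurrence count is divided by that
#' unit's total frequency; the resulting conditional probabilities are
#' averaged. In the pipeline this is applied word-given-contexts (counts are
#' the word's co-occurrence counts, marginals the context frequencies), but
#' the computation is direction-agnostic.
#'
#' @param counts numeric vector of co-occurrence counts (> 0), one per unit.
#' @param marginals numeric vector of unit total frequencies, aligned with
#'   `counts` (each marginal >= its count).
#' @return scalar in `(0, 1]`.
#' @examples
#' avg_conditional_probability(c(30, 45, 25), c(40, 50, 25)) # 0.88
#' avg_conditional_probability(c(30, 25, 45), c(150, 100, 200)) # 0.225
#' @export
avg_conditional_probability <- function(counts, marginals) {
  if (length(counts) == 0) stop("no co-occurring units")
  if (length(counts) != length(marginals)) stop("counts and marginals differ in length")
  if (any(counts <= 0)) stop("co-occurrence counts must be positive")
  if (any(counts > marginals)) stop("count exceeds its marginal")
  mean(counts / marginals)
}

entropy_cols <- function(p) {
  # column-wise natural-log entropy of a (classes x columns) probability matrix
  terms <- ifelse(p > 0, -p * log(p), 0)
  colSums(terms)
}

#' Information gain of every context at one slice
#'
#' How much knowing whether a word token co-occurs with context `c` reduces
#' the entropy of the coarse-tag distribution:
#' `IG(c) = H(Y) - P(c) H(Y|c) - P(!c) H(Y|!c)`, with natural-log entropies.
#' By default every co-occurrence event counts as one observation
#' (token-weighted); with `weighting = "type"` each (word, context) pairing
#' counts once regardless of its count.
#'
#' @param matrix a `cooccurrence_matrix`.
#' @param weighting `"token"` (default) or `"type"`.
#' @return named numeric vector, one IG value per context column, each in
#'   `[0, H(Y)]`.
#' @export
information_gain_table <- function(matrix, weighting = c("token", "type")) {
  weighting <- match.arg(weighting)
  m <- matrix$counts
  if (weighting == "type") {
    m <- methods::as(m, "CsparseMatrix")
    m@x <- rep(1, length(m@x))
  }
  tags <- factor(matrix$word_table$coarse_tag, levels = COARSE_TAGS)
  ind <- Matrix::sparseMatrix(
    i = as.integer(tags), j = seq_along(tags), x = 1,
    dims = c(length(COARSE_TAGS), length(tags))
  )
  T_mat <- as.matrix(ind %*% m) # classes x contexts co-occurrence mass
  g <- rowSums(T_mat) # global class mass
  N <- sum(g)
  cf <- colSums(T_mat)
  h_y <- entropy_cols(matrix(g / N, ncol = 1))
  p_c <- cf / N
  h_in <- entropy_cols(sweep(T_mat, 2, pmax(cf, 1e-300), "/"))
  rest <- g - T_mat
  h_out <- entropy_cols(sweep(rest, 2, pmax(N - cf, 1e-300), "/"))
  ig <- h_y - (p_c * h_in + (1 - p_c) * h_out)
  ig[ig < 0] <- 0 # rounding guard
  setNames(ig, colnames(matrix$counts))
}

#' Information gain of a single context
#'
#' @param context a context key (column of the matrix).
#' @param matrix a `cooccurrence_matrix`.
#' @param weighting see [information_gain_table()].
#' @return scalar IG value.
#' @export
information_gain <- function(context, matrix, weighting = c("token", "type")) {
  if (!context %in% colnames(matrix$counts))
    stop("context not in matrix: ", context)
  information_gain_table(matrix, weighting)[[context]]
}

#' Median information gain of a word's co-occurring contexts
#'
#' The IG values of the word's distinct contexts are sorted and the median is
#' taken (midpoint of the two central values for even counts); the median is
#' preferred because context IG distributions are skewed.
#'
#' @param word a word key (row of the matrix).
#' @param matrix a `cooccurrence_matrix`.
#' @param igs optional precomputed [information_gain_table()].
#' @return scalar median IG.
#' @export
median_ig <- function(word, matrix, igs = NULL) {
  if (is.null(igs)) igs <- information_gain_table(matrix)
  i <- match(word, rownames(matrix$counts))
  if (is.na(i)) stop("word not in matrix: ", word)
  row <- matrix$counts[i, ]
  ctx <- names(row)[row > 0]
  if (length(ctx) == 0) stop("word has no contexts")
  median(igs[ctx])
}

#' Distributional predictors for every word at one slice
#'
#' Per word: raw and natural-log token frequency; raw and natural-log
#' contextual diversity (number of distinct co-occurring contexts); average
#' conditional probability of the word given its contexts; and the median
#' information gain of its contexts.
#'
#' @param matrix a `cooccurrence_matrix`.
#' @param ig_weighting forwarded to [information_gain_table()].
#' @return data.frame with one row per word: corpus_id, time_index, word_key,
#'   wordform, fine_tag, coarse_tag, frequency, diversity, log_frequency,
#'   log_diversity, avg_cond_prob, median_ig.
#' @export
compute_predictors <- function(matrix, ig_weighting = "token") {
  m <- methods::as(matrix$counts, "CsparseMatrix")
  n <- nrow(m)
  if (n == 0) stop("empty matrix")
  freq <- as.integer(matrix$word_freq)
  # row-wise distinct-context counts and conditional probabilities via the
  # transposed CSC layout (word index per nonzero)
  mt <- methods::as(Matrix::t(m), "CsparseMatrix")
  word_of_nz <- rep.int(seq_len(n), diff(mt@p))
  ctx_of_nz <- mt@i + 1L # context column index in the original matrix
  diversity <- tabulate(word_of_nz, nbins = n)
  cond <- mt@x / matrix$context_freq[ctx_of_nz]
  avg_cond <- as.numeric(tapply(cond, word_of_nz, mean)[as.character(seq_len(n))])

  igs <- information_gain_table(matrix, ig_weighting)
  ig_of_nz <- igs[ctx_of_nz]
  med_ig <- as.numeric(tapply(ig_of_nz, word_of_nz, median)[as.character(seq_len(n))])

  wt <- matrix$word_table
  data.frame(
    corpus_id = matrix$corpus_id,
    time_index = matrix$slice$time_index,
    word_key = wt$word_key, wordform = wt$wordform,
    fine_tag = wt$fine_tag, coarse_tag = wt$coarse_tag,
    frequency = freq, diversity = diversity,
    log_frequency = log(freq), log_diversity = log(diversity),
    avg_cond_prob = avg_cond, median_ig = med_ig,
    stringsAsFactors = FALSE
  )
}
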