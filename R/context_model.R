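#' Extract the five lexically specific contexts around one token
#'
#' For a target token at `position` (1-based) in an utterance, the contexts
#' are the preceding bigram `w-1_X` (L1), the following bigram `X_w+1` (R1),
#' the preceding trigram `w-2_w-1_X` (L2), the following trigram `X_w+1_w+2`
#' (R2), and the surrounding frame `w-1_X_w+1` (FRAME). Exactly one boundary
#' symbol (`#start` / `#end`) exists on each side of the utterance: it fills
#' the slot immediately outside, and any template needing a slot beyond it is
#' omitted. Elements are homograph-disambiguated word keys.
#'
#' @param keys character vector: the word keys of the utterance tokens, in order.
#' @param position 1-based index of the target token.
#' @return named character vector of context keys (subset of L1, R1, L2, R2,
#'   FRAME, in that order).
#' @examples
#' extract_contexts(c("the", "dog", "barked", "at", "the", "angry", "postman"), 2)
#' @export
extract_contexts <- function(keys, position) {
  L <- length(keys)
  if (position < 1 || position > L) stop("position out of range")
  p <- position
  left1 <- if (p > 1) keys[p - 1] else "#start"
  right1 <- if (p < L) keys[p + 1] else "#end"
  out <- c(L1 = paste0(left1, "_X"), R1 = paste0("X_", right1))
  if (p >= 2) {
    left2 <- if (p > 2) keys[p - 2] else "#start"
    out <- c(out, L2 = paste0(left2, "_", left1, "_X"))
  }
  if (p <= L - 1) {
    right2 <- if (p < L - 1) keys[p + 2] else "#end"
    out <- c(out, R2 = paste0("X_", right1, "_", right2))
  }
  c(out, FRAME = paste0(left1, "_X_", right1))
}

#' Longitudinal slicing schedule
#'
#' Seven cumulative prefixes of the utterance sequence, covering the first
#' 40%, 50%, ..., 100% of utterances. Prefix sizes are
#' `max(1, floor(fraction * total))`; the final slice always covers the whole
#' corpus.
#'
#' @param total_utterances number of utterances in the corpus.
#' @return data.frame with columns `time_index` (0..6), `fraction`,
#'   `n_utterances`.
#' @export
slice_schedule <- function(total_utterances) {
  if (length(total_utterances) != 1 || is.na(total_utterances) || total_utterances < 1)
    stop("total_utterances must be a positive integer")
  fraction <- seq(0.4, 1.0, by = 0.1)
  n <- pmax(1L, as.integer(floor(fraction * total_utterances + 1e-9)))
  n[length(n)] <- as.integer(total_utterances)
  data.frame(time_index = 0:6, fraction = fraction, n_utterances = n)
}

# One (token, context) co-occurrence event per row, for the whole corpus.
# Vectorized over tokens: neighbours within each utterance via shift, boundary
# symbols at the edges, trigram templates beyond a boundary dropped.
context_events <- function(corpus) {
  if (is.null(corpus$tokens$word_key))
    stop("corpus has no word keys; call assign_word_keys() first")
  tok <- data.table::as.data.table(
    corpus$tokens[, c("utterance_id", "position", "word_key")])
  utterance_id <- position <- word_key <- NULL # NSE notes for R CMD check
  data.table::setorder(tok, utterance_id, position)
  tok[, `:=`(
    l1 = data.table::shift(word_key, 1L, fill = "#start"),
    l2 = data.table::shift(word_key, 2L, fill = NA_character_),
    r1 = data.table::shift(word_key, -1L, fill = "#end"),
    r2 = data.table::shift(word_key, -2L, fill = NA_character_)
  ), by = utterance_id]
  n <- nrow(tok)
  p <- tok$position
  L <- tok[, rep(max(position), .N), by = utterance_id]$V1
  # one boundary symbol per side; trigram slot beyond it does not exist
  l2 <- ifelse(p == 1L, NA_character_, ifelse(p == 2L, "#start", tok$l2))
  r2 <- ifelse(p == L, NA_character_, ifelse(p == L - 1L, "#end", tok$r2))
  ctx <- c(
    paste0(tok$l1, "_X"),
    paste0("X_", tok$r1),
    ifelse(is.na(l2), NA, paste0(l2, "_", tok$l1, "_X")),
    ifelse(is.na(r2), NA, paste0("X_", tok$r1, "_", r2)),
    paste0(tok$l1, "_X_", tok$r1)
  )
  ev <- data.table::data.table(
    utterance_id = rep(tok$utterance_id, 5L),
    order_key = rep(seq_len(n), 5L),
    word_key = rep(tok$word_key, 5L),
    context_key = ctx
  )
  ev <- ev[!is.na(ev$context_key)]
  data.table::setorder(ev, order_key)
  ev
}

#' Build a word-context co-occurrence matrix for one time slice
#'
#' Counts every (token, context) co-occurrence event over the first
#' `slice$n_utterances` utterances of the corpus. No restrictions: all words
#' and all contexts enter the matrix. Row and column orderings follow first
#' occurrence in the corpus traversal, so repeated runs are reproducible.
#'
#' @param corpus a `tagged_corpus` with word keys (see [assign_word_keys()]).
#' @param slice one row of [slice_schedule()] (a list/data.frame with
#'   `time_index`, `fraction`, `n_utterances`).
#' @param events optional precomputed result of the internal event extractor;
#'   used by the pipeline to avoid rescanning the corpus per slice.
#' @return a `cooccurrence_matrix`: list with `counts` (sparse word x context
#'   matrix), `word_freq`, `context_freq`, `word_table`, `slice`, `corpus_id`.
#' @export
build_cooccurrence <- function(corpus, slice, events = NULL) {
  if (is.null(events)) events <- context_events(corpus)
  n_utt <- slice$n_utterances
  ev <- events[events$utterance_id <= n_utt, ]
  words <- unique(ev$word_key)
  ctxs <- unique(ev$context_key)
  i <- match(ev$word_key, words)
  j <- match(ev$context_key, ctxs)
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(length(words), length(ctxs)),
    dimnames = list(words, ctxs)
  )
  tok <- corpus$tokens[corpus$tokens$utterance_id <= n_utt, ]
  wf <- table(tok$word_key)
  word_freq <- setNames(as.integer(wf[words]), words)
  wt <- corpus$word_table
  word_table <- wt[match(words, wt$word_key), ]
  rownames(word_table) <- NULL
  structure(list(
    counts = counts,
    word_freq = word_freq,
    context_freq = Matrix::colSums(counts),
    word_table = word_table,
    slice = list(time_index = slice$time_index, fraction = slice$fraction,
                 n_utterances = n_utt),
    corpus_id = corpus$corpus_id
  ), class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf(
    "<cooccurrence_matrix '%s' t=%d (%.0f%%): %d words x %d contexts, %d events>\n",
    x$corpus_id, x$slice$time_index, 100 * x$slice$fraction,
    nrow(x$counts), ncol(x$counts), as.integer(sum(x$counts))))
  invisible(x)
}

#' Export a co-occurrence matrix as sparse-triplet text files
#'
#' Writes a MatrixMarket coordinate file plus two sidecar TSVs with the row
#' (word) and column (context) labels.
#'
#' @param matrix a `cooccurrence_matrix`.
#' @param stem path stem; writes `<stem>.mtx`, `<stem>.words.tsv`,
#'   `<stem>.contexts.tsv`.
#' @return the three paths, invisibly.
#' @export
write_cooccurrence <- function(matrix, stem) {
  mtx <- paste0(stem, ".mtx")
  Matrix::writeMM(matrix$counts, mtx)
  words <- paste0(stem, ".words.tsv")
  ctxs <- paste0(stem, ".contexts.tsv")
  wt <- matrix$word_table
  wt$frequency <- matrix$word_freq[wt$word_key]
  write.table(wt, words, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(context_key = colnames(matrix$counts),
               context_freq = unname(matrix$context_freq)),
    ctxs, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mtx, words, ctxs))
}
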