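#' Configuration for the leave-one-out 1-NN categorizer
#'
#' @param metric `"cosine"` or `"numeric_overlap"`.
#' @param distance_tie_tol relative tolerance under which two distances count
#'   as tied: `|d1 - d2| <= tol * max(d1, d2, eps)`. Floating-point equality is
#'   fragile, and the tie-break cascade needs a well-defined tie set.
#' @param rng_seed integer seed consumed by the random stage of the tie-break.
#' @return a `categorizer_config` list (`k` is fixed at 1).
#' @export
categorizer_config <- function(metric = c("cosine", "numeric_overlap"),
                               distance_tie_tol = 1e-9,
                               rng_seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(distance_tie_tol > 0)
  structure(list(metric = metric, k = 1L,
                 distance_tie_tol = distance_tie_tol,
                 rng_seed = as.integer(rng_seed)),
            class = "categorizer_config")
}

# Tie-break cascade on a distance vector (target excluded upstream):
# 1. all rows within relative tolerance of the minimum distance are tied;
# 2. among ties, keep the most frequent rows (token frequency in the current
#    corpus prefix -- the only frequency available to the learner at that time);
# 3. if several remain, draw uniformly at random (consumes the current RNG).
resolve_neighbor <- function(d, freq, tol) {
  dmin <- min(d)
  tied <- which(d - dmin <= tol * pmax(pmax(d, dmin), 1e-300))
  n_tied <- length(tied)
  if (n_tied > 1) {
    fmax <- max(freq[tied])
    tied <- tied[freq[tied] == fmax]
  }
  n_after_freq <- length(tied)
  if (n_after_freq > 1) {
    pick <- tied[sample.int(n_after_freq, 1L)]
    random <- TRUE
  } else {
    pick <- tied[1L]
    random <- FALSE
  }
  list(neighbor = pick, n_tied = n_tied,
       n_after_freq = n_after_freq, tie_random = random)
}

#' Categorize one word by its nearest neighbour
#'
#' Leave-one-out 1-NN: distances from the target row to every other row of the
#' co-occurrence matrix, then the unique closest row; distance ties are broken
#' by token frequency in the current prefix, remaining ties uniformly at
#' random (using the current RNG state). The word counts as a *hit* when the
#' neighbour's coarse tag matches the target's.
#'
#' @param target a word key (row name of the matrix).
#' @param matrix a `cooccurrence_matrix` with at least 2 rows.
#' @param config a [categorizer_config()]. The metric is taken from it; the
#'   seed is *not* applied here (see [run_categorization()] for seeded runs).
#' @param distances optional precomputed row of pairwise distances (named by
#'   word key, target included); computed on the fly when missing.
#' @return one-row data.frame: word_key, wordform, fine_tag, coarse_tag,
#'   neighbor_key, predicted_coarse, hit, n_tied_at_min_distance,
#'   n_candidates_after_freq, tie_broken_randomly.
#' @export
categorize_word <- function(target, matrix, config, distances = NULL) {
  words <- rownames(matrix$counts)
  if (length(words) < 2) stop("cannot categorize with fewer than 2 words")
  ti <- match(target, words)
  if (is.na(ti)) stop("target word not in matrix: ", target)
  if (is.null(distances)) {
    m <- matrix$counts
    if (config$metric == "cosine") {
      v <- m[ti, ]
      norms <- sqrt(Matrix::rowSums(m^2))
      distances <- as.numeric(1 - (m %*% v) / (norms * sqrt(sum(v^2))))
      distances[distances < 0] <- 0
    } else {
      rng <- column_ranges(m)
      v <- as.numeric(m[ti, ])
      distances <- apply(as.matrix(m), 1, numeric_overlap_distance, b = v, ranges = rng)
    }
    names(distances) <- words
  }
  d <- distances[-ti]
  freq <- matrix$word_freq[-ti]
  res <- resolve_neighbor(d, freq, config$distance_tie_tol)
  neigh <- names(d)[res$neighbor]
  wt <- matrix$word_table
  trow <- wt[wt$word_key == target, ]
  ncoarse <- wt$coarse_tag[wt$word_key == neigh]
  data.frame(
    word_key = target, wordform = trow$wordform, fine_tag = trow$fine_tag,
    coarse_tag = trow$coarse_tag, neighbor_key = neigh,
    predicted_coarse = ncoarse, hit = trow$coarse_tag == ncoarse,
    n_tied_at_min_distance = res$n_tied,
    n_candidates_after_freq = res$n_after_freq,
    tie_broken_randomly = res$tie_random,
    stringsAsFactors = FALSE
  )
}

#' Categorize every word of a co-occurrence matrix
#'
#' Runs leave-one-out 1-NN over all rows. A single seeded RNG is consumed in
#' row order, so runs are bit-reproducible given `config$rng_seed`; the
#' caller's RNG state is left untouched.
#'
#' @param matrix a `cooccurrence_matrix` with at least 2 rows.
#' @param config a [categorizer_config()].
#' @return data.frame with one outcome row per word (columns as in
#'   [categorize_word()], plus corpus_id, time_index, metric).
#' @export
run_categorization <- function(matrix, config) {
  words <- rownames(matrix$counts)
  if (length(words) < 2) stop("cannot categorize with fewer than 2 words")
  D <- pairwise_distances(matrix, config$metric)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$rng_seed)

  n <- length(words)
  wt <- matrix$word_table
  neighbor <- character(n); n_tied <- integer(n)
  n_after <- integer(n); tie_rand <- logical(n)
  for (i in seq_len(n)) {
    res <- resolve_neighbor(D[i, -i], matrix$word_freq[-i], config$distance_tie_tol)
    neighbor[i] <- words[-i][res$neighbor]
    n_tied[i] <- res$n_tied
    n_after[i] <- res$n_after_freq
    tie_rand[i] <- res$tie_random
  }
  pred <- wt$coarse_tag[match(neighbor, wt$word_key)]
  data.frame(
    corpus_id = matrix$corpus_id,
    time_index = matrix$slice$time_index,
    metric = config$metric,
    word_key = words, wordform = wt$wordform, fine_tag = wt$fine_tag,
    coarse_tag = wt$coarse_tag,
    neighbor_key = neighbor, predicted_coarse = pred,
    hit = wt$coarse_tag == pred,
    n_tied_at_min_distance = n_tied,
    n_candidates_after_freq = n_after,
    tie_broken_randomly = tie_rand,
    stringsAsFactors = FALSE
  )
}
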