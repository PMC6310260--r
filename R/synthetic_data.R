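#' Specification for a synthetic child-directed-speech study
#'
#' Describes a multi-corpus, chronologically ordered, tagged synthetic input:
#' short utterances built from function-word carriers with tagged open slots,
#' Zipf-distributed word frequencies within each class, category-selective
#' local contexts with tunable selectivity, homographs carrying two fine tags,
#' and a shared core vocabulary across corpora plus per-corpus idiosyncratic
#' words.
#'
#' @param n_corpora number of longitudinal sub-corpora (13 emulates the real
#'   input of the study design: twelve children plus one).
#' @param n_utterances utterances per corpus.
#' @param vocab_size named integer vector, core vocabulary size per coarse tag.
#' @param zipf_exponent exponent of the rank-frequency law used to draw words
#'   within each class.
#' @param n_templates named integer vector: number of carrier templates whose
#'   open slot prefers each content tag. Carriers are function words, so the
#'   FUNCT class is realized by the carriers themselves.
#' @param selectivity probability, in `[0.2, 1]`, that a template's slot is
#'   filled from its preferred tag; otherwise the filler class is drawn
#'   uniformly from the other classes.
#' @param homograph_rate fraction (in `[0, 0.3]`) of wordforms carrying two
#'   fine tags (realized as noun/verb wordform sharing).
#' @param mean_utterance_length approximate average tokens per utterance
#'   (utterances are carrier-filler pairs; the number of pairs is
#'   1 + geometric; formulaic insertions add slightly to the mean).
#' @param formulaicity maximum per-word probability, in `[0, 1]`, that an
#'   occurrence of a content word is emitted inside its formulaic collocation
#'   (a fixed same-class companion word inserted before it). Each content word
#'   gets a concentration probability between 0 and this value, assigned
#'   quasi-randomly against frequency rank. Formulaic occurrences concentrate
#'   a word's co-occurrence mass in word-specific contexts, raising its
#'   average conditional probability given contexts and lowering its
#'   contextual diversity -- the collocational structure of child-directed
#'   speech that drives the predictability effect.
#' @param n_idiosyncratic per-corpus extra words appended to each content
#'   class (exercises the occurs-in-all-corpora filter).
#' @param tag_weights sampling weights of the content tags for slot targets.
#' @param rng_seed master seed; corpus `i` uses a seed derived from
#'   `(rng_seed, i)`, so corpora are independent but reproducible.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_corpora = 13L,
                           n_utterances = 3000L,
                           vocab_size = c(N = 120L, V = 80L, ADJ = 40L,
                                          ADV = 30L, FUNCT = 40L),
                           zipf_exponent = 1,
                           n_templates = c(N = 4L, V = 4L, ADJ = 3L, ADV = 3L),
                           selectivity = 0.75,
                           homograph_rate = 0.05,
                           mean_utterance_length = 5,
                           formulaicity = 0.6,
                           n_idiosyncratic = 4L,
                           tag_weights = c(N = 0.35, V = 0.30, ADJ = 0.20,
                                           ADV = 0.15),
                           rng_seed = 1L) {
  stopifnot(
    n_corpora >= 1, n_utterances >= 1,
    all(vocab_size >= 1),
    setequal(names(vocab_size), c("N", "V", "ADJ", "ADV", "FUNCT")),
    selectivity >= 0.2, selectivity <= 1,
    homograph_rate >= 0, homograph_rate <= 0.3,
    formulaicity >= 0, formulaicity <= 1,
    mean_utterance_length >= 2,
    all(n_templates >= 1),
    setequal(names(n_templates), c("N", "V", "ADJ", "ADV")),
    sum(n_templates) <= vocab_size[["FUNCT"]]
  )
  structure(list(
    n_corpora = as.integer(n_corpora),
    n_utterances = as.integer(n_utterances),
    vocab_size = vocab_size, zipf_exponent = zipf_exponent,
    n_templates = n_templates, selectivity = selectivity,
    homograph_rate = homograph_rate,
    mean_utterance_length = mean_utterance_length,
    formulaicity = formulaicity,
    n_idiosyncratic = as.integer(n_idiosyncratic),
    tag_weights = tag_weights,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_spec")
}

#' Read / write a synthetic study specification as YAML
#'
#' @param path YAML file path.
#' @return for `read_synthetic_spec`, a `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic_spec(
    n_corpora = y$n_corpora, n_utterances = y$n_utterances,
    vocab_size = unlist(y$vocab_size), zipf_exponent = y$zipf_exponent,
    n_templates = unlist(y$n_templates), selectivity = y$selectivity,
    homograph_rate = y$homograph_rate,
    mean_utterance_length = y$mean_utterance_length,
    formulaicity = y$formulaicity,
    n_idiosyncratic = y$n_idiosyncratic,
    tag_weights = unlist(y$tag_weights),
    rng_seed = y$rng_seed
  )
}

#' @rdname read_synthetic_spec
#' @param spec a `synthetic_spec`.
#' @export
write_synthetic_spec <- function(spec, path) {
  yaml::write_yaml(lapply(unclass(spec), function(x)
    if (length(names(x)) > 0) as.list(x) else x), path)
  invisible(path)
}

#' The shipped reference study specification
#'
#' Loads `reference_study.yaml` from the package, optionally overriding the
#' master seed.
#'
#' @param rng_seed optional seed override.
#' @return a `synthetic_spec`.
#' @export
reference_spec <- function(rng_seed = NULL) {
  spec <- read_synthetic_spec(
    system.file("extdata", "reference_study.yaml", package = "distboot",
                mustWork = TRUE))
  if (!is.null(rng_seed)) spec$rng_seed <- as.integer(rng_seed)
  spec
}

# Deterministic vocabulary shared by all corpora of a study. One row per
# (wordform, fine_tag) entry; homographs realized as noun/verb pairs sharing
# a wordform. No randomness: fully determined by the spec's size fields.
build_vocabulary <- function(spec) {
  vs <- spec$vocab_size
  make_class <- function(tag, n, fine_fun) {
    data.frame(
      wordform = sprintf("%s%03d", tolower(tag), seq_len(n)),
      fine_tag = fine_fun(n),
      coarse_tag = tag,
      rank = seq_len(n),
      stringsAsFactors = FALSE
    )
  }
  vocab <- rbind(
    make_class("N", vs[["N"]], function(n) ifelse(seq_len(n) <= ceiling(n / 8), "pro", "n")),
    make_class("V", vs[["V"]], function(n) ifelse(seq_len(n) <= ceiling(n / 8), "aux", "v")),
    make_class("ADJ", vs[["ADJ"]], function(n) rep("adj", n)),
    make_class("ADV", vs[["ADV"]], function(n) rep("adv", n)),
    make_class("FUNCT", vs[["FUNCT"]], function(n)
      rep(c("det", "prep", "conj", "co", "qn"), length.out = n))
  )
  # homographs: the i-th noun and i-th verb share a wordform, distinct fine tags
  n_homo <- floor(spec$homograph_rate * nrow(vocab))
  n_homo <- min(n_homo, vs[["N"]], vs[["V"]])
  if (n_homo > 0) {
    n_rows <- which(vocab$coarse_tag == "N" & vocab$fine_tag == "n")
    v_rows <- which(vocab$coarse_tag == "V" & vocab$fine_tag == "v")
    n_homo <- min(n_homo, length(n_rows), length(v_rows))
    vocab$wordform[v_rows[seq_len(n_homo)]] <- vocab$wordform[n_rows[seq_len(n_homo)]]
  }
  vocab
}

# Carrier templates: the most frequent FUNCT words, partitioned across the
# content tags; a carrier's open slot prefers its tag with prob = selectivity.
build_templates <- function(spec, vocab) {
  funct <- vocab[vocab$coarse_tag == "FUNCT", ]
  k <- spec$n_templates
  idx <- 0L
  out <- list()
  for (tag in names(k)) {
    rows <- funct[idx + seq_len(k[[tag]]), ]
    out[[tag]] <- rows
    idx <- idx + k[[tag]]
  }
  out
}

zipf_probs <- function(n, a) {
  p <- seq_len(n)^(-a)
  p / sum(p)
}

#' Generate one synthetic tagged corpus
#'
#' Utterances are sequences of carrier-filler pairs: a function-word carrier
#' drawn from the templates of a target tag, followed by an open-slot filler
#' drawn Zipf-wise from the preferred tag with probability `selectivity`,
#' otherwise from a uniformly chosen other class. Fully deterministic given
#' `(spec$rng_seed, corpus_index)`; the caller's RNG state is untouched.
#'
#' @param spec a [synthetic_spec()].
#' @param corpus_index 1-based corpus number.
#' @return a `tagged_corpus` (word keys not yet assigned).
#' @export
generate_corpus <- function(spec, corpus_index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), corpus_index >= 1)
  vocab <- build_vocabulary(spec)
  templates <- build_templates(spec, vocab)
  classes <- c("N", "V", "ADJ", "ADV", "FUNCT")

  # per-corpus idiosyncratic tail words for the content classes
  if (spec$n_idiosyncratic > 0) {
    idio <- do.call(rbind, lapply(c("N", "V", "ADJ", "ADV"), function(tag) {
      n0 <- sum(vocab$coarse_tag == tag)
      data.frame(
        wordform = sprintf("c%02dx%s%02d", corpus_index, tolower(tag),
                           seq_len(spec$n_idiosyncratic)),
        fine_tag = c(N = "n", V = "v", ADJ = "adj", ADV = "adv")[[tag]],
        coarse_tag = tag,
        rank = n0 + seq_len(spec$n_idiosyncratic),
        stringsAsFactors = FALSE
      )
    }))
    vocab <- rbind(vocab, idio)
  }
  class_rows <- lapply(setNames(classes, classes), function(tag) {
    rows <- vocab[vocab$coarse_tag == tag, ]
    rows[order(rows$rank), ]
  })
  class_probs <- lapply(class_rows, function(rows)
    zipf_probs(nrow(rows), spec$zipf_exponent))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$rng_seed + 7919L * as.integer(corpus_index))

  n_utt <- spec$n_utterances
  # pairs per utterance: 1 + geometric, mean pairs = mean length / 2
  mean_pairs <- spec$mean_utterance_length / 2
  n_pairs <- 1L + rgeom(n_utt, prob = 1 / mean_pairs)
  total <- sum(n_pairs)
  utt_of_pair <- rep.int(seq_len(n_utt), n_pairs)

  tags <- sample(names(spec$tag_weights), total, replace = TRUE,
                 prob = spec$tag_weights)
  # carrier: uniform among the preferred tag's templates
  carrier_row <- integer(total)
  for (tag in names(templates)) {
    sel <- which(tags == tag)
    carrier_row[sel] <- sample.int(nrow(templates[[tag]]), length(sel),
                                   replace = TRUE)
  }
  carrier_wf <- character(total); carrier_ft <- character(total)
  for (tag in names(templates)) {
    sel <- which(tags == tag)
    carrier_wf[sel] <- templates[[tag]]$wordform[carrier_row[sel]]
    carrier_ft[sel] <- templates[[tag]]$fine_tag[carrier_row[sel]]
  }
  # filler class: preferred with prob selectivity, else uniform other class
  keep <- runif(total) < spec$selectivity
  filler_class <- tags
  if (any(!keep)) {
    others <- vapply(tags[!keep], function(tag)
      sample(setdiff(classes, tag), 1L), character(1))
    filler_class[!keep] <- others
  }
  filler_wf <- character(total); filler_ft <- character(total)
  phi <- numeric(total) # per-token formulaic-concentration probability
  comp_wf <- character(total); comp_ft <- character(total)
  content <- c("N", "V", "ADJ", "ADV")
  for (tag in classes) {
    sel <- which(filler_class == tag)
    if (length(sel) == 0) next
    rows <- class_rows[[tag]]
    draw <- sample.int(nrow(rows), length(sel), replace = TRUE,
                       prob = class_probs[[tag]])
    filler_wf[sel] <- rows$wordform[draw]
    filler_ft[sel] <- rows$fine_tag[draw]
    if (tag %in% content) {
      # word-specific concentration, quasi-random against frequency rank,
      # and a fixed same-class companion word for the formulaic frame
      nr <- nrow(rows)
      phi[sel] <- spec$formulaicity * (((draw * 61L + 17L) %% 97L) / 96)
      comp <- (draw * 7L + 3L) %% nr + 1L
      comp[comp == draw] <- comp[comp == draw] %% nr + 1L
      comp_wf[sel] <- rows$wordform[comp]
      comp_ft[sel] <- rows$fine_tag[comp]
    }
  }
  formulaic <- runif(total) < phi

  # assemble tokens: carrier [, companion] , filler -- ordered by utterance,
  # pair, then slot within pair
  slot_n <- 2L + formulaic
  tok <- data.frame(
    utterance_id = c(utt_of_pair, utt_of_pair[formulaic], utt_of_pair),
    pair = c(seq_len(total), which(formulaic), seq_len(total)),
    slot = c(rep(1L, total), rep(2L, sum(formulaic)), rep(3L, total)),
    wordform = c(carrier_wf, comp_wf[formulaic], filler_wf),
    fine_tag = c(carrier_ft, comp_ft[formulaic], filler_ft),
    stringsAsFactors = FALSE
  )
  tok <- tok[order(tok$pair, tok$slot), ]
  tok$position <- unlist(lapply(
    tapply(slot_n, utt_of_pair, sum)[as.character(seq_len(n_utt))], seq_len),
    use.names = FALSE)
  tok$coarse_tag <- map_coarse_tag(tok$fine_tag)
  rownames(tok) <- NULL
  new_tagged_corpus(sprintf("synthetic-%02d", corpus_index),
                    tok[, c("utterance_id", "position", "wordform",
                            "fine_tag", "coarse_tag")])
}

#' Generate a full synthetic study
#'
#' `n_corpora` corpora sharing the core vocabulary (so the occurs-in-all-
#' corpora filter retains a known word set) plus per-corpus idiosyncratic
#' words, together with the ground-truth tag map.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `corpora` (list of `tagged_corpus`), `ground_truth`
#'   (data.frame wordform, fine_tag, coarse_tag over the full vocabulary),
#'   and `spec`.
#' @export
generate_study <- function(spec) {
  corpora <- lapply(seq_len(spec$n_corpora), function(i) generate_corpus(spec, i))
  gt <- unique(do.call(rbind, lapply(corpora, function(co)
    co$tokens[, c("wordform", "fine_tag", "coarse_tag")])))
  gt <- gt[order(gt$wordform, gt$fine_tag), ]
  rownames(gt) <- NULL
  list(corpora = corpora, ground_truth = gt, spec = spec)
}

#' Write a synthetic study to disk
#'
#' Emits each corpus in the `tsv` dialect plus a `ground_truth.tsv` and the
#' spec as `spec.yaml`.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (co in study$corpora)
    write_tagged_corpus(co, file.path(dir, paste0(co$corpus_id, ".tsv")))
  write.table(study$ground_truth, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_synthetic_spec(study$spec, file.path(dir, "spec.yaml"))
  invisible(dir)
}
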