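#' distboot: distributional bootstrapping of lexical categories
#'
#' Longitudinal word-context co-occurrence modelling of tagged child-directed
#' speech, unsupervised leave-one-out 1-nearest-neighbour categorization into
#' five coarse lexical categories, distributional predictors of categorization
#' accuracy, and logistic mixed-effects analyses of the outcomes.
#'
#' @useDynLib distboot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats AIC aggregate median rbinom rgeom rpois runif setNames var
#' @importFrom utils head read.table write.csv write.table
#' @keywords internal
"_PACKAGE"

# data.table used via :: throughout
.datatable.aware <- TRUE

#' The five coarse lexical categories
#'
#' Evaluation categories: nouns (including pronouns), verbs (including
#' auxiliaries and non-finite forms), adjectives, adverbs, and a residual
#' function-word bucket collapsing all remaining categories.
#'
#' @export
COARSE_TAGS <- c("N", "V", "ADJ", "ADV", "FUNCT")

# Default fine -> coarse mapping for the CHILDES MOR tag inventory.
# Subtypes ("pro:per", "n:prop", ...) are resolved by stripping everything
# after the first ":". Anything not listed falls into FUNCT (the residual
# bucket) unless strict mode is on.
default_tag_table <- function() {
  c(
    n = "N", pro = "N",
    v = "V", aux = "V", cop = "V", part = "V", mod = "V",
    adj = "ADJ",
    adv = "ADV",
    # common MOR function/other categories, made explicit for readability;
    # unlisted tags fall through to FUNCT anyway
    det = "FUNCT", prep = "FUNCT", conj = "FUNCT", comp = "FUNCT",
    co = "FUNCT", qn = "FUNCT", num = "FUNCT", post = "FUNCT",
    ptl = "FUNCT", inf = "FUNCT", neg = "FUNCT", fil = "FUNCT",
    int = "FUNCT", on = "FUNCT", meta = "FUNCT", wh = "FUNCT"
  )
}

#' Map fine (annotation) tags to the 5 coarse categories
#'
#' Fine tags are lower-cased and subtype suffixes after `":"` are dropped
#' before lookup (`"pro:per"` resolves like `"pro"`). Unknown tags map to
#' `FUNCT`, the residual bucket, unless `strict = TRUE`.
#'
#' @param fine_tag character vector of fine tags.
#' @param mapping named character vector, fine tag -> coarse tag. Entries
#'   override/extend the shipped MOR default table.
#' @param strict error on unknown fine tags instead of bucketing into FUNCT.
#' @return character vector of coarse tags (`N`, `V`, `ADJ`, `ADV`, `FUNCT`).
#' @examples
#' map_coarse_tag(c("pro", "aux", "det", "adj", "n:prop"))
#' @export
map_coarse_tag <- function(fine_tag, mapping = NULL, strict = FALSE) {
  table <- default_tag_table()
  if (!is.null(mapping)) {
    mapping <- vapply(mapping, as.character, character(1))
    bad <- setdiff(unique(mapping), COARSE_TAGS)
    if (length(bad) > 0)
      stop("tag mapping targets outside the coarse set: ", paste(bad, collapse = ", "))
    table[names(mapping)] <- mapping
  }
  base <- sub(":.*$", "", tolower(fine_tag))
  out <- unname(table[base])
  unknown <- is.na(out)
  if (any(unknown)) {
    if (strict)
      stop("unknown fine tag(s): ", paste(unique(fine_tag[unknown]), collapse = ", "))
    out[unknown] <- "FUNCT"
  }
  out
}

#' Read a tag-mapping / pipeline configuration file
#'
#' YAML with optional keys `tag_mapping` (named fine -> coarse overrides) and
#' `strict_tags` (logical).
#'
#' @param path path to a YAML file.
#' @return list with elements `tag_mapping` and `strict_tags`.
#' @export
read_tag_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    tag_mapping = if (is.null(cfg$tag_mapping)) NULL else unlist(cfg$tag_mapping),
    strict_tags = isTRUE(cfg$strict_tags)
  )
}

new_tagged_corpus <- function(corpus_id, tokens) {
  stopifnot(is.data.frame(tokens),
            all(c("utterance_id", "position", "wordform", "fine_tag", "coarse_tag")
                %in% names(tokens)))
  structure(list(corpus_id = corpus_id, tokens = tokens),
            class = "tagged_corpus")
}

#' @export
print.tagged_corpus <- function(x, ...) {
  cat(sprintf("<tagged_corpus '%s': %d utterances, %d tokens>\n",
              x$corpus_id, n_utterances(x), nrow(x$tokens)))
  invisible(x)
}

#' Number of utterances in a tagged corpus
#' @param corpus a `tagged_corpus`.
#' @return integer count.
#' @export
n_utterances <- function(corpus) {
  length(unique(corpus$tokens$utterance_id))
}

#' Build a tagged corpus from utterances given as token/tag pairs
#'
#' Programmatic constructor used by the synthetic generator and tests.
#'
#' @param corpus_id identifier string.
#' @param utterances list; each element a data.frame (or list) with `wordform`
#'   and `fine_tag` vectors for one utterance, in order.
#' @param mapping,strict forwarded to [map_coarse_tag()].
#' @return a `tagged_corpus`.
#' @export
tagged_corpus <- function(corpus_id, utterances, mapping = NULL, strict = FALSE) {
  if (length(utterances) < 1) stop("a corpus needs at least one utterance")
  lens <- vapply(utterances, function(u) length(u$wordform), integer(1))
  if (any(lens < 1)) stop("utterances must contain at least one token")
  tokens <- data.frame(
    utterance_id = rep(seq_along(utterances), lens),
    position = unlist(lapply(lens, seq_len)),
    wordform = tolower(unlist(lapply(utterances, function(u) as.character(u$wordform)))),
    fine_tag = unlist(lapply(utterances, function(u) as.character(u$fine_tag))),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(tokens$wordform))) stop("empty wordform")
  tokens$coarse_tag <- map_coarse_tag(tokens$fine_tag, mapping, strict)
  new_tagged_corpus(corpus_id, tokens)
}

#' Read a tagged-utterance corpus from a plain-text file
#'
#' Two dialects are supported:
#' \describe{
#'   \item{tsv}{one utterance per line, tokens as `word/tag` pairs separated by
#'     whitespace (a tab between word and tag is also accepted).}
#'   \item{vertical}{one `word<TAB>tag` pair per line, utterances separated by
#'     blank lines.}
#' }
#' Wordforms are lower-cased; utterance and token order is preserved from the
#' file. Chronological order of the source must therefore be the file order.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"vertical"`.
#' @param corpus_id identifier; defaults to the file name without extension.
#' @param mapping,strict forwarded to [map_coarse_tag()].
#' @return a `tagged_corpus`.
#' @export
read_tagged_corpus <- function(path, dialect = c("tsv", "vertical"),
                               corpus_id = NULL, mapping = NULL, strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(corpus_id)) corpus_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)

  split_pair <- function(tok, lineno) {
    # word/tag, allowing "/" inside the tag but not the word
    m <- regmatches(tok, regexpr("/", tok, fixed = TRUE))
    if (length(m) == 0)
      stop(sprintf("line %d: token '%s' carries no tag", lineno, tok))
    pos <- regexpr("/", tok, fixed = TRUE)
    word <- substr(tok, 1, pos - 1)
    tag <- substr(tok, pos + 1, nchar(tok))
    if (!nzchar(word) || !nzchar(tag))
      stop(sprintf("line %d: malformed token '%s'", lineno, tok))
    c(word, tag)
  }

  utterances <- list()
  if (dialect == "tsv") {
    keep <- which(nzchar(trimws(lines)))
    if (length(keep) == 0) stop("empty corpus: ", path)
    for (ln in keep) {
      toks <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
      pairs <- lapply(toks, split_pair, lineno = ln)
      utterances[[length(utterances) + 1L]] <- list(
        wordform = vapply(pairs, `[`, character(1), 1),
        fine_tag = vapply(pairs, `[`, character(1), 2)
      )
    }
  } else {
    cur_w <- character(0); cur_t <- character(0)
    flush <- function() {
      if (length(cur_w) > 0)
        utterances[[length(utterances) + 1L]] <<- list(wordform = cur_w, fine_tag = cur_t)
      cur_w <<- character(0); cur_t <<- character(0)
    }
    for (ln in seq_along(lines)) {
      line <- lines[ln]
      if (!nzchar(trimws(line))) { flush(); next }
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 2 || !nzchar(trimws(fields[2])))
        stop(sprintf("line %d: token '%s' carries no tag", ln, trimws(line)))
      cur_w <- c(cur_w, trimws(fields[1]))
      cur_t <- c(cur_t, trimws(fields[2]))
    }
    flush()
    if (length(utterances) == 0) stop("empty corpus: ", path)
  }
  tagged_corpus(corpus_id, utterances, mapping = mapping, strict = strict)
}

#' Write a tagged corpus to a plain-text file
#'
#' Inverse of [read_tagged_corpus()]; round-trips exactly.
#'
#' @param corpus a `tagged_corpus`.
#' @param path output path.
#' @param dialect `"tsv"` or `"vertical"`.
#' @return `path`, invisibly.
#' @export
write_tagged_corpus <- function(corpus, path, dialect = c("tsv", "vertical")) {
  dialect <- match.arg(dialect)
  tok <- corpus$tokens
  if (dialect == "tsv") {
    lines <- vapply(split(paste0(tok$wordform, "/", tok$fine_tag), tok$utterance_id),
                    paste, character(1), collapse = " ")
    lines <- lines[order(as.integer(names(lines)))]
  } else {
    per_utt <- split(paste0(tok$wordform, "\t", tok$fine_tag), tok$utterance_id)
    per_utt <- per_utt[order(as.integer(names(per_utt)))]
    lines <- unlist(lapply(per_utt, function(u) c(u, "")), use.names = FALSE)
    lines <- lines[-length(lines)]
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Assign homograph-distinct word keys
#'
#' Two tokens share a key iff they share both wordform and fine tag. A
#' wordform occurring with `m > 1` distinct fine tags in the corpus yields
#' keys `wordform-1 .. wordform-m`, numbered by first occurrence of each
#' (wordform, fine tag) pairing; unambiguous wordforms keep their plain form
#' as key.
#'
#' @param corpus a `tagged_corpus`.
#' @return the corpus with a `word_key` column added to `$tokens` and a
#'   `$word_table` data.frame (word_key, wordform, fine_tag, coarse_tag) in
#'   first-occurrence order.
#' @export
assign_word_keys <- function(corpus) {
  tok <- corpus$tokens
  pair <- paste(tok$wordform, tok$fine_tag, sep = "\r")
  first <- !duplicated(pair)
  tab <- data.frame(
    wordform = tok$wordform[first],
    fine_tag = tok$fine_tag[first],
    coarse_tag = tok$coarse_tag[first],
    stringsAsFactors = FALSE
  )
  n_tags <- table(tab$wordform)
  sense_idx <- stats::ave(seq_len(nrow(tab)), tab$wordform, FUN = seq_along)
  tab$word_key <- as.vector(ifelse(n_tags[tab$wordform] > 1,
                                   paste0(tab$wordform, "-", sense_idx),
                                   tab$wordform))
  key_of <- setNames(tab$word_key, paste(tab$wordform, tab$fine_tag, sep = "\r"))
  tok$word_key <- unname(key_of[pair])
  corpus$tokens <- tok
  corpus$word_table <- tab[, c("word_key", "wordform", "fine_tag", "coarse_tag")]
  corpus
}
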