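test_that("generation is deterministic and leaves the caller's RNG alone", {
  spec <- small_spec(seed = 17L)
  set.seed(999)
  before <- .Random.seed
  c1 <- generate_corpus(spec, 2)
  expect_identical(.Random.seed, before)
  c2 <- generate_corpus(spec, 2)
  expect_identical(c1, c2)
  # different corpus index, different text
  c3 <- generate_corpus(spec, 3)
  expect_false(identical(c1$tokens$wordform, c3$tokens$wordform))
  expect_error(synthetic_spec(selectivity = 0.1), "selectivity")
  expect_error(synthetic_spec(homograph_rate = 0.5), "homograph_rate")
})

test_that("every token matches the ground-truth tag map", {
  st <- generate_study(small_spec(seed = 23L))
  gt_key <- paste(st$ground_truth$wordform, st$ground_truth$fine_tag)
  expect_false(any(duplicated(gt_key))) # one coarse tag per (wordform, fine tag)
  gt_map <- stats::setNames(st$ground_truth$coarse_tag, gt_key)
  for (co in st$corpora) {
    tok_key <- paste(co$tokens$wordform, co$tokens$fine_tag)
    expect_true(all(tok_key %in% gt_key))
    expect_equal(unname(gt_map[tok_key]), co$tokens$coarse_tag)
  }
})

test_that("corpora share the core vocabulary; idiosyncratic words stay local", {
  st <- generate_study(small_spec(seed = 29L))
  vocab_by_corpus <- lapply(st$corpora, function(co)
    unique(paste(co$tokens$wordform, co$tokens$fine_tag)))
  in_all <- Reduce(intersect, vocab_by_corpus)
  expect_gt(length(in_all), 30) # a solid shared core survives sampling
  # idiosyncratic wordforms carry the corpus marker and never cross corpora
  idio <- grep("^c\\d\\dx", st$ground_truth$wordform, value = TRUE)
  expect_gt(length(idio), 0)
  expect_false(any(grepl("^c\\d\\dx", in_all)))
  for (i in seq_along(st$corpora)) {
    forms <- unique(st$corpora[[i]]$tokens$wordform)
    foreign <- grepl("^c\\d\\dx", forms) &
      !startsWith(forms, sprintf("c%02dx", i))
    expect_false(any(foreign))
  }
})

test_that("homographs appear with two fine tags at a positive rate", {
  spec <- small_spec(seed = 31L, homograph_rate = 0.1, n_utterances = 600L)
  st <- generate_study(spec)
  gt <- st$ground_truth
  n_tags <- table(gt$wordform)
  expect_gt(sum(n_tags > 1), 0)
  # a homograph wordform carries distinct fine tags with distinct coarse tags
  h <- names(n_tags)[n_tags > 1][1]
  senses <- gt[gt$wordform == h, ]
  expect_equal(nrow(senses), length(unique(senses$fine_tag)))
  # with the rate at zero there are none
  st0 <- generate_study(small_spec(seed = 31L, homograph_rate = 0))
  expect_true(all(table(st0$ground_truth$wordform) == 1))
})

test_that("token frequencies follow the target Zipf exponent", {
  # ~20k tokens; rank-frequency slope of the noun class fitted on top ranks
  spec <- synthetic_spec(n_corpora = 1, n_utterances = 4000, rng_seed = 21)
  co <- generate_corpus(spec, 1)
  expect_gt(nrow(co$tokens), 20000)
  nouns <- co$tokens[co$tokens$coarse_tag == "N", ]
  f <- sort(table(nouns$wordform), decreasing = TRUE)
  ranks <- seq_len(30)
  slope <- unname(coef(lm(log(as.numeric(f[ranks])) ~ log(ranks)))[2])
  expect_lt(abs(slope - (-spec$zipf_exponent)), 0.3)
})

test_that("degenerate selectivity yields tag-pure slots after each carrier", {
  spec <- small_spec(seed = 37L, selectivity = 1, n_utterances = 400L)
  co <- generate_corpus(spec, 1)
  tok <- co$tokens
  # reconstruct carrier -> next-token pairs within utterances
  nxt_same_utt <- c(tok$utterance_id[-1] == tok$utterance_id[-nrow(tok)], FALSE)
  carrier_pos <- which(tok$coarse_tag == "FUNCT" & nxt_same_utt)
  slots <- data.frame(carrier = tok$wordform[carrier_pos],
                      slot_tag = tok$coarse_tag[carrier_pos + 1])
  purity <- tapply(slots$slot_tag, slots$carrier,
                   function(x) length(unique(x)))
  expect_true(all(purity == 1))
})

test_that("raising selectivity raises the categorization hit rate", {
  hit_at <- function(selectivity, seed) {
    sp <- small_spec(seed = seed, selectivity = selectivity,
                     n_utterances = 300L, n_idiosyncratic = 0L)
    co <- assign_word_keys(generate_corpus(sp, 1))
    mat <- build_cooccurrence(co, slice_schedule(n_utterances(co))[7, ])
    mean(run_categorization(mat, categorizer_config("cosine", rng_seed = seed))$hit)
  }
  means <- vapply(c(0.4, 0.7, 1.0), function(s)
    mean(vapply(1:5, function(k) hit_at(s, 30L + k), numeric(1))), numeric(1))
  expect_lt(means[1], means[2])
  expect_lt(means[2], means[3])
})

test_that("formulaicity concentrates words in predictable private contexts", {
  profile_at <- function(formulaicity, seed) {
    sp <- synthetic_spec(n_corpora = 1, n_utterances = 600,
                         formulaicity = formulaicity, rng_seed = seed)
    co <- assign_word_keys(generate_corpus(sp, 1))
    mat <- build_cooccurrence(co, slice_schedule(n_utterances(co))[7, ])
    p <- compute_predictors(mat)
    p <- p[p$coarse_tag != "FUNCT" & p$frequency >= 3, ]
    c(acp = mean(p$avg_cond_prob), div_per_tok = mean(p$diversity / p$frequency))
  }
  lo <- profile_at(0, 9L)
  hi <- profile_at(0.8, 9L)
  expect_gt(hi[["acp"]], lo[["acp"]])
  expect_lt(hi[["div_per_tok"]], lo[["div_per_tok"]])
})

test_that("study specifications round-trip through YAML", {
  spec <- small_spec(seed = 41L, selectivity = 0.9)
  path <- tempfile(fileext = ".yaml")
  write_synthetic_spec(spec, path)
  back <- read_synthetic_spec(path)
  expect_equal(back, spec, tolerance = 1e-12)
  ref <- reference_spec()
  expect_equal(ref$n_corpora, 13L)
  expect_equal(ref$n_utterances, 3000L)
  expect_equal(reference_spec(rng_seed = 5)$rng_seed, 5L)
})

test_that("a study written to disk reads back into the pipeline", {
  st <- generate_study(small_spec(seed = 43L, n_utterances = 50L))
  dir <- tempfile()
  write_study(st, dir)
  files <- list.files(dir)
  expect_true("ground_truth.tsv" %in% files)
  expect_true("spec.yaml" %in% files)
  co <- read_tagged_corpus(file.path(dir, "synthetic-01.tsv"), "tsv",
                           corpus_id = st$corpora[[1]]$corpus_id)
  expect_equal(co$tokens, st$corpora[[1]]$tokens, ignore_attr = TRUE)
})
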