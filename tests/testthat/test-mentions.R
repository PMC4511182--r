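test_that("token features cover the window with boundary sentinels", {
  corp <- cached_corpus(4, 11)
  doc <- corp$docs[[1]]
  f <- extract_token_features(doc, corp$resources, mention_config(window = 1))
  expect_length(f, nrow(doc$tokens))
  # the title is a one- or two-token sentence: its first token has a left
  # sentinel
  expect_true(any(grepl("^w\\[-1\\]=<S>$", f[[1]])))
  # punctuation token: has_punct true, length 1
  dot <- which(doc$tokens$text == ".")[1]
  expect_true("pc[0]=TRUE" %in% f[[dot]])
  expect_true("ln[0]=1" %in% f[[dot]])
  # lexicon features fire on a genus token
  bac <- which(doc$tokens$start == doc$mentions$start[1])[1]
  expect_true("tx[0]=TRUE" %in% f[[bac]])
})

test_that("BIO encoding round-trips boundary-aligned gold mentions", {
  corp <- cached_corpus(6, 13)
  for (doc in corp$docs) {
    labels <- encode_bio(doc)
    men <- decode_bio(doc$tokens, labels, doc$text)
    outer <- bbrelex:::outermost_mentions(doc$mentions)
    outer <- outer[order(outer$start), ]
    expect_equal(men$start, outer$start)
    expect_equal(men$end, outer$end)
    expect_equal(men$etype, outer$etype)
  }
})

test_that("illegal BIO transitions are repaired at decode", {
  doc <- segment_document(bb_document("X", "one two three"))
  men <- decode_bio(doc$tokens, c("O", "I-Habitat", "I-Bacteria"), doc$text)
  expect_equal(men$etype, c("Habitat", "Bacteria"))
  expect_equal(men$text, c("two", "three"))
})

test_that("a one-document model recovers its own training mentions", {
  corp <- cached_corpus(4, 11)
  doc <- corp$docs[[1]]
  model <- suppressWarnings(
    train_mention_model(list(doc), corp$resources,
                        mention_config(min_count = 1)))
  pred <- predict_mentions(doc, model, corp$resources)
  outer <- bbrelex:::outermost_mentions(doc$mentions)
  key <- function(m) paste(m$etype, m$start, m$end)
  expect_true(all(key(outer) %in% key(pred)))
})

test_that("training is deterministic and fails without any mention", {
  corp <- cached_corpus(4, 11)
  docs <- corp$docs[1:2]
  m1 <- suppressWarnings(train_mention_model(docs, corp$resources))
  m2 <- suppressWarnings(train_mention_model(docs, corp$resources))
  expect_identical(m1$W, m2$W)
  p1 <- predict_mentions(corp$docs[[3]], m1, corp$resources)
  p2 <- predict_mentions(corp$docs[[3]], m2, corp$resources)
  expect_identical(p1, p2)

  blank <- segment_document(bb_document("B", "No annotations here."))
  expect_error(train_mention_model(list(blank)), "no training mention")
})

test_that("nested-mention lexicon is built from strictly nested gold spans", {
  corp <- cached_corpus(8, 17)
  nested <- build_nested_lexicon(corp$docs)
  inner_any <- do.call(rbind, lapply(corp$docs, function(d)
    bbrelex:::nested_inner_mentions(d$mentions)))
  if (!is.null(inner_any) && nrow(inner_any) > 0) {
    expect_true(all(tolower(inner_any$text) %in% nested$text))
  }
  # every lexicon entry really occurred strictly inside a larger mention
  for (r in seq_len(nrow(nested))) {
    hit <- FALSE
    for (d in corp$docs) {
      men <- d$mentions
      cand <- men[tolower(men$text) == nested$text[r] &
                    men$etype == nested$etype[r], ]
      for (i in seq_len(nrow(cand))) {
        if (any(men$start <= cand$start[i] & men$end >= cand$end[i] &
                  (men$start < cand$start[i] | men$end > cand$end[i])))
          hit <- TRUE
      }
    }
    expect_true(hit, info = nested$text[r])
  }
})

test_that("nested-mention injection adds occurrences without removing any", {
  text <- "Microbes live in the gut of cows and the gut of cows only."
  doc <- segment_document(bb_document("X", text))
  s1 <- locate_span(text, "gut of cows", 1)
  s2 <- locate_span(text, "only")
  base <- data.frame(id = "M1", etype = "Habitat",
                     start = s1[["start"]], end = s2[["end"]],
                     frag_spec = paste(s1[["start"]], s2[["end"]]),
                     text = substring(text, s1[["start"]] + 1, s2[["end"]]),
                     indirect = FALSE)
  nested <- data.frame(etype = "Habitat", text = "gut of cows")
  out <- bbrelex:::inject_nested(base, doc, nested)
  # both occurrences inside the long span are added
  expect_equal(sum(out$text == "gut of cows"), 2)
  expect_true(all(c(base$start) %in% out$start))
  expect_true(nrow(out) >= nrow(base))
})

test_that("the end-to-end detector finds typed mentions on held-out text", {
  corp <- cached_corpus(16, 21)
  sp <- corpus_split(corp$docs, 0.75)
  model <- suppressWarnings(train_mention_model(sp$train, corp$resources))
  pred_docs <- lapply(sp$eval, function(d) {
    d$mentions <- predict_mentions(d, model, corp$resources)
    d
  })
  sc <- score_mentions_chunk(sp$eval, pred_docs)
  expect_gt(sc$overall$f_measure, 0.6)
  # resource features help: a surface-only model should not do better
  base_model <- suppressWarnings(
    train_mention_model(sp$train, corp$resources,
                        mention_config(feature_sets = "base")))
  base_docs <- lapply(sp$eval, function(d) {
    d$mentions <- predict_mentions(d, base_model, corp$resources)
    d
  })
  sc_base <- score_mentions_chunk(sp$eval, base_docs)
  expect_gte(sc$overall$f_measure, sc_base$overall$f_measure)
})
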