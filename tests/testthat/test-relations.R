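mk_mentions <- function(etypes, sentences) {
  n <- length(etypes)
  data.frame(id = paste0("T", seq_len(n)), etype = etypes,
             start = seq_len(n) * 10L, end = seq_len(n) * 10L + 5L,
             frag_spec = paste(seq_len(n) * 10L, seq_len(n) * 10L + 5L),
             text = paste0("m", seq_len(n)), indirect = FALSE,
             sentence = as.integer(sentences), stringsAsFactors = FALSE)
}

# brute-force candidate oracle
cand_oracle <- function(men, s) {
  out <- 0L
  for (i in seq_len(nrow(men))) for (j in seq_len(nrow(men))) {
    if (i == j) next
    rt <- bbrelex:::signature_rtype(men$etype[i], men$etype[j])
    if (!is.na(rt) && abs(men$sentence[i] - men$sentence[j]) <= s)
      out <- out + 1L
  }
  out
}

test_that("candidate generation respects signatures and distance", {
  men <- mk_mentions(c("Bacteria", "Habitat"), c(1, 1))
  c0 <- generate_candidates(men, 0)
  expect_equal(nrow(c0), 1)
  expect_equal(c0$rtype, "Localization")
  expect_equal(c0$m1, "T1")

  expect_equal(nrow(generate_candidates(
    mk_mentions(c("Bacteria", "Bacteria"), c(1, 1)), 3)), 0)

  # Habitat pairs generate both orders; Geographical is never arg1
  men2 <- mk_mentions(c("Habitat", "Habitat", "Geographical"), c(1, 1, 2))
  c2 <- generate_candidates(men2, 0)
  expect_setequal(paste(c2$m1, c2$m2), c("T1 T2", "T2 T1"))

  men3 <- mk_mentions(c("Bacteria", "Habitat", "Habitat", "Habitat"),
                      c(1, 1, 2, 2))
  for (s in 0:2)
    expect_equal(nrow(generate_candidates(men3, s)), cand_oracle(men3, s))

  withr::local_seed(31)
  for (k in 1:20) {
    men <- mk_mentions(sample(c("Bacteria", "Habitat", "Geographical"), 8,
                              replace = TRUE),
                       sample(1:4, 8, replace = TRUE))
    for (s in c(0, 2, 5))
      expect_equal(nrow(generate_candidates(men, s)), cand_oracle(men, s))
  }
})

test_that("candidate sets are monotone in the distance threshold", {
  withr::local_seed(17)
  men <- mk_mentions(sample(c("Bacteria", "Habitat", "Geographical"), 10,
                            replace = TRUE), sample(1:5, 10, replace = TRUE))
  prev <- 0L
  for (s in 0:5) {
    cur <- nrow(generate_candidates(men, s))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("labels propagate through equivalence classes exactly as set expansion", {
  doc <- fig_abbrev_doc()
  chains <- resolve_coreference(doc, config = coref_config(strategies = "similarity"))$chains
  cands <- generate_candidates(assign_sentences(doc, doc$mentions), 99)
  lab <- label_candidates(cands, doc, chains)
  # the abbreviated mention inherits the relation of its full-name variant
  expect_true(lab$positive[lab$m1 == "T3" & lab$m2 == "T4"])
  expect_true(all(lab$positive[lab$m1 == "T1" & lab$m2 %in% c("T4", "T5", "T6")]))

  # without chains, positives are exactly the gold pairs
  lab0 <- label_candidates(cands, doc, list())
  expect_setequal(paste(lab0$m1, lab0$m2)[lab0$positive],
                  c("T1 T4", "T1 T5", "T1 T6"))

  # oracle: explicit expansion of gold pairs by the equivalence classes
  cls <- bbrelex:::equivalence_classes(doc$mentions$id, chains)
  expand <- outer(doc$mentions$id, doc$mentions$id, function(a, b) {
    vapply(seq_along(a), function(k) {
      any(cls[doc$relations$arg1] == cls[a[k]] &
            cls[doc$relations$arg2] == cls[b[k]])
    }, logical(1))
  })
  dimnames(expand) <- list(doc$mentions$id, doc$mentions$id)
  for (k in seq_len(nrow(lab)))
    expect_equal(lab$positive[k], expand[lab$m1[k], lab$m2[k]],
                 info = paste(lab$m1[k], lab$m2[k]))
})

test_that("gold relations violating the signatures are ignored with a warning", {
  doc <- fig_abbrev_doc()
  doc$relations <- rbind(doc$relations, data.frame(
    id = "R9", rtype = "Localization", arg1 = "T4", arg2 = "T5"))
  cands <- generate_candidates(assign_sentences(doc, doc$mentions), 99)
  expect_warning(lab <- label_candidates(cands, doc, list()), "violating")
  expect_false(any(lab$positive[lab$rtype == "PartOf"]))
})

test_that("negative sampling is balanced, exhaustive-capped and seeded", {
  lab <- data.frame(m1 = paste0("a", 1:110), m2 = "b", rtype = "Localization",
                    dist = 0L, positive = c(rep(TRUE, 10), rep(FALSE, 100)))
  es <- sample_negatives(lab, seed = 3)
  expect_equal(nrow(es$negatives), 10)
  expect_equal(nrow(es$positives), 10)
  es2 <- sample_negatives(lab, seed = 3)
  expect_identical(es$negatives$m1, es2$negatives$m1)
  es3 <- sample_negatives(lab, seed = 4)
  expect_false(identical(es$negatives$m1, es3$negatives$m1))

  few <- lab[c(1:10, 11:14), ]
  expect_equal(nrow(sample_negatives(few, 1)$negatives), 4)
  none <- lab[11:20, ]
  expect_error(sample_negatives(none, 1), "no positive")
})

test_that("relation features reflect configuration", {
  doc <- fig_abbrev_doc()
  men <- assign_sentences(doc, doc$mentions)
  cands <- generate_candidates(men, 99)
  row <- cands[cands$m1 == "T1" & cands$m2 == "T4", ]
  f1 <- extract_relation_features(row, doc, men, NULL,
                                  relation_config(context_size = 0))[[1]]
  expect_false(any(grepl("^m[12][lr]", f1)))        # no context features
  expect_true("tt=Bacteria_Habitat" %in% f1)
  expect_true("m1bag=campylobacter" %in% f1)
  f2 <- extract_relation_features(row, doc, men, NULL,
                                  relation_config(context_size = 1))[[1]]
  expect_true(any(grepl("^m2l1w=", f2)))
  expect_true(all(f1 %in% f2))

  geo <- mk_doc("Borrelia afzelii occurs in Europe.",
                mspec = list(list(text = "Borrelia afzelii", etype = "Bacteria"),
                             list(text = "Europe", etype = "Geographical")))
  gmen <- assign_sentences(geo, geo$mentions)
  gc <- generate_candidates(gmen, 0)
  gf <- extract_relation_features(gc, geo, gmen, NULL, relation_config())[[1]]
  expect_true("tt=Bacteria_Geographical" %in% gf)
  expect_true("db=0" %in% gf)
})

test_that("the relation classifier separates a separable fixture and is deterministic", {
  withr::local_seed(8)
  n <- 60
  feats <- lapply(seq_len(n), function(i) {
    if (i <= n / 2) c("tt=Bacteria_Habitat", "db=0", paste0("m2bag=h", i %% 7))
    else c("tt=Bacteria_Habitat", "db=3", paste0("m2bag=h", i %% 7))
  })
  ex <- list(features = feats, label = rep(c(TRUE, FALSE), each = n / 2))
  m1 <- train_relation_model(ex, relation_config())
  m2 <- train_relation_model(ex, relation_config())
  expect_identical(m1$w, m2$w)
  p <- bbrelex:::predict_relation_prob(m1, feats)
  expect_equal(p > 0.5, ex$label)

  expect_error(train_relation_model(
    list(features = feats[1:5], label = rep(TRUE, 5)), relation_config()),
    "degenerate")
})

test_that("predicted relations replace indirect arguments by chain representatives", {
  doc <- fig_anaphora_doc()
  res <- resolve_coreference(doc)
  # train on the abbreviation fixture corpus so the model is non-trivial
  corp <- cached_corpus(8, 17)
  sp <- corpus_split(corp$docs, 0.75)
  trained <- train_relation_pipeline(sp$train, corp$resources, "all")
  rel <- predict_relations(doc, res$mentions, res$chains, trained$model,
                           corp$resources)
  expect_true(all(rel$arg1 %in% doc$mentions$id))      # no indirect ids
  expect_true(all(bbrelex:::signature_rtype(
    doc$mentions$etype[match(rel$arg1, doc$mentions$id)],
    doc$mentions$etype[match(rel$arg2, doc$mentions$id)]) == rel$rtype))
  expect_false(anyDuplicated(paste(rel$rtype, rel$arg1, rel$arg2)) > 0)
})
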