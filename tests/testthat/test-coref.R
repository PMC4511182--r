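test_that("edit distance handles identity, deletions and transpositions", {
  expect_equal(damerau_levenshtein("coli", "coli"), 0)
  expect_equal(damerau_levenshtein("cloi", "coli"), 1)
  expect_equal(damerau_levenshtein("abc", ""), 3)
  expect_equal(damerau_levenshtein("", "ab"), 2)
  expect_equal(damerau_levenshtein("soils", "soil"), 1)
})

test_that("edit distance agrees with the brute-force oracle", {
  withr::local_seed(99)
  for (k in 1:200) {
    a <- rand_string(8); b <- rand_string(8)
    expect_equal(damerau_levenshtein(a, b), dl_oracle(a, b),
                 info = paste(a, "~", b))
  }
})

test_that("conventional abbreviations of bacterium names are recognized", {
  expect_true(abbreviation_match("Bacillus subtilis", "B. subtilis"))
  expect_true(abbreviation_match("Campylobacter coli", "C. coli"))
  expect_true(abbreviation_match("C. coli", "Campylobacter coli"))
  expect_false(abbreviation_match("C. coli", "C. jejuni"))
  expect_false(abbreviation_match("Bacillus", "Bacillus subtilis"))
  expect_true(abbreviation_match("Bacillus subtilis subsp. niger",
                                 "Bacillus subtilis"))
  expect_true(abbreviation_match("B. subtilis", "b. Subtilis"))
})

test_that("strain designators match across name variants", {
  expect_true(strain_match("Borrelia afzelii PKo", "Borrelia afzelii"))
  expect_true(strain_match("Bradyrhizobium japonicum strain USDA110",
                           "Bradyrhizobium japonicum"))
  expect_false(strain_match("strain USDA110", "strain DSMZ 266"))
  expect_true(strain_match("strain USDA110",
                           "Bradyrhizobium japonicum strain USDA110"))
  expect_false(strain_match("Borrelia afzelii", "Borrelia garinii PKo"))
  expect_true(strain_match("B. japonicum USDA110",
                           "Bradyrhizobium japonicum USDA110"))
})

test_that("taxonomic levels follow the strain < ... < family cline", {
  expect_equal(hierarchical_level("Bradyrhizobium japonicum strain USDA110"),
               "strain")
  expect_equal(hierarchical_level("Borrelia afzelii PKo"), "strain")
  expect_equal(hierarchical_level("Bacillus subtilis subsp. niger"),
               "subspecies")
  expect_equal(hierarchical_level("Bacillus subtilis"), "species")
  expect_equal(hierarchical_level("B. subtilis"), "species")
  expect_equal(hierarchical_level("Bifidobacterium"), "genus")
  expect_equal(hierarchical_level("Enterobacteriaceae"), "family")
  expect_equal(hierarchical_level("Rhizobiales"), "higher")
  expect_equal(hierarchical_level("7 percent"), "unknown")
})

test_that("generic bacteria expressions are detected and blocked", {
  expect_true(is_generic_bacteria_mention("bacteria"))
  expect_true(is_generic_bacteria_mention("bacterial bacteria"))
  expect_false(is_generic_bacteria_mention("Borrelia"))
  expect_false(is_generic_bacteria_mention("soil bacteria"))

  men <- mk_doc("bacteria occur. bacteria remain.",
                mspec = list(list(text = "bacteria", etype = "Bacteria"),
                             list(text = "bacteria", etype = "Bacteria", occ = 2)))$mentions
  expect_equal(nrow(similarity_pass(men, coref_config())), 0)
  unblocked <- coref_config(block_generic_bacteria = FALSE)
  expect_equal(nrow(similarity_pass(men, unblocked)), 1)
})

test_that("similarity pass links anterior same-type mentions only", {
  doc <- fig_abbrev_doc()
  links <- similarity_pass(doc$mentions, coref_config())
  key <- paste(links$anaphor, links$antecedent)
  expect_true("T2 T1" %in% key)   # identical full names
  expect_true("T3 T1" %in% key)   # abbreviation to full name
  expect_true("T3 T2" %in% key)
  expect_false(any(links$anaphor == "T4"))  # habitats unrelated in form

  men <- mk_doc("Found in soil. Found in soils.",
                mspec = list(list(text = "soil", etype = "Habitat"),
                             list(text = "soils", etype = "Habitat")))$mentions
  expect_equal(nrow(similarity_pass(men, coref_config())), 1)
  expect_equal(nrow(similarity_pass(men, coref_config(max_edit_distance = 0))), 0)

  # same surface but different types never link
  men2 <- mk_doc("Europe. Europe.",
                 mspec = list(list(text = "Europe", etype = "Geographical"),
                              list(text = "Europe", etype = "Habitat", occ = 2)))$mentions
  expect_equal(nrow(similarity_pass(men2, coref_config())), 0)
})

test_that("hierarchy constraint only removes links and is off by default", {
  men <- mk_doc("Bifidobacterium grows. Bifidobacterium longum grows. Bifidobacterium lives.",
                mspec = list(list(text = "Bifidobacterium", etype = "Bacteria"),
                             list(text = "Bifidobacterium longum", etype = "Bacteria"),
                             list(text = "Bifidobacterium", etype = "Bacteria", occ = 3)))$mentions
  base <- similarity_pass(men, coref_config())
  strict <- similarity_pass(men, coref_config(hierarchy_constraint_enabled = TRUE,
                                              max_hierarchy_distance = 0))
  expect_true(nrow(strict) <= nrow(base))
  expect_true(all(paste(strict$anaphor, strict$antecedent) %in%
                    paste(base$anaphor, base$antecedent)))
})

test_that("sentence-initial definite descriptions resolve by centering and recentness", {
  doc <- fig_anaphora_doc()
  ana <- anaphora_pass(doc)
  expect_equal(nrow(ana$mentions), 1)
  expect_equal(ana$mentions$text, "The organism")
  expect_true(ana$mentions$indirect)
  expect_equal(ana$mentions$etype, "Bacteria")
  # the focus is the paragraph-initial mention of the title bacterium
  ante <- doc$mentions$text[match(ana$links$antecedent, doc$mentions$id)]
  expect_equal(ante, "Yersinia pestis")

  # "This strain" selects the most recent bacterium, not the focus
  text <- paste0("Alphabacter primus\n\n",
                 "Alphabacter primus was described first. ",
                 "Betabacter secundus was described later. ",
                 "This strain grows quickly.")
  doc2 <- mk_doc(text, mspec = list(
    list(text = "Alphabacter primus", etype = "Bacteria"),
    list(text = "Alphabacter primus", etype = "Bacteria", occ = 2),
    list(text = "Betabacter secundus", etype = "Bacteria")))
  ana2 <- anaphora_pass(doc2)
  expect_equal(ana2$links$antecedent, "T3")
  expect_equal(ana2$mentions$text, "This strain")

  # no bacterium mention at all: no indirect mentions, no links
  doc3 <- mk_doc("Soil\n\nThe organism is unknown.",
                 mspec = list(list(text = "Soil", etype = "Habitat")))
  ana3 <- anaphora_pass(doc3)
  expect_equal(nrow(ana3$mentions), 0)

  # non-sentence-initial descriptions are ignored
  doc4 <- mk_doc(paste0("Gammabacter tertius\n\n",
                        "Gammabacter tertius grows. ",
                        "Colonies of the organism are pale."),
                 mspec = list(
                   list(text = "Gammabacter tertius", etype = "Bacteria"),
                   list(text = "Gammabacter tertius", etype = "Bacteria", occ = 2)))
  expect_equal(nrow(anaphora_pass(doc4)$mentions), 0)
})

test_that("transitive closure equals graph components and partitions members", {
  links <- data.frame(anaphor = c("A", "B"), antecedent = c("B", "C"),
                      source = "similarity")
  men <- data.frame(id = c("A", "B", "C"), etype = "Bacteria",
                    start = 1:3, end = 2:4, frag_spec = "x", text = "x",
                    indirect = FALSE)
  ch <- build_chains(links, men)
  expect_length(ch, 1)
  expect_setequal(ch[[1]]$members, c("A", "B", "C"))
  expect_equal(ch[[1]]$representative, "A")

  expect_length(build_chains(links[0, ], men), 0)

  withr::local_seed(5)
  for (k in 1:10) {
    n <- sample(4:12, 1)
    ids <- paste0("M", seq_len(n))
    nl <- sample(1:8, 1)
    links <- data.frame(anaphor = sample(ids, nl, replace = TRUE),
                        antecedent = sample(ids, nl, replace = TRUE),
                        source = "similarity")
    links <- links[links$anaphor != links$antecedent, , drop = FALSE]
    men <- data.frame(id = ids, etype = "Bacteria", start = seq_len(n),
                      end = seq_len(n) + 1, frag_spec = "x", text = "x",
                      indirect = FALSE)
    ch <- build_chains(links, men)
    g <- igraph::graph_from_data_frame(links[, 1:2], directed = FALSE,
                                       vertices = ids)
    comp <- igraph::components(g)
    expected <- unname(split(ids, comp$membership))
    expected <- expected[lengths(expected) >= 2]
    got <- lapply(ch, `[[`, "members")
    expect_equal(length(got), length(expected))
    for (e in expected)
      expect_true(any(vapply(got, setequal, logical(1), e)))
    # chains partition their members
    expect_false(anyDuplicated(unlist(got)) > 0)
  }
})

test_that("chains of only indirect mentions are dropped with a warning", {
  men <- data.frame(id = c("A1", "A2"), etype = "Bacteria", start = 1:2,
                    end = 3:4, frag_spec = "x", text = "x", indirect = TRUE)
  links <- data.frame(anaphor = "A1", antecedent = "A2", source = "anaphora")
  expect_warning(ch <- build_chains(links, men), "only indirect")
  expect_length(ch, 0)
})

test_that("resolved chains never mix entity types and are a closure fixpoint", {
  corp <- cached_corpus(6, 13)
  for (doc in corp$docs) {
    res <- resolve_coreference(doc)
    types <- stats::setNames(res$mentions$etype, res$mentions$id)
    for (ch in res$chains) {
      expect_length(unique(types[ch$members]), 1)
      expect_false(res$mentions$indirect[match(ch$representative, res$mentions$id)])
    }
    # closure is a fixpoint: chain-induced links re-close to the same chains
    induced <- do.call(rbind, lapply(res$chains, function(ch)
      data.frame(anaphor = ch$members[-1], antecedent = ch$members[1],
                 source = "similarity")))
    if (!is.null(induced)) {
      ch2 <- build_chains(induced, res$mentions)
      canon <- function(chs) sort(vapply(chs, function(c)
        paste(sort(c$members), collapse = ","), character(1)))
      expect_equal(canon(ch2), canon(res$chains))
    }
  }
})
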