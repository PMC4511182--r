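test_that("standoff files parse into mentions, relations and Equiv groups", {
  dir <- withr::local_tempdir()
  text <- "Borrelia afzelii lives in a skin lesion from a patient in Europe."
  writeLines(text, file.path(dir, "D1.txt"))
  writeLines(c(
    "T1\tBacteria 0 16\tBorrelia afzelii",
    "T2\tHabitat 28 64\tskin lesion from a patient in Europe",
    "T3\tGeographical 58 64\tEurope"),
    file.path(dir, "D1.a1"))
  writeLines(c(
    "R1\tLocalization Bacterium:T1 Localization:T2",
    "R2\tLocalization Bacterium:T1 Localization:T3",
    "*\tEquiv T1 T2"),
    file.path(dir, "D1.a2"))
  doc <- read_document(file.path(dir, "D1.txt"),
                       file.path(dir, paste0("D1.", c("a1", "a2"))))
  expect_equal(nrow(doc$mentions), 3)
  expect_equal(doc$mentions$etype, c("Bacteria", "Habitat", "Geographical"))
  expect_equal(doc$mentions$text[1], "Borrelia afzelii")
  expect_equal(doc$relations$rtype, c("Localization", "Localization"))
  expect_equal(doc$equiv_groups, list(c("T1", "T2")))
})

test_that("discontinuous mentions, unknown lines and malformed offsets", {
  dir <- withr::local_tempdir()
  writeLines("abcdefghij klmnopqrst uvwxyz", file.path(dir, "D2.txt"))
  writeLines(c("T1\tHabitat 0 4;11 15\tabcd klmn",
               "E1\tProcess:T1",
               "T2\tBacteria 22 26\tuvwx"),
             file.path(dir, "D2.a1"))
  expect_warning(
    doc <- read_document(file.path(dir, "D2.txt"), file.path(dir, "D2.a1")),
    "unsupported annotation line")
  expect_equal(nrow(doc$mentions), 2)
  expect_equal(doc$mentions$frag_spec[1], "0 4;11 15")
  expect_equal(doc$mentions$start[1], 0)
  expect_equal(doc$mentions$end[1], 4)

  writeLines("T1\tHabitat 0 400\tabc", file.path(dir, "D2.a1"))
  expect_error(read_document(file.path(dir, "D2.txt"), file.path(dir, "D2.a1")),
               "out of bounds")
  writeLines("T1\tHabitat zero four\tabc", file.path(dir, "D2.a1"))
  expect_error(read_document(file.path(dir, "D2.txt"), file.path(dir, "D2.a1")),
               "malformed offsets")
})

test_that("empty annotation files give an empty document", {
  dir <- withr::local_tempdir()
  writeLines("Some text.", file.path(dir, "D3.txt"))
  file.create(file.path(dir, "D3.a1"))
  doc <- read_document(file.path(dir, "D3.txt"), file.path(dir, "D3.a1"))
  expect_equal(nrow(doc$mentions), 0)
})

test_that("segmentation protects abbreviation initials and counts structure", {
  d1 <- segment_document(bb_document("S1", "B. subtilis is a bacterium."))
  expect_equal(nrow(d1$sentences), 1)

  d2 <- segment_document(bb_document("S2", ""))
  expect_equal(nrow(d2$sentences), 0)

  d3 <- segment_document(bb_document("S3", "Title\n\nBody one. Body two."))
  expect_equal(nrow(d3$paragraphs), 2)
  expect_equal(nrow(d3$sentences), 3)
  expect_true(d3$paragraphs$is_title[1])
  expect_false(any(d3$paragraphs$is_title[-1]))

  d4 <- segment_document(bb_document("S4", "Bacillus subtilis subsp. niger grows. It lives."))
  expect_equal(nrow(d4$sentences), 2)
})

test_that("token spans tile sentences and carry POS tags", {
  corp <- cached_corpus(4, 11)
  for (doc in corp$docs) {
    tok <- doc$tokens
    expect_true(all(tok$pos != ""))
    for (si in doc$sentences$index) {
      tt <- tok[tok$sentence_index == si, ]
      expect_equal(tt$start[1], doc$sentences$start[si])
      expect_equal(tt$end[nrow(tt)], doc$sentences$end[si])
      if (nrow(tt) > 1) {
        gaps <- substring(doc$text, tt$end[-nrow(tt)] + 1, tt$start[-1])
        expect_true(all(grepl("^\\s*$", gaps)))   # only whitespace between
        expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
      }
    }
    expect_equal(tok$text, bbrelex:::span_text(doc$text, tok$start, tok$end))
  }
})

test_that("mention sentence assignment follows the first fragment", {
  doc <- fig_abbrev_doc()
  men <- doc$mentions
  expect_equal(men$sentence[men$text == "C. coli"],
               nrow(doc$sentences))
  expect_equal(men$sentence[1], 1)
})

test_that("write + read round-trips annotation content", {
  dir <- withr::local_tempdir()
  doc <- fig_abbrev_doc()
  write_annotations(doc, dir, write_text = TRUE)
  back <- read_document(file.path(dir, "FIG-ABBREV.txt"),
                        file.path(dir, paste0("FIG-ABBREV.", c("a1", "a2"))))
  expect_equal(back$mentions$frag_spec, doc$mentions$frag_spec)
  expect_equal(back$mentions$etype, doc$mentions$etype)
  expect_equal(back$mentions$text, doc$mentions$text)
  expect_equal(back$relations$rtype, doc$relations$rtype)
  expect_equal(length(back$equiv_groups), 1)
  expect_equal(back$text, doc$text)
})

test_that("indirect mentions are never serialized and break relations", {
  doc <- fig_anaphora_doc()
  ana <- anaphora_pass(doc)
  doc$mentions <- rbind(doc$mentions, ana$mentions)
  dir <- withr::local_tempdir()
  write_annotations(doc, dir)
  a1 <- readLines(file.path(dir, "FIG-ANA.a1"))
  expect_length(a1, 4)                      # the indirect mention is absent
  expect_false(any(grepl("The organism", a1)))

  bad <- doc
  bad$relations <- rbind(bad$relations, data.frame(
    id = "R9", rtype = "Localization", arg1 = ana$mentions$id[1], arg2 = "T3"))
  expect_error(write_annotations(bad, dir), "missing or indirect")
})
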