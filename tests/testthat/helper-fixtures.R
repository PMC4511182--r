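# Shared fixture builders: documents are constructed programmatically by
# locating surface strings in a text, so offsets never have to be
# hand-counted.

locate_span <- function(text, surface, occurrence = 1L) {
  hits <- gregexpr(surface, text, fixed = TRUE)[[1]]
  stopifnot(hits[1] != -1, length(hits) >= occurrence)
  start <- hits[occurrence] - 1L
  c(start = start, end = start + nchar(surface))
}

# mspec: list of list(text =, etype =, occ = 1); relations reference mention
# list positions; equiv references mention list positions.
mk_doc <- function(text, mspec = list(), relations = list(), equiv = list(),
                   doc_id = "FIX-1", segment = TRUE) {
  men <- bbrelex:::empty_mentions()
  for (i in seq_along(mspec)) {
    m <- mspec[[i]]
    sp <- locate_span(text, m$text, m$occ %||% 1L)
    men <- rbind(men, data.frame(
      id = paste0("T", i), etype = m$etype, start = sp[["start"]],
      end = sp[["end"]], frag_spec = paste(sp[["start"]], sp[["end"]]),
      text = m$text, indirect = FALSE, stringsAsFactors = FALSE))
  }
  rel <- bbrelex:::empty_relations()
  for (i in seq_along(relations)) {
    r <- relations[[i]]
    rel <- rbind(rel, data.frame(id = paste0("R", i), rtype = r$rtype,
                                 arg1 = paste0("T", r$a1),
                                 arg2 = paste0("T", r$a2),
                                 stringsAsFactors = FALSE))
  }
  doc <- bb_document(doc_id, text, mentions = men, relations = rel,
                     equiv_groups = lapply(equiv, function(g) paste0("T", g)))
  if (segment) doc <- segment_document(doc)
  doc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small annotated document in the shape of the worked corpus excerpt with
# a co-referring abbreviation (full name in the title and opening, C. coli
# variant carrying the habitat relations later on).
fig_abbrev_doc <- function() {
  text <- paste0(
    "Campylobacter coli\n\n",
    "Campylobacter coli was described a long time ago. ",
    "Cultures grow slowly in the laboratory. ",
    "Colonies appear pale on standard media. ",
    "Growth requires careful handling.\n\n",
    "C. coli is found in pigs and birds and surface water.")
  mk_doc(text,
         mspec = list(
           list(text = "Campylobacter coli", etype = "Bacteria"),
           list(text = "Campylobacter coli", etype = "Bacteria", occ = 2),
           list(text = "C. coli", etype = "Bacteria"),
           list(text = "pigs", etype = "Habitat"),
           list(text = "birds", etype = "Habitat"),
           list(text = "surface water", etype = "Habitat")),
         relations = list(
           list(rtype = "Localization", a1 = 1, a2 = 4),
           list(rtype = "Localization", a1 = 1, a2 = 5),
           list(rtype = "Localization", a1 = 1, a2 = 6)),
         equiv = list(c(1, 2, 3)),
         doc_id = "FIG-ABBREV")
}

# A document exercising definite-description anaphora: sentence-initial
# "The organism" must resolve to the focus bacterium of the document.
fig_anaphora_doc <- function() {
  text <- paste0(
    "Yersinia pestis\n\n",
    "Yersinia pestis causes serious infection. ",
    "The organism is found in rats and humans.")
  mk_doc(text,
         mspec = list(
           list(text = "Yersinia pestis", etype = "Bacteria"),
           list(text = "Yersinia pestis", etype = "Bacteria", occ = 2),
           list(text = "rats", etype = "Habitat"),
           list(text = "humans", etype = "Habitat")),
         relations = list(
           list(rtype = "Localization", a1 = 1, a2 = 3),
           list(rtype = "Localization", a1 = 1, a2 = 4)),
         equiv = list(c(1, 2)),
         doc_id = "FIG-ANA")
}

# Independent brute-force Damerau-Levenshtein (optimal string alignment)
# oracle: plain recursion with memoization, structured differently from the
# package's matrix DP.
dl_oracle <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    ca <- substr(a, i, i); cb <- substr(b, j, j)
    best <- min(rec(i - 1, j) + 1, rec(i, j - 1) + 1,
                rec(i - 1, j - 1) + (ca != cb))
    if (i > 1 && j > 1 && ca == substr(b, j - 1, j - 1) &&
        cb == substr(a, i - 1, i - 1))
      best <- min(best, rec(i - 2, j - 2) + 1)
    memo[[key]] <- best
    best
  }
  rec(nchar(a), nchar(b))
}

rand_string <- function(maxlen, alphabet = c("a", "b", "c", "o", "l", "i")) {
  n <- sample(0:maxlen, 1)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Session-wide cache of generated corpora (generation is deterministic, so
# sharing across test files is safe).
.fixture_cache <- new.env(parent = emptyenv())
cached_corpus <- function(n_docs, seed, key = paste0("c", n_docs, "_", seed)) {
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("bbx_", key))
    generate_corpus(synth_config(n_docs = n_docs, seed = seed), dir)
    .fixture_cache[[key]] <- c(read_corpus(dir), list(dir = dir))
  }
  .fixture_cache[[key]]
}

# Brute-force CEAF: maximum total similarity over all injective alignments.
ceaf_brute <- function(phi) {
  n <- nrow(phi); m <- ncol(phi)
  if (n == 0 || m == 0) return(0)
  if (n > m) return(ceaf_brute(t(phi)))
  best <- 0
  for (p in combinat_perms(m)) {
    tot <- sum(phi[cbind(seq_len(n), p[seq_len(n)])])
    best <- max(best, tot)
  }
  best
}

combinat_perms <- function(m) {
  if (m == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(m - 1)) {
    for (k in seq_len(m)) out <- c(out, list(append(p, m, after = k - 1)))
  }
  out
}
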