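## Paragraph / sentence / token segmentation with pluggable POS tagging.
##
## The first line of every document is its title (a bacterium name alone on
## the line), so the first paragraph is flagged `is_title`. The sentence
## splitter protects single-capital initials ("B. subtilis") and a small
## abbreviation list; bacterial abbreviations would otherwise shatter
## sentences and corrupt the sentence distance used by relation detection.

SENT_ABBREVS <- c("sp", "spp", "subsp", "str", "cf", "var", "e.g", "i.e", "al")

#' Rule-based Penn-Treebank-style POS tagger
#'
#' A small deterministic heuristic tagger satisfying the pluggable tagger
#' contract of [segment_document()]: closed-class lookup, digit/punctuation
#' detection, capitalization for proper nouns, suffix heuristics, `NN`
#' otherwise. Any function mapping a character vector of token surfaces to a
#' same-length vector of tags may be used instead.
#'
#' @param words Character vector of token surfaces.
#' @return Character vector of tags.
#' @export
bb_pos_tagger <- function(words) {
  dets <- c("the", "a", "an", "this", "these", "that", "those", "its", "their")
  preps <- c("in", "of", "from", "on", "at", "by", "with", "to", "for",
             "near", "within", "without", "throughout", "across", "beyond",
             "toward", "alongside", "as", "into", "during")
  conj <- c("and", "or", "but", "nor")
  verbs_z <- c("is", "has", "occurs", "forms", "grows", "prefers", "inhabits",
               "colonizes", "causes", "remains", "thrives", "lives", "appears",
               "represents", "belongs")
  verbs_other <- c("are", "was", "were", "have", "been", "be", "found",
                   "isolated", "described", "reported", "identified",
                   "studied", "observed", "collected", "detected", "obtained",
                   "recovered", "cultured", "maintained", "named")
  lw <- tolower(words)
  tags <- rep("NN", length(words))
  tags[lw %in% dets] <- "DT"
  tags[lw %in% preps] <- "IN"
  tags[lw %in% conj] <- "CC"
  tags[lw %in% verbs_z] <- "VBZ"
  tags[lw %in% verbs_other] <- "VBN"
  tags[grepl("^[0-9]+$", words)] <- "CD"
  tags[grepl("[0-9]", words) & grepl("[A-Za-z]", words)] <- "NNP"
  cap <- grepl("^[A-Z]", words) & tags == "NN"
  tags[cap] <- "NNP"
  adj <- grepl("(ous|ic|ive|al|ary|like)$", lw) & tags == "NN"
  tags[adj] <- "JJ"
  tags[grepl("^[^A-Za-z0-9]+$", words)] <- words[grepl("^[^A-Za-z0-9]+$", words)]
  tags
}

# Sentence boundary candidates inside one paragraph string; returns 1-based
# positions (within the paragraph) of terminal punctuation that ends a
# sentence.
sentence_breaks <- function(pt) {
  hits <- gregexpr("[.!?]", pt)[[1]]
  if (hits[1] == -1) return(integer())
  n <- nchar(pt)
  keep <- logical(length(hits))
  for (k in seq_along(hits)) {
    i <- hits[k]
    ch <- substr(pt, i, i)
    nxt <- if (i < n) substr(pt, i + 1, i + 1) else ""
    if (!(nxt == "" || grepl("\\s", nxt))) next
    if (ch == ".") {
      before <- substr(pt, 1, i - 1)
      prev <- regmatches(before, regexpr("[A-Za-z0-9.]*$", before))
      prev <- sub("\\.$", "", prev)
      if (grepl("^[A-Z]$", prev)) next            # single-capital initial
      if (tolower(prev) %in% SENT_ABBREVS) next   # sp., subsp., e.g., ...
    }
    keep[k] <- TRUE
  }
  hits[keep]
}

#' Segment a document into paragraphs, sentences and tokens
#'
#' Paragraphs are maximal runs of non-newline text (so both blank lines and
#' single newlines separate paragraphs, and the title line is its own
#' paragraph). Sentences are split on terminal punctuation with guards for
#' single-capital initials and common abbreviations. Tokens are maximal
#' alphanumeric runs or single punctuation marks.
#'
#' @param doc A [bb_document()].
#' @param tagger A function mapping a character vector of token surfaces to
#'   POS tags; defaults to [bb_pos_tagger]. Use `function(w) rep("UNK",
#'   length(w))` for an identity tagger.
#' @return The document with `paragraphs`, `sentences` and `tokens` data
#'   frames filled in (0-based end-exclusive spans), and a `sentence` column
#'   added to `mentions` (index of the sentence containing the first
#'   fragment's start).
#' @export
segment_document <- function(doc, tagger = bb_pos_tagger) {
  text <- doc$text
  paras <- gregexpr("[^\n]+", text)[[1]]
  if (paras[1] == -1) {
    doc$paragraphs <- data.frame(index = integer(), start = integer(),
                                 end = integer(), is_title = logical())
    doc$sentences <- data.frame(index = integer(), start = integer(),
                                end = integer(), paragraph_index = integer())
    doc$tokens <- data.frame(text = character(), start = integer(),
                             end = integer(), sentence_index = integer(),
                             pos = character(), stringsAsFactors = FALSE)
    if (nrow(doc$mentions) > 0) doc$mentions$sentence <- NA_integer_
    return(doc)
  }
  p_start <- as.integer(paras) - 1L            # 0-based
  p_end <- p_start + attr(paras, "match.length")
  doc$paragraphs <- data.frame(index = seq_along(p_start),
                               start = p_start, end = p_end,
                               is_title = seq_along(p_start) == 1L)

  s_start <- integer(); s_end <- integer(); s_para <- integer()
  for (pi in seq_along(p_start)) {
    pt <- span_text(text, p_start[pi], p_end[pi])
    brk <- sentence_breaks(pt)
    bounds <- unique(c(brk, nchar(pt)))
    from <- 1L
    for (b in bounds) {
      seg <- substr(pt, from, b)
      lead_ws <- nchar(seg) - nchar(sub("^\\s+", "", seg))
      trail_ws <- nchar(seg) - nchar(sub("\\s+$", "", seg))
      if (nchar(trimws(seg)) > 0) {
        s_start <- c(s_start, p_start[pi] + from - 1L + lead_ws)
        s_end <- c(s_end, p_start[pi] + b - trail_ws)
        s_para <- c(s_para, pi)
      }
      from <- b + 1L
    }
  }
  doc$sentences <- data.frame(index = seq_along(s_start), start = s_start,
                              end = s_end, paragraph_index = s_para)

  tok_text <- character(); tok_start <- integer(); tok_end <- integer()
  tok_sent <- integer()
  for (si in seq_along(s_start)) {
    st <- span_text(text, s_start[si], s_end[si])
    m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9 \t\r\n]", st)[[1]]
    if (m[1] == -1) next
    starts <- s_start[si] + as.integer(m) - 1L
    ends <- starts + attr(m, "match.length")
    tok_text <- c(tok_text, substring(st, as.integer(m),
                                      as.integer(m) + attr(m, "match.length") - 1L))
    tok_start <- c(tok_start, starts)
    tok_end <- c(tok_end, ends)
    tok_sent <- c(tok_sent, rep(si, length(starts)))
  }
  doc$tokens <- data.frame(text = tok_text, start = tok_start, end = tok_end,
                           sentence_index = tok_sent,
                           pos = if (length(tok_text)) tagger(tok_text) else character(),
                           stringsAsFactors = FALSE)
  doc$mentions <- assign_sentences(doc, doc$mentions)
  doc
}

#' Attach sentence indexes to mentions
#'
#' A mention belongs to the sentence containing its first fragment's start
#' offset (discontinuous mentions are handled via their first fragment).
#'
#' @param doc A segmented [bb_document()].
#' @param mentions A mentions data frame (defaults to the document's own).
#' @return The mentions data frame with a `sentence` integer column.
#' @export
assign_sentences <- function(doc, mentions = doc$mentions) {
  if (is.null(doc$sentences)) stop("document is not segmented")
  if (nrow(mentions) == 0) {
    mentions$sentence <- integer(0)
    return(mentions)
  }
  idx <- findInterval(mentions$start, doc$sentences$start)
  idx[idx < 1L] <- 1L
  mentions$sentence <- as.integer(idx)
  mentions
}
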