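## Rule-based co-reference resolution over typed entity mentions.
##
## Two precision-oriented strategies are combined and closed transitively:
##
## * Similarity of form: for each mention, every anterior mention of the
##   same type that is identical, matches by conventional abbreviation
##   (B. subtilis ~ Bacillus subtilis), matches by strain designator, or
##   differs by at most `e` Damerau-Levenshtein edit operations is linked.
##   Mentions consisting only of the words bacteria/bacterium/bacterial are
##   too generic and are blocked from similarity links.
## * Anaphora: the focus bacterium (title bacterium, updated at the first
##   bacterium mention of each paragraph) and the last bacterium mentioned
##   are tracked through the text; sentence-initial definite descriptions
##   ("This organism", "The bacterium", "The strain", ...) create new
##   indirect Bacteria mentions linked to the focus or last bacterium.
##   Pronouns and non-sentence-initial descriptions are never handled.

#' Co-reference resolver configuration
#'
#' @param max_edit_distance Maximum number of Damerau-Levenshtein edit
#'   operations for the similarity rule (default 1, the precision optimum).
#' @param block_generic_bacteria Block similarity links for mentions made
#'   only of the words bacteria/bacterium/bacterial (default `TRUE`).
#' @param hierarchy_constraint_enabled Suppress Bacteria-Bacteria similarity
#'   links whose taxonomic-level distance on the cline strain < subspecies <
#'   species < genus < family < higher exceeds `max_hierarchy_distance`
#'   (default `FALSE`; the retained configuration discards this constraint).
#' @param max_hierarchy_distance Maximum allowed level distance when the
#'   hierarchy constraint is enabled.
#' @param strategies Subset of `c("similarity", "anaphora")`.
#' @param min_edit_length Strings shorter than this many characters are
#'   never linked by raw edit distance (identity/abbreviation/strain rules
#'   still apply); avoids spurious 1-edit matches between short strain codes.
#' @return A list of class `bb_coref_config`.
#' @export
coref_config <- function(max_edit_distance = 1L,
                         block_generic_bacteria = TRUE,
                         hierarchy_constraint_enabled = FALSE,
                         max_hierarchy_distance = 2L,
                         strategies = c("similarity", "anaphora"),
                         min_edit_length = 4L) {
  stopifnot(max_edit_distance >= 0)
  structure(list(max_edit_distance = as.integer(max_edit_distance),
                 block_generic_bacteria = block_generic_bacteria,
                 hierarchy_constraint_enabled = hierarchy_constraint_enabled,
                 max_hierarchy_distance = as.integer(max_hierarchy_distance),
                 strategies = strategies,
                 min_edit_length = as.integer(min_edit_length)),
            class = "bb_coref_config")
}

#' Damerau-Levenshtein edit distance
#'
#' Minimal number of character insertions, deletions, substitutions or
#' adjacent transpositions (optimal string alignment) turning `a` into `b`.
#'
#' @param a,b Strings.
#' @return Non-negative integer.
#' @export
damerau_levenshtein <- function(a, b) {
  s <- strsplit(a, "")[[1]]; t <- strsplit(b, "")[[1]]
  n <- length(s); m <- length(t)
  if (n == 0) return(m)
  if (m == 0) return(n)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in 1:n) {
    for (j in 1:m) {
      cost <- if (s[i] == t[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
      if (i > 1 && j > 1 && s[i] == t[j - 1] && s[i - 1] == t[j])
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
    }
  }
  d[n + 1, m + 1]
}

split_words <- function(x) strsplit(trimws(x), "\\s+")[[1]]

# One word pair matches under the abbreviation convention: equal
# (case-insensitive), or one is a single initial + period expanding the
# other ("B." ~ "Bacillus").
word_abbrev_eq <- function(u, v) {
  lu <- tolower(u); lv <- tolower(v)
  if (lu == lv) return(TRUE)
  init <- function(w) grepl("^[A-Za-z]\\.$", w)
  if (init(u) && !init(v))
    return(substr(lu, 1, 1) == substr(lv, 1, 1))
  if (init(v) && !init(u))
    return(substr(lv, 1, 1) == substr(lu, 1, 1))
  FALSE
}

#' Conventional abbreviation / name matching of bacterium names
#'
#' True when the two forms match word by word under the initial-abbreviation
#' convention (writing B. subtilis for Bacillus subtilis), or when one form
#' is a word-boundary truncation of the other after a shared genus + species
#' head of at least two words (the name matching rule).
#'
#' @param a,b Mention surface strings.
#' @return Logical.
#' @export
abbreviation_match <- function(a, b) {
  wa <- split_words(a); wb <- split_words(b)
  if (length(wa) == 0 || length(wb) == 0) return(FALSE)
  k <- min(length(wa), length(wb))
  head_match <- all(vapply(seq_len(k), function(i) word_abbrev_eq(wa[i], wb[i]),
                           logical(1)))
  if (!head_match) return(FALSE)
  if (length(wa) == length(wb)) return(TRUE)
  k >= 2  # truncation allowed only after a genus + species head
}

# A token that looks like a strain code: contains a digit, a short code
# with at least two capital letters (PKo, DSMZ, USDA110), or a lone capital
# (the type-strain marker T).
is_strain_code <- function(tok) {
  if (grepl("[0-9]", tok)) return(TRUE)
  if (grepl("^[A-Z]$", tok)) return(TRUE)
  nchar(tok) <= 8 && nchar(gsub("[^A-Z]", "", tok)) >= 2
}

# Split a mention into (base name, strain designator token sequence).
split_strain <- function(x) {
  w <- split_words(x)
  n <- length(w)
  i <- n + 1L
  while (i > 1 && is_strain_code(w[i - 1L])) i <- i - 1L
  if (i > 1 && tolower(sub("\\.$", "", w[i - 1L])) %in% c("strain", "str") &&
      i <= n)
    i <- i - 1L
  list(base = w[seq_len(i - 1L)], designator = if (i <= n) w[i:n] else character())
}

strip_strain_kw <- function(d) {
  d[!tolower(sub("\\.$", "", d)) %in% c("strain", "str")]
}

#' Strain designator matching of bacterium names
#'
#' True when both mentions carry the identical strain designator token
#' sequence (pattern: `strain`/`str.` plus a code, or bare strain-code
#' tokens), or when one mention is the other plus a trailing strain
#' designator.
#'
#' @param a,b Mention surface strings.
#' @return Logical.
#' @export
strain_match <- function(a, b) {
  sa <- split_strain(a); sb <- split_strain(b)
  base_eq <- function(x, y) {
    if (length(x) == 0 || length(y) == 0) return(length(x) == length(y))
    abbreviation_match(paste(x, collapse = " "), paste(y, collapse = " "))
  }
  da <- strip_strain_kw(sa$designator); db <- strip_strain_kw(sb$designator)
  if (length(da) > 0 && length(db) > 0) {
    same_code <- length(da) == length(db) && all(tolower(da) == tolower(db))
    if (!same_code) return(FALSE)
    return(length(sa$base) == 0 || length(sb$base) == 0 || base_eq(sa$base, sb$base))
  }
  if (xor(length(da) > 0, length(db) > 0)) {
    # one form is the other plus a trailing designator
    return(length(sa$base) > 0 && length(sb$base) > 0 && base_eq(sa$base, sb$base))
  }
  FALSE
}

HIER_LEVELS <- c(strain = 1, subspecies = 2, species = 3, genus = 4,
                 family = 5, higher = 6)

#' Taxonomic level of a bacterium mention
#'
#' Pattern-based detection along the cline strain < subspecies < species <
#' genus < family < higher: strain designators, `subsp.`/`subspecies`,
#' binomial `Genus epithet` (full or abbreviated initial), single
#' capitalized Latin word (genus), `-aceae` suffix (family), `-ales`
#' and similar order/class suffixes (higher), `"unknown"` otherwise.
#'
#' @param m Mention surface string.
#' @return One of `"strain"`, `"subspecies"`, `"species"`, `"genus"`,
#'   `"family"`, `"higher"`, `"unknown"`.
#' @export
hierarchical_level <- function(m) {
  w <- split_words(m)
  if (length(w) == 0) return("unknown")
  if (length(strip_strain_kw(split_strain(m)$designator)) > 0) return("strain")
  if (any(tolower(sub("\\.$", "", w)) %in% c("subsp", "subspecies"))) return("subspecies")
  if (length(w) >= 2 && grepl("^[A-Z]", w[1]) && grepl("^[a-z]+$", w[2]))
    return("species")
  if (length(w) == 1 && grepl("^[A-Z][a-z]+$", w[1])) {
    if (grepl("aceae$", w[1])) return("family")
    if (grepl("(ales|etes)$", w[1])) return("higher")
    return("genus")
  }
  "unknown"
}

#' Is a mention a generic bacteria expression?
#'
#' True when every token of the mention, lowercased, is one of bacteria,
#' bacterium, bacterial. Such mentions are too generic to carry similarity
#' links reliably and are blocked by default.
#'
#' @param m Mention surface string.
#' @return Logical.
#' @export
is_generic_bacteria_mention <- function(m) {
  toks <- tolower(unlist(regmatches(m, gregexpr("[A-Za-z]+", m))))
  length(toks) > 0 && all(toks %in% c("bacteria", "bacterium", "bacterial"))
}

# Do two mention surface strings co-refer under the similarity rules?
similar_mentions <- function(a, b, config) {
  la <- tolower(trimws(a)); lb <- tolower(trimws(b))
  if (la == lb) return(TRUE)
  if (abbreviation_match(a, b)) return(TRUE)
  if (strain_match(a, b)) return(TRUE)
  if (nchar(la) >= config$min_edit_length && nchar(lb) >= config$min_edit_length &&
      abs(nchar(la) - nchar(lb)) <= config$max_edit_distance &&
      damerau_levenshtein(la, lb) <= config$max_edit_distance) return(TRUE)
  FALSE
}

#' Similarity-of-form co-reference pass
#'
#' Processes mentions in document order; for each mention, links it to every
#' anterior mention of the same entity type that is identical
#' (case-insensitive), matches the abbreviation or strain rule, or differs
#' by at most `max_edit_distance` edit operations.
#'
#' @param mentions Mentions data frame in document order.
#' @param config A [coref_config()].
#' @return Data frame of links with columns `anaphor`, `antecedent`,
#'   `source`.
#' @export
similarity_pass <- function(mentions, config = coref_config()) {
  links <- data.frame(anaphor = character(), antecedent = character(),
                      source = character(), stringsAsFactors = FALSE)
  if (nrow(mentions) < 2) return(links)
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  blocked <- if (config$block_generic_bacteria)
    vapply(mentions$text, is_generic_bacteria_mention, logical(1)) else
    rep(FALSE, nrow(mentions))
  levels_ <- rep(NA_real_, nrow(mentions))
  if (config$hierarchy_constraint_enabled) {
    isbac <- mentions$etype == "Bacteria"
    levels_[isbac] <- HIER_LEVELS[vapply(mentions$text[isbac],
                                         hierarchical_level, character(1))]
  }
  for (i in 2:nrow(mentions)) {
    if (blocked[i]) next
    for (j in seq_len(i - 1)) {
      if (blocked[j] || mentions$etype[j] != mentions$etype[i]) next
      if (config$hierarchy_constraint_enabled &&
          mentions$etype[i] == "Bacteria" &&
          !is.na(levels_[i]) && !is.na(levels_[j]) &&
          abs(levels_[i] - levels_[j]) > config$max_hierarchy_distance) next
      if (similar_mentions(mentions$text[i], mentions$text[j], config)) {
        links <- rbind(links, data.frame(
          anaphor = mentions$id[i], antecedent = mentions$id[j],
          source = "similarity", stringsAsFactors = FALSE))
      }
    }
  }
  links
}

ANA_LAST_RE <-
  "^[Tt]his (bacterium|bacteria|organism|genus|species|strain)\\b|^[Tt]his group of organisms\\b|^[Tt]he (genus|species|strain)\\b"
ANA_FOCUS_RE <- "^[Tt]he (bacterium|bacteria|organism)\\b"

#' Anaphora co-reference pass (centering + recentness)
#'
#' Tracks the focus bacterium (initially the title bacterium; updated at the
#' first Bacteria mention of each new paragraph) and the last bacterium
#' mentioned. Sentence-initial demonstrative descriptions (`This bacterium
#' |bacteria|organism|genus|species|strain`, `This group of organisms`) and
#' specific definite descriptions (`The genus|species|strain`) are linked to
#' the last bacterium; generic definite descriptions (`The bacterium
#' |bacteria|organism`) are linked to the focus bacterium. Each match
#' creates a new indirect Bacteria mention spanning the matched phrase.
#' Non-sentence-initial occurrences and pronouns are ignored.
#'
#' @param doc A segmented [bb_document()].
#' @param mentions Mentions data frame (defaults to the document's).
#' @return List with `mentions` (new indirect mentions), `links`, and
#'   `trace` (per-sentence focus/last state).
#' @export
anaphora_pass <- function(doc, mentions = doc$mentions) {
  if (is.null(doc$sentences)) stop("document is not segmented")
  mentions <- assign_sentences(doc, mentions)
  bac <- mentions[mentions$etype == "Bacteria" & !mentions$indirect, , drop = FALSE]
  bac <- bac[order(bac$start), , drop = FALSE]

  new_men <- empty_mentions()
  links <- data.frame(anaphor = character(), antecedent = character(),
                      source = character(), stringsAsFactors = FALSE)
  trace <- data.frame(sentence = integer(), focus = character(),
                      last = character(), stringsAsFactors = FALSE)
  if (nrow(doc$sentences) == 0)
    return(list(mentions = new_men, links = links, trace = trace))

  focus <- NA_character_; last <- NA_character_
  seen_para <- integer()
  next_id <- 1L
  sent_para <- doc$sentences$paragraph_index

  for (si in seq_len(nrow(doc$sentences))) {
    s0 <- doc$sentences$start[si]; s1 <- doc$sentences$end[si]
    stext <- span_text(doc$text, s0, s1)
    in_sent <- bac[bac$start >= s0 & bac$start < s1, , drop = FALSE]

    # anaphor pattern anchored at sentence start, resolved against the
    # discourse state *before* this sentence's bacterium mentions
    m_last <- regexpr(ANA_LAST_RE, stext)
    m_focus <- regexpr(ANA_FOCUS_RE, stext)
    pick <- if (m_last > 0) list(re = m_last, ante = last)
            else if (m_focus > 0) list(re = m_focus, ante = focus)
            else NULL
    if (!is.null(pick) && !is.na(pick$ante)) {
      len <- attr(pick$re, "match.length")
      id <- paste0("A", next_id); next_id <- next_id + 1L
      new_men <- rbind(new_men, data.frame(
        id = id, etype = "Bacteria", start = s0, end = s0 + len,
        frag_spec = paste(s0, s0 + len), text = substr(stext, 1, len),
        indirect = TRUE, stringsAsFactors = FALSE))
      links <- rbind(links, data.frame(anaphor = id, antecedent = pick$ante,
                                       source = "anaphora",
                                       stringsAsFactors = FALSE))
    }

    if (nrow(in_sent) > 0) {
      pi <- sent_para[si]
      if (!(pi %in% seen_para)) {
        focus <- in_sent$id[1]   # first bacterium of a new paragraph
        seen_para <- c(seen_para, pi)
      }
      if (is.na(focus)) focus <- in_sent$id[1]
      last <- in_sent$id[nrow(in_sent)]
    }
    trace <- rbind(trace, data.frame(sentence = si, focus = focus, last = last,
                                     stringsAsFactors = FALSE))
  }
  if (nrow(new_men) > 0) new_men <- assign_sentences(doc, new_men)
  list(mentions = new_men, links = links, trace = trace)
}

#' Transitive closure of co-reference links into chains
#'
#' Union-find closure over the links; only chains with at least two members
#' are kept. Each chain's representative is its earliest non-indirect
#' mention; chains containing only indirect mentions are dropped with a
#' warning.
#'
#' @param links Data frame with columns `anaphor`, `antecedent`.
#' @param mentions Mentions data frame covering all linked ids.
#' @return List of chains; each chain is a list with `members` (mention
#'   ids) and `representative`.
#' @export
build_chains <- function(links, mentions) {
  if (nrow(links) == 0) return(list())
  ids <- unique(c(links$anaphor, links$antecedent))
  unknown <- setdiff(ids, mentions$id)
  if (length(unknown) > 0)
    stop("links reference unknown mentions: ", paste(unknown, collapse = ", "))
  uf <- uf_new(ids)
  for (k in seq_len(nrow(links))) uf_union(uf, links$anaphor[k], links$antecedent[k])
  comps <- uf_components(uf, min_size = 2L)
  out <- list()
  for (comp in comps) {
    rows <- mentions[match(comp, mentions$id), , drop = FALSE]
    direct <- rows[!rows$indirect, , drop = FALSE]
    if (nrow(direct) == 0) {
      warning("dropping chain containing only indirect mentions: ",
              paste(comp, collapse = ", "), call. = FALSE)
      next
    }
    rep_id <- direct$id[which.min(direct$start)]
    out <- c(out, list(list(members = comp[order(rows$start)],
                            representative = rep_id)))
  }
  out
}

#' Resolve co-reference for one document
#'
#' Runs the configured strategies (similarity first, then anaphora) and
#' closes the resulting links transitively into chains.
#'
#' @param doc A segmented [bb_document()].
#' @param mentions Mentions to resolve (defaults to the document's own, e.g.
#'   gold mentions for the gold-mention setting or predicted mentions for
#'   the end-to-end setting).
#' @param config A [coref_config()].
#' @return List with `chains`, `links`, `indirect_mentions` and `mentions`
#'   (input plus indirect).
#' @export
resolve_coreference <- function(doc, mentions = doc$mentions,
                                config = coref_config()) {
  links <- data.frame(anaphor = character(), antecedent = character(),
                      source = character(), stringsAsFactors = FALSE)
  indirect <- empty_mentions()
  if ("similarity" %in% config$strategies)
    links <- rbind(links, similarity_pass(mentions, config))
  if ("anaphora" %in% config$strategies) {
    ana <- anaphora_pass(doc, mentions)
    links <- rbind(links, ana$links)
    indirect <- ana$mentions
  }
  all_men <- rbind(mentions[, names(empty_mentions())],
                   indirect[, names(empty_mentions())])
  all_men <- assign_sentences(doc, all_men)
  chains <- build_chains(links, all_men)
  list(chains = chains, links = links, indirect_mentions = indirect,
       mentions = all_men)
}
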