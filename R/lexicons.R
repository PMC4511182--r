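## Loaders for the four external feature resources used by mention detection:
## an OBO ontology term list (habitat vocabulary), a flat taxon name list,
## a Brown-cluster path file (word -> bit-string), and Cocoa-style standoff
## category annotations.

normalize_term <- function(x) tolower(trimws(gsub("\\s+", " ", x)))

term_tokens <- function(terms) {
  unique(unlist(regmatches(terms, gregexpr("[a-z0-9]+", terms))))
}

new_lexicon <- function(name, terms) {
  terms <- unique(normalize_term(terms))
  terms <- terms[nzchar(terms)]
  structure(list(name = name, terms = terms, token_index = term_tokens(terms)),
            class = "bb_lexicon")
}

#' @export
print.bb_lexicon <- function(x, ...) {
  cat(sprintf("<bb_lexicon %s: %d terms, %d distinct tokens>\n",
              x$name, length(x$terms), length(x$token_index)))
  invisible(x)
}

#' Lexicon membership queries
#'
#' `lex_has_term()` tests full (multi-word) terms; `lex_has_token()` tests
#' whether a single token occurs inside any lexicon term (the token-wise
#' statistic used as a classifier feature). Both are case-insensitive.
#'
#' @param lex A lexicon from [load_obo_terms()] or [load_name_list()].
#' @param x Character vector of terms or tokens.
#' @return Logical vector.
#' @export
lex_has_term <- function(lex, x) normalize_term(x) %in% lex$terms

#' @rdname lex_has_term
#' @export
lex_has_token <- function(lex, x) tolower(x) %in% lex$token_index

#' Load habitat terms from an OBO ontology file
#'
#' Collects the `name:` and every `synonym:` string of each `[Term]` stanza
#' of an OBO 1.2 flat file, lowercased, into a term lexicon.
#'
#' @param path Path to the OBO file.
#' @return A `bb_lexicon`.
#' @export
load_obo_terms <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  in_term <- FALSE
  terms <- character()
  for (line in lines) {
    line <- trimws(line)
    if (grepl("^\\[", line)) {
      in_term <- identical(line, "[Term]")
    } else if (in_term) {
      if (startsWith(line, "name:")) {
        terms <- c(terms, sub("^name:\\s*", "", line))
      } else if (startsWith(line, "synonym:")) {
        m <- regmatches(line, regexpr('"[^"]*"', line))
        if (length(m)) terms <- c(terms, gsub('"', "", m))
      }
    }
  }
  new_lexicon("ontobiotope", terms)
}

#' Load a flat one-name-per-line taxon list
#'
#' @param path Path to the text file (one bacterium name per line).
#' @return A `bb_lexicon`.
#' @export
load_name_list <- function(path) {
  lines <- if (file.exists(path)) readLines(path, warn = FALSE, encoding = "UTF-8")
           else stop("cannot read name list: ", path)
  new_lexicon("taxa", lines)
}

#' Load a Brown-cluster path file
#'
#' Reads lines `bitpath<TAB>word[<TAB>count]` mapping each word to its
#' bit-string path in the cluster hierarchy. Lookup of an unseen word
#' returns the designated out-of-vocabulary value.
#'
#' @param path Path to the TSV file.
#' @param oov_value Value returned for unseen words (default `"<OOV>"`).
#' @return An object of class `bb_clusters`.
#' @export
load_cluster_paths <- function(path, oov_value = "<OOV>") {
  lines <- if (file.exists(path)) readLines(path, warn = FALSE, encoding = "UTF-8")
           else stop("cannot read cluster file: ", path)
  lines <- lines[nzchar(lines)]
  words <- character(length(lines)); paths <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2 || !grepl("^[01]+$", f[1]))
      stop("malformed cluster line at ", path, ":", i)
    paths[i] <- f[1]; words[i] <- f[2]
  }
  structure(list(map = stats::setNames(paths, tolower(words)),
                 oov_value = oov_value),
            class = "bb_clusters")
}

#' Look up cluster paths for words
#'
#' @param clusters A `bb_clusters` object.
#' @param words Character vector.
#' @param prefix Optional prefix length to truncate paths to (full path if
#'   `NULL`).
#' @return Character vector of bit-string paths or the OOV value.
#' @export
cluster_path <- function(clusters, words, prefix = NULL) {
  out <- unname(clusters$map[tolower(words)])
  out[is.na(out)] <- clusters$oov_value
  if (!is.null(prefix)) {
    hit <- out != clusters$oov_value
    out[hit] <- substr(out[hit], 1, prefix)
  }
  out
}

#' Load Cocoa-style category annotations for one document
#'
#' Cocoa annotations are `T`-line standoff spans with arbitrary category
#' names (Organism, Habitat, Disease, ...). All spans and categories are
#' retained, including overlapping spans and categories outside the
#' entity-type inventory.
#'
#' @param path Path to the standoff `.ann` file.
#' @param text_length Optional document length for bounds checking.
#' @return Data frame with columns `start`, `end`, `category`, `text`.
#' @export
load_cocoa <- function(path, text_length = NULL) {
  out <- data.frame(start = integer(), end = integer(),
                    category = character(), text = character(),
                    stringsAsFactors = FALSE)
  if (!file.exists(path)) return(out)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i]) || substr(lines[i], 1, 1) != "T") next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    m <- regmatches(fields[2], regexec("^(\\S+) (\\d+) (\\d+)", fields[2]))[[1]]
    if (length(m) == 0) stop("malformed Cocoa line at ", path, ":", i)
    start <- as.integer(m[3]); end <- as.integer(m[4])
    if (!is.null(text_length) && (start < 0 || end > text_length || start >= end))
      stop("Cocoa offsets out of bounds at ", path, ":", i)
    out <- rbind(out, data.frame(start = start, end = end, category = m[2],
                                 text = if (length(fields) >= 3) fields[3] else "",
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Bundle feature resources for a corpus
#'
#' @param obo Path to the OBO ontology file (or `NULL`).
#' @param taxa Path to the taxon name list (or `NULL`).
#' @param clusters Path to the Brown-cluster path file (or `NULL`).
#' @param cocoa_dir Directory of per-document Cocoa `.ann` files (or `NULL`).
#' @return A list of loaded resources of class `bb_resources`.
#' @export
load_resources <- function(obo = NULL, taxa = NULL, clusters = NULL,
                           cocoa_dir = NULL) {
  structure(list(
    obo = if (!is.null(obo)) load_obo_terms(obo),
    taxa = if (!is.null(taxa)) load_name_list(taxa),
    clusters = if (!is.null(clusters)) load_cluster_paths(clusters),
    cocoa_dir = cocoa_dir,
    cocoa_cache = new.env(parent = emptyenv())
  ), class = "bb_resources")
}

# Cocoa annotations for one document id (cached); empty df when absent.
cocoa_for_doc <- function(resources, doc_id) {
  if (is.null(resources) || is.null(resources$cocoa_dir))
    return(load_cocoa(tempfile()))  # empty frame
  if (!is.null(resources$cocoa_cache[[doc_id]]))
    return(resources$cocoa_cache[[doc_id]])
  ann <- load_cocoa(file.path(resources$cocoa_dir, paste0(doc_id, ".ann")))
  resources$cocoa_cache[[doc_id]] <- ann
  ann
}
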