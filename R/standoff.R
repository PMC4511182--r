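## BRAT standoff input/output in the Bacteria Biotope dialect.
##
## A document is a plain-text file (`.txt`) plus standoff annotation files:
## `.a1` holds entity mentions (`T` lines), `.a2` holds binary relations
## (`R` lines) and co-reference equivalence groups (`*<TAB>Equiv` lines).
## Offsets are 0-based, end-exclusive character positions into the text.

ENTITY_TYPES <- c("Bacteria", "Habitat", "Geographical")
RELATION_TYPES <- c("Localization", "PartOf")

empty_mentions <- function() {
  data.frame(id = character(), etype = character(),
             start = integer(), end = integer(),
             frag_spec = character(), text = character(),
             indirect = logical(), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = character(), rtype = character(),
             arg1 = character(), arg2 = character(), stringsAsFactors = FALSE)
}

#' Construct a standoff document
#'
#' Bundles a document's raw text with its annotation layers (entity mentions,
#' relations, equivalence groups) and, after [segment_document()], its
#' paragraph/sentence/token segmentation.
#'
#' @param doc_id Document identifier (usually the file stem).
#' @param text Full document text.
#' @param mentions Data frame of entity mentions with columns `id`, `etype`
#'   (`Bacteria`, `Habitat` or `Geographical`), `start`, `end` (first
#'   fragment, 0-based end-exclusive), `frag_spec` (all fragments as
#'   `"start end[;start end]*"`), `text` and `indirect` (`TRUE` only for
#'   mentions created by anaphora resolution; never serialized to `.a1`).
#' @param relations Data frame with columns `id`, `rtype` (`Localization` or
#'   `PartOf`), `arg1`, `arg2` (mention ids; Bacterium/Host first).
#' @param equiv_groups List of character vectors of mention ids, each of
#'   length >= 2, marking co-referring mentions.
#' @return An object of class `bb_document`.
#' @export
bb_document <- function(doc_id, text, mentions = empty_mentions(),
                        relations = empty_relations(), equiv_groups = list()) {
  stopifnot(is.character(text), length(text) == 1)
  structure(list(doc_id = doc_id, text = text,
                 mentions = mentions, relations = relations,
                 equiv_groups = equiv_groups,
                 paragraphs = NULL, sentences = NULL, tokens = NULL),
            class = "bb_document")
}

#' @export
print.bb_document <- function(x, ...) {
  cat(sprintf("<bb_document %s: %d chars, %d mentions, %d relations, %d equiv groups%s>\n",
              x$doc_id, nchar(x$text), nrow(x$mentions), nrow(x$relations),
              length(x$equiv_groups),
              if (is.null(x$sentences)) "" else sprintf(", %d sentences", nrow(x$sentences))))
  invisible(x)
}

# Parse "start end[;start end]*" into an integer matrix (one row per fragment).
parse_frag_spec <- function(spec) {
  parts <- strsplit(strsplit(spec, ";", fixed = TRUE)[[1]], " ", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) as.integer(p[1:2])))
  colnames(m) <- c("start", "end")
  m
}

# Substring by 0-based end-exclusive offsets.
span_text <- function(text, start, end) substring(text, start + 1, end)

frag_text <- function(text, spec) {
  m <- parse_frag_spec(spec)
  paste(span_text(text, m[, 1], m[, 2]), collapse = " ")
}

#' Read a BRAT standoff document
#'
#' Parses the text file and any number of annotation files. `T` lines become
#' entity mentions (semicolon-separated discontinuous fragments supported),
#' `R` lines become relations and `*<TAB>Equiv` lines become equivalence
#' groups. Lines of other annotation types (events, normalizations, notes)
#' are skipped with a warning.
#'
#' @param txt_path Path to the `.txt` file.
#' @param ann_paths Character vector of annotation file paths (`.a1`, `.a2`);
#'   missing files are allowed and ignored.
#' @param doc_id Document id; defaults to the text file stem.
#' @return A [bb_document()].
#' @export
read_document <- function(txt_path, ann_paths = character(), doc_id = NULL) {
  if (!file.exists(txt_path)) stop("text file not found: ", txt_path)
  text <- readChar(txt_path, file.info(txt_path)$size, useBytes = FALSE)
  Encoding(text) <- "UTF-8"
  if (is.null(doc_id)) doc_id <- sub("\\.txt$", "", basename(txt_path))
  doc <- bb_document(doc_id, text)

  for (path in ann_paths) {
    if (!file.exists(path)) next
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    for (i in seq_along(lines)) {
      line <- lines[i]
      if (!nzchar(line)) next
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      head1 <- substr(fields[1], 1, 1)
      if (head1 == "T") {
        if (length(fields) < 2) stop("malformed T line at ", path, ":", i)
        ts <- regmatches(fields[2], regexpr("^\\S+", fields[2]))
        spec <- sub("^\\S+ ", "", fields[2])
        if (!grepl("^\\d+ \\d+(;\\d+ \\d+)*$", spec))
          stop("malformed offsets at ", path, ":", i, ": '", spec, "'")
        frags <- parse_frag_spec(spec)
        if (any(frags[, 1] >= frags[, 2]) || any(frags[, 2] > nchar(text)) ||
            any(frags[, 1] < 0))
          stop("offsets out of bounds at ", path, ":", i)
        surface <- if (length(fields) >= 3) fields[3] else frag_text(text, spec)
        doc$mentions <- rbind(doc$mentions, data.frame(
          id = fields[1], etype = ts, start = frags[1, 1], end = frags[1, 2],
          frag_spec = spec, text = surface, indirect = FALSE,
          stringsAsFactors = FALSE))
      } else if (head1 == "R") {
        m <- regmatches(fields[2],
                        regexec("^(\\S+) (\\S+):(\\S+) (\\S+):(\\S+)$", fields[2]))[[1]]
        if (length(m) == 0) stop("malformed R line at ", path, ":", i)
        doc$relations <- rbind(doc$relations, data.frame(
          id = fields[1], rtype = m[2], arg1 = m[4], arg2 = m[6],
          stringsAsFactors = FALSE))
      } else if (fields[1] == "*") {
        toks <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
        if (toks[1] != "Equiv" || length(toks) < 3)
          stop("malformed Equiv line at ", path, ":", i)
        doc$equiv_groups <- c(doc$equiv_groups, list(toks[-1]))
      } else {
        warning("skipping unsupported annotation line type '", head1,
                "' at ", path, ":", i, call. = FALSE)
      }
    }
  }
  missing <- unlist(doc$equiv_groups)[!unlist(doc$equiv_groups) %in% doc$mentions$id]
  if (length(missing) > 0)
    stop("Equiv group references unknown mention id(s): ",
         paste(unique(missing), collapse = ", "))
  doc
}

#' Write standoff annotations
#'
#' Emits `<doc_id>.a1` (entity mentions) and `<doc_id>.a2` (relations and
#' Equiv groups) in the dialect read by [read_document()]. Indirect mentions
#' (created by anaphora resolution) are never serialized; mention and
#' relation ids are renumbered contiguously in document order.
#'
#' @param doc A [bb_document()].
#' @param out_dir Output directory (created if needed).
#' @param write_text If `TRUE`, also write `<doc_id>.txt`.
#' @return Invisibly, the paths written.
#' @export
write_annotations <- function(doc, out_dir, write_text = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  men <- doc$mentions
  if (anyDuplicated(men$id)) stop("duplicate mention ids in ", doc$doc_id)
  direct <- men[!men$indirect, , drop = FALSE]
  direct <- direct[order(direct$start, direct$end), , drop = FALSE]
  new_ids <- paste0("T", seq_len(nrow(direct)))
  id_map <- stats::setNames(new_ids, direct$id)

  a1 <- sprintf("%s\t%s %s\t%s", new_ids, direct$etype, direct$frag_spec, direct$text)

  rel <- doc$relations
  a2 <- character()
  if (nrow(rel) > 0) {
    bad <- !(rel$arg1 %in% direct$id) | !(rel$arg2 %in% direct$id)
    if (any(bad))
      stop("relation references a missing or indirect mention in ", doc$doc_id,
           ": ", paste(rel$id[bad], collapse = ", "))
    roles <- ifelse(rel$rtype == "Localization",
                    "Bacterium:%s Localization:%s", "Host:%s Part:%s")
    a2 <- sprintf("R%d\t%s %s", seq_len(nrow(rel)), rel$rtype,
                  sprintf(roles, id_map[rel$arg1], id_map[rel$arg2]))
  }
  for (grp in doc$equiv_groups) {
    kept <- grp[grp %in% direct$id]
    if (length(kept) >= 2)
      a2 <- c(a2, paste0("*\tEquiv ", paste(id_map[kept], collapse = " ")))
  }

  paths <- file.path(out_dir, paste0(doc$doc_id, c(".a1", ".a2")))
  writeLines(a1, paths[1])
  writeLines(a2, paths[2])
  if (write_text) {
    tp <- file.path(out_dir, paste0(doc$doc_id, ".txt"))
    writeChar(doc$text, tp, eos = NULL)
    paths <- c(paths, tp)
  }
  invisible(paths)
}
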