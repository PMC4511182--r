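## Seeded generator of encyclopedia-style documents about bacteria, with
## gold standoff annotations and all four feature resources, so that every
## pipeline stage is trainable and testable without downloading anything.
##
## Each document is titled with a binomial bacterium name (alone on the
## first line), describes one or two focus bacteria over several
## paragraphs, and expresses Localization/PartOf relations in single
## sentences. Later references to a bacterium use the full binomial, the
## conventional `G. epithet` abbreviation, or a strain-suffixed variant;
## all name variants of one bacterium form a gold Equiv group. A
## configurable fraction of relations is expressed only through such a
## variant placed far (more than the decoding distance) from every
## full-name mention, which is what makes co-reference resolution
## measurable extrinsically. Sentence-initial anaphors ("This organism
## ...") are inserted but never annotated as gold mentions, mirroring the
## annotation guideline that a definite description is not the name of a
## bacterium.
##
## Bacteria names are built from synthetic Latin-like morphemes (no real
## taxonomy is shipped); habitat and geography vocabularies are curated so
## that no two single-word entries are within one edit operation of each
## other, keeping the similarity rules' behaviour on the corpus exact.

GENUS_PREFIX <- c("Lacto", "Strepto", "Clostro", "Rhodo", "Thermo", "Halo",
                  "Nitro", "Sulfo", "Flavo", "Chryso", "Geo", "Aqua",
                  "Pyro", "Xantho", "Brevi", "Dulci", "Micro", "Ferro",
                  "Agro", "Petro")
GENUS_SUFFIX <- c("bacillus", "coccus", "monas", "bacter", "myces",
                  "spira", "vibrio", "planes", "cystis", "thrix")
EPITHETS <- c("albarius", "brevipes", "calidus", "durans", "estuarii",
              "fervidus", "glaciei", "horti", "ignavus", "jucundus",
              "karsticus", "litoralis", "montanus", "nivalis", "obscurus",
              "paludis", "quietus", "rupestris", "silvae", "tepidus",
              "umbrosus", "vastus", "xylosus", "pratensis", "fontis",
              "maritimus", "arenae", "collis", "dunensis", "vernalis")
HABITATS <- c("soil", "freshwater", "sediment", "compost", "sewage",
              "groundwater", "seawater", "raw milk", "fermented dough",
              "cheese brine", "wheat silage", "rice paddies", "hot springs",
              "salt marshes", "river mud", "forest litter",
              "coastal lagoons", "alpine meadows", "thermal vents",
              "peat bogs")
PART_WORDS <- c("gut", "rumen", "intestine", "hide", "roots", "gills",
                "bark", "plumage")
HOST_WORDS <- c("cows", "pigs", "humans", "chickens", "sheep", "horses",
                "salmon", "poplar trees", "wild boars", "honey bees")
GEOS <- c("Europe", "Japan", "Brazil", "Canada", "Norway", "Kenya",
          "Mexico", "Vietnam", "Portugal", "Finland", "Australia", "Peru")
COCOA_CATS <- c("Organism", "Habitat", "Location", "Chemical", "Disease",
                "Technique", "Unknown")
OBO_DECOYS <- c("autoclave", "culture flask", "microscope slide",
                "cold room", "glass beads", "filter paper",
                "reference library", "storage cabinet", "water bath",
                "steel tank", "growth chamber", "sampling kit")
FILLERS <- c("It grows best at moderate temperatures.",
             "Colonies appear smooth and pale on standard media.",
             "Growth slows markedly under acidic conditions.",
             "Its metabolism has been studied in detail.",
             "Laboratory cultures require routine subculturing.",
             "Cells are rod shaped and weakly motile.",
             "Optimal growth occurs after two days of incubation.",
             "Several related strains remain poorly characterized.",
             "Genome sequencing was completed recently.",
             "Further taxonomic work is clearly needed.")

#' Synthetic corpus configuration
#'
#' The defaults define the reference study conditions used throughout the
#' package's tests: 200 documents, conventional abbreviation used for 80
#' percent of variant references, 40 percent of relation events expressed
#' only through a co-referring name variant, and 10 percent expressed only
#' through a sentence-initial anaphor.
#'
#' @param n_docs Number of documents.
#' @param n_bacteria,n_habitats,n_geo Vocabulary sizes (bounded by the
#'   built-in morpheme inventories).
#' @param p_abbrev Probability that a variant reference uses the
#'   `G. epithet` abbreviation (otherwise a strain-suffixed variant).
#' @param p_second Probability that a document describes a second
#'   bacterium.
#' @param p_anaphora Rate of non-relation sentence-initial anaphor
#'   sentences among connective sentences (roughly per paragraph).
#' @param cross_fraction Fraction of relation events expressible only via a
#'   co-referring name variant in a distant sentence.
#' @param ana_fraction Fraction of relation events expressible only via a
#'   sentence-initial anaphor.
#' @param events_range Integer range (min, max) of relation events per
#'   document.
#' @param cocoa_noise Fraction of Cocoa spans given a wrong category.
#' @param n_decoys Decoy entries added to the ontology and taxon list.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return A list of class `bb_synth_config`.
#' @export
synth_config <- function(n_docs = 200L, n_bacteria = 60L, n_habitats = 20L,
                         n_geo = 12L, p_abbrev = 0.8, p_second = 0.3,
                         p_anaphora = 0.25, cross_fraction = 0.4,
                         ana_fraction = 0.1, events_range = c(3L, 5L),
                         cocoa_noise = 0.1, n_decoys = 12L, seed = 20259L) {
  probs <- c(p_abbrev, p_second, p_anaphora, cross_fraction, ana_fraction,
             cocoa_noise)
  stopifnot(all(probs >= 0 & probs <= 1), cross_fraction + ana_fraction <= 1)
  if (n_habitats > length(HABITATS) || n_geo > length(GEOS) ||
      n_bacteria > length(GENUS_PREFIX) * length(GENUS_SUFFIX))
    stop("requested vocabulary larger than the built-in inventories")
  structure(list(n_docs = as.integer(n_docs), n_bacteria = as.integer(n_bacteria),
                 n_habitats = as.integer(n_habitats), n_geo = as.integer(n_geo),
                 p_abbrev = p_abbrev, p_second = p_second,
                 p_anaphora = p_anaphora, cross_fraction = cross_fraction,
                 ana_fraction = ana_fraction,
                 events_range = as.integer(events_range),
                 cocoa_noise = cocoa_noise, n_decoys = as.integer(n_decoys),
                 seed = as.integer(seed)),
            class = "bb_synth_config")
}

synth_vocab <- function(config) {
  combos <- expand.grid(p = GENUS_PREFIX, s = GENUS_SUFFIX,
                        stringsAsFactors = FALSE)
  combos <- combos[sample(nrow(combos)), , drop = FALSE]
  genus <- paste0(combos$p, tolower(combos$s))
  n_bact <- config$n_bacteria
  bacteria <- data.frame(
    genus = genus[seq_len(n_bact)],
    epithet = EPITHETS[1 + (seq_len(n_bact) - 1) %% length(EPITHETS)],
    stringsAsFactors = FALSE)
  bacteria$full <- paste(bacteria$genus, bacteria$epithet)
  bacteria$abbrev <- paste0(substr(bacteria$genus, 1, 1), ". ",
                            bacteria$epithet)
  bacteria$code <- paste0(
    vapply(seq_len(n_bact), function(i)
      paste(sample(LETTERS, 3), collapse = ""), character(1)),
    sample(100:999, n_bact, replace = TRUE))
  decoy_idx <- seq(n_bact + 1, min(n_bact + config$n_decoys, length(genus)))
  list(bacteria = bacteria,
       habitats = sample(HABITATS, config$n_habitats),
       geos = sample(GEOS, config$n_geo),
       parts = PART_WORDS, hosts = HOST_WORDS,
       taxa_decoys = paste(genus[decoy_idx],
                           sample(EPITHETS, length(decoy_idx))))
}

# --- sentence assembly -----------------------------------------------------

# A part is plain text or a mention; a mention part may carry one nested
# inner mention given by a character offset/length within the part.
pt <- function(text) list(text = text, etype = NA_character_)
pm <- function(text, etype, entity = NA_character_,
               inner = NULL) {
  list(text = text, etype = etype, entity = entity, inner = inner)
}

assemble_sentence <- function(parts) {
  text <- ""
  mentions <- list()
  for (p in parts) {
    at <- nchar(text)
    text <- paste0(text, p$text)
    if (!is.na(p$etype)) {
      mentions <- c(mentions, list(list(start = at, end = at + nchar(p$text),
                                        etype = p$etype, entity = p$entity)))
      if (!is.null(p$inner))
        mentions <- c(mentions, list(list(start = at + p$inner$offset,
                                          end = at + p$inner$offset + p$inner$len,
                                          etype = p$inner$etype,
                                          entity = NA_character_)))
    }
  }
  list(text = text, mentions = mentions)
}

# --- document generation ---------------------------------------------------

gen_document <- function(doc_id, config, vocab) {
  n_ent <- 1L + stats::rbinom(1, 1, config$p_second)
  cand <- vocab$bacteria[sample(nrow(vocab$bacteria)), , drop = FALSE]
  ents <- cand[!duplicated(substr(cand$genus, 1, 1)) & !duplicated(cand$epithet), ,
               drop = FALSE][seq_len(n_ent), , drop = FALSE]

  n_events <- sample(config$events_range[1]:config$events_range[2], 1)
  kinds <- sample(c("cross", "ana", "direct"), n_events, replace = TRUE,
                  prob = c(config$cross_fraction, config$ana_fraction,
                           1 - config$cross_fraction - config$ana_fraction))
  subkind <- ifelse(kinds == "direct",
                    sample(c("habitat", "geo", "partof"), n_events,
                           replace = TRUE, prob = c(0.55, 0.25, 0.20)),
                    kinds)
  ent_of <- sample(seq_len(n_ent), n_events, replace = TRUE,
                   prob = if (n_ent == 2) c(0.7, 0.3) else 1)

  hab_pool <- sample(vocab$habitats)
  geo_pool <- sample(vocab$geos)
  part_pool <- sample(vocab$parts)
  host_pool <- sample(vocab$hosts)
  genv <- environment()
  take <- function(pool_name, n = 1) {
    pool <- get(pool_name, envir = genv)
    if (length(pool) < n) stop("vocabulary too small for requested density (",
                               pool_name, ") in ", doc_id)
    out <- pool[seq_len(n)]
    assign(pool_name, pool[-seq_len(n)], envir = genv)
    out
  }

  # sentence/mention/relation accumulators; mention rows are appended in
  # emission order so row order equals offset order
  sents <- character(); men <- list(); rels <- list()
  first_row <- integer(n_ent)       # first mention row of each entity
  last_B <- rep(-10L, n_ent)        # sentence of last bacterium mention
  last_H <- rep(-10L, n_ent)        # sentence of last related habitat/geo
  last_entity <- NA_integer_
  stats_rows <- c(total = 0L, cross = 0L, ana = 0L)

  emit <- function(sent) {
    sents[[length(sents) + 1L]] <<- sent$text
    si <- length(sents)
    for (m in sent$mentions) {
      men[[length(men) + 1L]] <<- c(m, list(sentence = si))
      ent <- m$entity %||% NA_character_
      if (!is.na(ent)) {
        e <- as.integer(ent)
        if (first_row[e] == 0L) first_row[e] <<- length(men)
        last_B[e] <<- si
        last_entity <<- e
      }
    }
    si
  }
  n_men <- function() length(men)

  filler_sentence <- function() {
    # connective material: plain filler or a negative-context entity
    # sentence (habitat/geography mention carrying no relation)
    r <- stats::runif(1)
    if (r < 0.25 && length(geo_pool) > 6) {
      g <- take("geo_pool")
      tmpl <- sample(c("Reference collections near %s maintain several isolates.",
                       "Taxonomists throughout %s revised the genus twice."), 1)
      pre <- sub("%s.*$", "", tmpl); post <- sub("^.*%s", "", tmpl)
      return(assemble_sentence(list(pt(pre), pm(g, "Geographical"), pt(post))))
    }
    if (r < 0.5 && length(hab_pool) > 12) {
      h <- take("hab_pool")
      tmpl <- sample(c("Comparative surveys beyond %s found no trace of it.",
                       "Unrelated microbes dominate near %s all year round."), 1)
      pre <- sub("%s.*$", "", tmpl); post <- sub("^.*%s", "", tmpl)
      return(assemble_sentence(list(pt(pre), pm(h, "Habitat"), pt(post))))
    }
    assemble_sentence(list(pt(sample(FILLERS, 1))))
  }

  pad_until <- function(cond) {
    while (!cond()) emit(filler_sentence())
  }
  gap_ok <- function(e, need_B_gap, need_H_gap) {
    force(e)
    function() {
      si <- length(sents) + 1L
      (!need_B_gap || si - last_B[e] >= 4L) &&
        (!need_H_gap || si - last_H[e] >= 4L)
    }
  }

  add_rel <- function(rtype, arg1_row, arg2_row, kind) {
    rels[[length(rels) + 1L]] <<- list(rtype = rtype, a1 = arg1_row,
                                       a2 = arg2_row, kind = kind)
    stats_rows["total"] <<- stats_rows["total"] + 1L
    if (kind %in% c("cross", "ana"))
      stats_rows[kind] <<- stats_rows[kind] + 1L
  }

  # title + intros
  emit(assemble_sentence(list(pm(ents$full[1], "Bacteria", "1"))))
  year <- 1900 + sample(0:99, 1)
  emit(assemble_sentence(list(pm(ents$full[1], "Bacteria", "1"),
                              pt(sprintf(" was described as a distinct species in %d.", year)))))
  if (n_ent == 2)
    emit(assemble_sentence(list(pt("A related species, "),
                                pm(ents$full[2], "Bacteria", "2"),
                                pt(", shows comparable behaviour."))))

  # one variant sentence bundles all cross events of an entity; plain
  # anaphor sentences (annotated nowhere, related to nothing) are anchors
  # too so that the spacing rules see the indirect mention they will create
  cross_of <- lapply(seq_len(n_ent), function(e) which(kinds == "cross" & ent_of == e))
  n_plain_ana <- stats::rbinom(1, 2, config$p_anaphora)
  anchors <- c(
    lapply(which(subkind %in% c("habitat", "geo", "partof")),
           function(i) list(type = subkind[i], e = ent_of[i])),
    lapply(which(vapply(cross_of, length, integer(1)) > 0),
           function(e) list(type = "cross", e = e, n = length(cross_of[[e]]))),
    lapply(which(kinds == "ana"), function(i) list(type = "ana")),
    rep(list(list(type = "ana_plain")), n_plain_ana)
  )
  anchors <- anchors[sample(length(anchors))]

  for (a in anchors) {
    if (a$type == "ana_plain") {
      if (is.na(last_entity)) next
      e <- last_entity
      pad_until(gap_ok(e, TRUE, TRUE))
      si <- emit(assemble_sentence(list(
        pt("This species was first described over a century ago."))))
      last_B[e] <- si        # the indirect mention acts as a bacterium here
      next
    }
    if (a$type == "ana") {
      if (is.na(last_entity)) next     # needs an antecedent bacterium
      e <- last_entity
      pad_until(gap_ok(e, TRUE, TRUE))
      h <- take("hab_pool")
      head_ <- sample(c("This organism", "This bacterium", "This species"), 1)
      verb <- sample(c(" has also been isolated from ", " is regularly found in "), 1)
      si <- emit(assemble_sentence(list(pt(paste0(head_, verb)),
                                        pm(h, "Habitat"), pt("."))))
      add_rel("Localization", first_row[e], n_men(), "ana")
      last_B[e] <- si; last_H[e] <- si
      next
    }
    e <- a$e
    pad_until(gap_ok(e, TRUE, TRUE))
    if (a$type == "habitat") {
      n_h <- sample(1:2, 1)
      hs <- take("hab_pool", n_h)
      verb <- sample(c(" is commonly found in ", " thrives in ",
                      " has been isolated from "), 1)
      parts <- list(pm(ents$full[e], "Bacteria", as.character(e)), pt(verb),
                    pm(hs[1], "Habitat"))
      if (n_h == 2) parts <- c(parts, list(pt(" and "), pm(hs[2], "Habitat")))
      parts <- c(parts, list(pt(".")))
      si <- emit(assemble_sentence(parts))
      b_row <- n_men() - n_h
      for (k in seq_len(n_h))
        add_rel("Localization", b_row, b_row + k, "direct")
      last_H[e] <- si
    } else if (a$type == "geo") {
      g <- take("geo_pool")
      verb <- sample(c(" was first isolated in ", " has been reported from "), 1)
      si <- emit(assemble_sentence(list(pm(ents$full[e], "Bacteria", as.character(e)),
                                        pt(verb), pm(g, "Geographical"), pt("."))))
      add_rel("Localization", n_men() - 1L, n_men(), "direct")
      last_H[e] <- si
    } else if (a$type == "partof") {
      p <- take("part_pool"); h <- take("host_pool")
      outer <- paste(p, "of", h)
      si <- emit(assemble_sentence(list(
        pm(ents$full[e], "Bacteria", as.character(e)),
        pt(" colonizes the "),
        pm(outer, "Habitat",
           inner = list(offset = nchar(p) + 4L, len = nchar(h),
                        etype = "Habitat")),
        pt("."))))
      b_row <- n_men() - 2L; outer_row <- n_men() - 1L; inner_row <- n_men()
      add_rel("Localization", b_row, outer_row, "direct")
      add_rel("Localization", b_row, inner_row, "direct")
      add_rel("PartOf", inner_row, outer_row, "direct")
      last_H[e] <- si
    } else if (a$type == "cross") {
      n_h <- min(a$n, length(hab_pool))
      hs <- take("hab_pool", n_h)
      form <- if (stats::runif(1) < config$p_abbrev) ents$abbrev[e]
              else paste(ents$full[e], ents$code[e])
      verb <- sample(c(" is also found in ", " has been recovered from "), 1)
      parts <- list(pm(form, "Bacteria", as.character(e)), pt(verb),
                    pm(hs[1], "Habitat"))
      if (n_h > 1) for (k in 2:n_h)
        parts <- c(parts, list(pt(" and "), pm(hs[k], "Habitat")))
      parts <- c(parts, list(pt(".")))
      si <- emit(assemble_sentence(parts))
      b_row <- n_men() - n_h
      for (k in seq_len(n_h))
        add_rel("Localization", first_row[e], b_row + k, "cross")
      last_H[e] <- si
    }
  }
  # a little trailing material so documents do not end abruptly
  for (k in seq_len(sample(1:2, 1))) emit(filler_sentence())

  # paragraphs: title alone, then chunks of 3-5 sentences
  body <- if (length(sents) > 1) 2:length(sents) else integer()
  paras <- list(1L)
  while (length(body) > 0) {
    n <- min(length(body), sample(3:5, 1))
    paras <- c(paras, list(body[seq_len(n)]))
    body <- body[-seq_len(n)]
  }

  text <- ""
  sent_abs <- integer(length(sents))
  for (p in seq_along(paras)) {
    if (p > 1) text <- paste0(text, "\n\n")
    for (j in seq_along(paras[[p]])) {
      if (j > 1) text <- paste0(text, " ")
      si <- paras[[p]][j]
      sent_abs[si] <- nchar(text)
      text <- paste0(text, sents[si])
    }
  }

  mentions <- do.call(rbind, lapply(seq_along(men), function(i) {
    m <- men[[i]]
    st <- sent_abs[m$sentence] + m$start
    en <- sent_abs[m$sentence] + m$end
    data.frame(id = paste0("T", i), etype = m$etype, start = st, end = en,
               frag_spec = paste(st, en), text = span_text(text, st, en),
               indirect = FALSE, stringsAsFactors = FALSE)
  }))
  relations <- do.call(rbind, lapply(seq_along(rels), function(i) {
    r <- rels[[i]]
    data.frame(id = paste0("R", i), rtype = r$rtype,
               arg1 = paste0("T", r$a1), arg2 = paste0("T", r$a2),
               stringsAsFactors = FALSE)
  })) %||% empty_relations()

  ent_ids <- vapply(men, function(m) m$entity %||% NA_character_, character(1))
  equiv <- list()
  for (e in seq_len(n_ent)) {
    ids <- paste0("T", which(!is.na(ent_ids) & ent_ids == as.character(e)))
    if (length(ids) >= 2) equiv <- c(equiv, list(ids))
  }

  doc <- bb_document(doc_id, text, mentions = mentions,
                     relations = relations, equiv_groups = equiv)
  attr(doc, "synth_stats") <- stats_rows
  doc
}

# --- resources -------------------------------------------------------------

#' Generate the feature resources for a synthetic corpus
#'
#' Writes a mini OBO ontology containing every habitat vocabulary term plus
#' decoys, a flat taxon name list with the bacteria names and their
#' strain-suffixed variants plus decoys, a word-cluster path file assigning
#' consistent bit-string paths by word class, and per-document Cocoa
#' standoff files over the gold mentions with a configurable fraction of
#' wrong categories.
#'
#' @param config A [synth_config()].
#' @param docs List of generated [bb_document()]s.
#' @param vocab Internal vocabulary bundle (attribute of the corpus).
#' @param out_dir Corpus directory.
#' @return Invisibly, the paths written.
#' @export
generate_resources <- function(config, docs, vocab, out_dir) {
  obo_path <- file.path(out_dir, "ontology.obo")
  terms <- c(vocab$habitats, vocab$parts, vocab$hosts,
             OBO_DECOYS[seq_len(min(config$n_decoys, length(OBO_DECOYS)))])
  lines <- c("format-version: 1.2", "")
  for (i in seq_along(terms)) {
    lines <- c(lines, "[Term]", sprintf("id: SBT:%07d", i),
               paste0("name: ", terms[i]))
    if (!grepl(" ", terms[i]))
      lines <- c(lines, sprintf('synonym: "%ss" RELATED []', terms[i]))
    lines <- c(lines, "")
  }
  writeLines(lines, obo_path)

  taxa_path <- file.path(out_dir, "taxa.txt")
  writeLines(c(vocab$bacteria$full,
               paste(vocab$bacteria$full, vocab$bacteria$code),
               vocab$taxa_decoys), taxa_path)

  cluster_path <- file.path(out_dir, "clusters.tsv")
  classes <- list(
    c("000", tolower(vocab$bacteria$genus)),
    c("001", unique(vocab$bacteria$epithet)),
    c("010", unique(unlist(strsplit(tolower(c(vocab$habitats, vocab$parts,
                                              vocab$hosts)), " ")))),
    c("011", tolower(vocab$geos)),
    c("100", c("found", "isolated", "recovered", "reported", "colonizes",
               "thrives", "described", "occurs")),
    c("101", c("the", "a", "in", "of", "from", "and", "is", "was", "has",
               "been", "near", "beyond", "throughout")))
  cl_lines <- character()
  for (cls in classes) {
    words <- cls[-1]
    for (k in seq_along(words))
      cl_lines <- c(cl_lines, sprintf("%s%s\t%s\t%d", cls[1],
                                      paste(rev(as.integer(intToBits(k))[1:5]),
                                            collapse = ""),
                                      words[k], 2L))
  }
  writeLines(cl_lines, cluster_path)

  cocoa_dir <- file.path(out_dir, "cocoa")
  dir.create(cocoa_dir, showWarnings = FALSE, recursive = TRUE)
  cat_of <- c(Bacteria = "Organism", Habitat = "Habitat",
              Geographical = "Location")
  for (doc in docs) {
    men <- doc$mentions
    cats <- cat_of[men$etype]
    flip <- stats::runif(nrow(men)) < config$cocoa_noise
    cats[flip] <- vapply(cats[flip], function(cc)
      sample(setdiff(COCOA_CATS, cc), 1), character(1))
    writeLines(sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(men)), cats,
                       men$start, men$end, men$text),
               file.path(cocoa_dir, paste0(doc$doc_id, ".ann")))
  }
  invisible(c(obo_path, taxa_path, cluster_path, cocoa_dir))
}

#' Generate a synthetic annotated corpus
#'
#' Writes, under `out_dir`, one `.txt`/`.a1`/`.a2` triple per document plus
#' the feature resources (`ontology.obo`, `taxa.txt`, `clusters.tsv`,
#' `cocoa/*.ann`). Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of generated [bb_document()]s with a
#'   `synth_stats` attribute (relation-event counts per expression mode).
#' @export
generate_corpus <- function(config = synth_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  docs <- with_seed(config$seed, {
    vocab <- synth_vocab(config)
    ds <- lapply(seq_len(config$n_docs), function(i)
      gen_document(sprintf("SYN-%03d", i), config, vocab))
    generate_resources(config, ds, vocab, out_dir)
    ds
  })
  for (doc in docs) write_annotations(doc, out_dir, write_text = TRUE)
  stats <- do.call(rbind, lapply(docs, attr, "synth_stats"))
  attr(docs, "synth_stats") <- colSums(stats)
  invisible(docs)
}

#' Read a corpus directory
#'
#' Loads every `<id>.txt` with its `.a1`/`.a2` annotations, segments the
#' documents, and loads whichever feature resources are present.
#'
#' @param dir Corpus directory as written by [generate_corpus()].
#' @param tagger POS tagger passed to [segment_document()].
#' @return List with `docs` (segmented [bb_document()]s) and `resources`.
#' @export
read_corpus <- function(dir, tagger = bb_pos_tagger) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  txts <- txts[file.exists(sub("\\.txt$", ".a1", txts))]   # resource files are not documents
  docs <- lapply(txts, function(tp) {
    base <- sub("\\.txt$", "", tp)
    segment_document(read_document(tp, paste0(base, c(".a1", ".a2"))),
                     tagger = tagger)
  })
  has <- function(f) if (file.exists(file.path(dir, f))) file.path(dir, f)
  resources <- load_resources(
    obo = has("ontology.obo"), taxa = has("taxa.txt"),
    clusters = has("clusters.tsv"),
    cocoa_dir = if (dir.exists(file.path(dir, "cocoa"))) file.path(dir, "cocoa"))
  list(docs = docs, resources = resources)
}
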