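## Supervised relation detection between typed entity mentions.
##
## Candidate relation instances are mention pairs respecting the relation
## signatures (PartOf: Habitat -> Habitat; Localization: Bacteria ->
## Geographical or Bacteria -> Habitat) whose sentence distance is at most
## s. Positive examples are the gold relation instances closed under the
## co-reference equivalence classes; an equal number of negatives is
## sampled from the remaining candidates (balanced training). A binary
## logistic (maximum-entropy) classifier with entity-type features covers
## all signatures at once; the relation type is a deterministic function of
## the argument types. After inference, relation instances whose argument
## is an indirect (anaphora-created) mention are rewritten onto that
## mention's chain representative.

RELATION_SIGNATURES <- data.frame(
  rtype = c("PartOf", "Localization", "Localization"),
  t1 = c("Habitat", "Bacteria", "Bacteria"),
  t2 = c("Habitat", "Geographical", "Habitat"),
  stringsAsFactors = FALSE)

signature_rtype <- function(t1, t2) {
  ifelse(t1 == "Habitat" & t2 == "Habitat", "PartOf",
         ifelse(t1 == "Bacteria" & t2 %in% c("Habitat", "Geographical"),
                "Localization", NA_character_))
}

#' Relation detector configuration
#'
#' @param s_train,s_decode Maximum sentence distance between the two
#'   mentions of a candidate at training / decoding time (defaults 3, the
#'   decode optimum; 0 means same sentence, 1 adjoining sentences, ...).
#' @param context_size Number of context positions on each side of each
#'   mention from which word/POS features are taken (default 1; larger
#'   contexts showed no improvement).
#' @param feature_sets Subset of `c("base", "pos", "cocoa", "context")`.
#' @param negative_seed Seed for the balanced negative sample.
#' @param decision_threshold Positive-probability threshold (default 0.5;
#'   ties break toward negative).
#' @param l1 L1 regularization strength (per-observation lasso penalty) of
#'   the logistic model.
#' @param union_gold Also union gold Equiv groups into the equivalence
#'   classes used for training augmentation (default `FALSE`:
#'   predicted-chains only).
#' @return A list of class `bb_relation_config`.
#' @export
relation_config <- function(s_train = 3L, s_decode = 3L, context_size = 1L,
                            feature_sets = c("base", "pos", "cocoa", "context"),
                            negative_seed = 1L, decision_threshold = 0.5,
                            l1 = 1e-3, union_gold = FALSE) {
  stopifnot(s_train >= 0, s_decode >= 0, context_size >= 0)
  structure(list(s_train = as.integer(s_train), s_decode = as.integer(s_decode),
                 context_size = as.integer(context_size),
                 feature_sets = feature_sets,
                 negative_seed = as.integer(negative_seed),
                 decision_threshold = decision_threshold, l1 = l1,
                 union_gold = union_gold),
            class = "bb_relation_config")
}

#' Generate signature-respecting relation candidates
#'
#' Every ordered mention pair matching a relation signature whose sentence
#' distance is at most `s`. For Habitat-Habitat pairs both orderings are
#' generated (argument orientation is learned, not assumed).
#'
#' @param mentions Mentions data frame with a `sentence` column (see
#'   [assign_sentences()]).
#' @param s Maximum sentence distance.
#' @param include_indirect Include anaphora-created indirect mentions as
#'   arguments (used at decode time).
#' @return Data frame with columns `m1`, `m2`, `rtype`, `dist`.
#' @export
generate_candidates <- function(mentions, s, include_indirect = FALSE) {
  men <- mentions
  if (!include_indirect) men <- men[!men$indirect, , drop = FALSE]
  out <- data.frame(m1 = character(), m2 = character(), rtype = character(),
                    dist = integer(), stringsAsFactors = FALSE)
  if (nrow(men) < 2) return(out)
  idx <- expand.grid(i = seq_len(nrow(men)), j = seq_len(nrow(men)))
  idx <- idx[idx$i != idx$j, , drop = FALSE]
  rt <- signature_rtype(men$etype[idx$i], men$etype[idx$j])
  dist <- abs(men$sentence[idx$i] - men$sentence[idx$j])
  keep <- !is.na(rt) & dist <= s
  data.frame(m1 = men$id[idx$i][keep], m2 = men$id[idx$j][keep],
             rtype = rt[keep], dist = as.integer(dist[keep]),
             stringsAsFactors = FALSE)
}

# Map mention id -> equivalence class id under chains (and optionally gold
# Equiv groups); unlinked mentions are their own class.
equivalence_classes <- function(mention_ids, chains = list(), gold_groups = list()) {
  uf <- uf_new(mention_ids)
  add <- function(members) {
    members <- members[members %in% mention_ids]
    if (length(members) >= 2)
      for (k in 2:length(members)) uf_union(uf, members[1], members[k])
  }
  for (ch in chains) add(ch$members)
  for (g in gold_groups) add(g)
  stats::setNames(vapply(mention_ids, function(m) uf_find(uf, m), character(1)),
                  mention_ids)
}

#' Label candidates using gold relations closed under equivalence
#'
#' A candidate (m1, m2) is positive iff some gold relation of the same type
#' holds between a mention equivalent to m1 and a mention equivalent to m2,
#' where equivalence means same predicted chain or (optionally) same gold
#' Equiv group. All other candidates are negative-eligible.
#'
#' @param cands Candidates from [generate_candidates()].
#' @param doc The gold [bb_document()] (for relations and Equiv groups).
#' @param chains Chains from [resolve_coreference()].
#' @param union_gold Union the document's gold Equiv groups into the
#'   equivalence classes.
#' @return Candidates with a logical `positive` column.
#' @export
label_candidates <- function(cands, doc, chains = list(), union_gold = FALSE) {
  men <- doc$mentions
  cls <- equivalence_classes(
    unique(c(men$id, cands$m1, cands$m2)), chains,
    if (union_gold) doc$equiv_groups else list())
  rel <- doc$relations
  if (nrow(rel) > 0) {
    t1 <- men$etype[match(rel$arg1, men$id)]
    t2 <- men$etype[match(rel$arg2, men$id)]
    ok <- !is.na(signature_rtype(t1, t2)) & signature_rtype(t1, t2) == rel$rtype
    if (any(!ok))
      warning("ignoring ", sum(!ok), " gold relation(s) violating signatures in ",
              doc$doc_id, call. = FALSE)
    rel <- rel[ok, , drop = FALSE]
  }
  gold_keys <- unique(paste(rel$rtype, cls[rel$arg1], cls[rel$arg2]))
  cands$positive <- paste(cands$rtype, cls[cands$m1], cls[cands$m2]) %in% gold_keys
  cands
}

#' Sample a balanced example set
#'
#' Keeps all positive candidates and a uniform without-replacement sample of
#' negatives of the same size (all negatives if fewer are available).
#' Reproducible given the seed.
#'
#' @param labeled Labeled candidates (rows from [label_candidates()],
#'   possibly concatenated over documents).
#' @param seed RNG seed for the negative sample.
#' @return List with `positives` and `negatives` data frames.
#' @export
sample_negatives <- function(labeled, seed = 1L) {
  pos <- labeled[labeled$positive, , drop = FALSE]
  neg_pool <- labeled[!labeled$positive, , drop = FALSE]
  if (nrow(pos) == 0) stop("no positive examples; cannot build a training set")
  n_neg <- min(nrow(pos), nrow(neg_pool))
  neg <- with_seed(seed, neg_pool[sample(nrow(neg_pool), n_neg), , drop = FALSE])
  list(positives = pos, negatives = neg)
}

mention_token_idx <- function(doc, start, end) {
  which(doc$tokens$end > start & doc$tokens$start < end)
}

# Feature strings for one candidate; `men` indexed by id.
candidate_features <- function(doc, men, m1, m2, dist, config) {
  fs <- config$feature_sets
  n <- config$context_size
  co <- if ("cocoa" %in% fs) attr(doc, "cocoa_ann") else NULL
  f <- character()
  for (slot in 1:2) {
    id <- if (slot == 1) m1 else m2
    row <- match(id, men$id)
    ti <- mention_token_idx(doc, men$start[row], men$end[row])
    words <- tolower(doc$tokens$text[ti])
    tags <- doc$tokens$pos[ti]
    p <- paste0("m", slot)
    f <- c(f, paste0(p, "t=", men$etype[row]))
    if ("base" %in% fs)
      f <- c(f, paste0(p, "seq=", paste(words, collapse = "_")),
             paste0(p, "bag=", unique(words)))
    if ("pos" %in% fs)
      f <- c(f, paste0(p, "pseq=", paste(tags, collapse = "_")),
             paste0(p, "pbag=", unique(tags)))
    if ("context" %in% fs && n > 0 && length(ti) > 0) {
      ntok <- nrow(doc$tokens)
      sent <- doc$tokens$sentence_index
      for (o in seq_len(n)) {
        li <- min(ti) - o; ri <- max(ti) + o
        lv <- if (li >= 1 && sent[li] == sent[min(ti)])
          c(tolower(doc$tokens$text[li]), doc$tokens$pos[li]) else
          c(BIO_SENTINEL, BIO_SENTINEL)
        rv <- if (ri <= ntok && sent[ri] == sent[max(ti)])
          c(tolower(doc$tokens$text[ri]), doc$tokens$pos[ri]) else
          c(BIO_SENTINEL, BIO_SENTINEL)
        f <- c(f, paste0(p, "l", o, "w=", lv[1]), paste0(p, "l", o, "p=", lv[2]),
               paste0(p, "r", o, "w=", rv[1]), paste0(p, "r", o, "p=", rv[2]))
      }
    }
    if (!is.null(co) && nrow(co) > 0) {
      cats <- co$category[co$start < men$end[row] & co$end > men$start[row]]
      if (length(cats) > 0) f <- c(f, paste0(p, "co=", unique(cats)))
    }
  }
  f <- c(f, paste0("tt=", men$etype[match(m1, men$id)], "_",
                   men$etype[match(m2, men$id)]),
         paste0("db=", min(dist, 3L)), paste0("d=", dist))
  f
}

#' Extract features for relation candidates
#'
#' Base features: the words within each mention as a sequence and as a bag,
#' the entity types (individually and as a pair), and the sentence distance
#' (raw and bucketed at 0/1/2/3+). POS features repeat the word features
#' with tags. Cocoa features are the categories covering each mention.
#' Context features take words and tags from `context_size` positions on
#' each side of each mention.
#'
#' @param cands Candidate data frame.
#' @param doc A segmented [bb_document()].
#' @param mentions Mentions data frame covering all candidate arguments.
#' @param resources A [load_resources()] bundle (for Cocoa).
#' @param config A [relation_config()].
#' @return List of character feature vectors, one per candidate.
#' @export
extract_relation_features <- function(cands, doc, mentions, resources = NULL,
                                      config = relation_config()) {
  if ("cocoa" %in% config$feature_sets && !is.null(resources))
    attr(doc, "cocoa_ann") <- cocoa_for_doc(resources, doc$doc_id)
  lapply(seq_len(nrow(cands)), function(k) {
    candidate_features(doc, mentions, cands$m1[k], cands$m2[k],
                       cands$dist[k], config)
  })
}

#' Train the relation detection model
#'
#' Binary L1-regularized logistic regression (maximum-entropy classifier)
#' over the balanced example set; the relation type at decode time is
#' determined by the argument-type signature.
#'
#' @param examples List with `features` (list of character vectors) and
#'   `label` (logical vector), as assembled by the pipeline.
#' @param config A [relation_config()].
#' @return A `bb_relation_model`.
#' @export
train_relation_model <- function(examples, config = relation_config()) {
  y <- examples$label
  if (length(unique(y)) < 2)
    stop("degenerate training set: only one class present")
  counts <- table(unlist(examples$features))
  dict <- names(counts)
  x <- features_to_sparse(examples$features, dict)
  lam <- config$l1
  fit <- glmnet::glmnet(x, factor(y), family = "binomial", alpha = 1,
                        lambda = exp(seq(log(1), log(lam), length.out = 50)),
                        standardize = FALSE, thresh = 1e-7, maxit = 2e5)
  cf <- as.matrix(stats::coef(fit, s = lam))
  structure(list(dict = dict, w = cf[-1, 1], b = cf[1, 1], config = config),
            class = "bb_relation_model")
}

#' @export
print.bb_relation_model <- function(x, ...) {
  cat(sprintf("<bb_relation_model: %d features, %d non-zero weights>\n",
              length(x$dict), sum(x$w != 0)))
  invisible(x)
}

predict_relation_prob <- function(model, features) {
  x <- features_to_sparse(features, model$dict)
  as.numeric(stats::plogis(as.numeric(x %*% model$w) + model$b))
}

#' Predict relation instances for a document
#'
#' Generates candidates at `s_decode` (including indirect mentions),
#' classifies them, keeps those whose positive probability exceeds the
#' decision threshold, replaces any indirect argument by its co-reference
#' chain representative, drops relation instances still referencing an
#' indirect mention, and merges duplicates.
#'
#' @param doc A segmented [bb_document()].
#' @param mentions Mentions data frame (direct + indirect).
#' @param chains Chains from [resolve_coreference()].
#' @param model A `bb_relation_model`.
#' @param resources A [load_resources()] bundle.
#' @return A relations data frame (columns `id`, `rtype`, `arg1`, `arg2`).
#' @export
predict_relations <- function(doc, mentions, chains, model, resources = NULL) {
  config <- model$config
  mentions <- assign_sentences(doc, mentions)
  cands <- generate_candidates(mentions, config$s_decode,
                               include_indirect = TRUE)
  if (nrow(cands) == 0) return(empty_relations())
  feats <- extract_relation_features(cands, doc, mentions, resources, config)
  prob <- predict_relation_prob(model, feats)
  kept <- cands[prob > config$decision_threshold, , drop = FALSE]
  if (nrow(kept) == 0) return(empty_relations())

  rep_of <- stats::setNames(mentions$id, mentions$id)
  for (ch in chains) for (m in ch$members) rep_of[m] <- ch$representative
  indirect_ids <- mentions$id[mentions$indirect]
  kept$m1 <- ifelse(kept$m1 %in% indirect_ids, rep_of[kept$m1], kept$m1)
  kept$m2 <- ifelse(kept$m2 %in% indirect_ids, rep_of[kept$m2], kept$m2)
  kept <- kept[!(kept$m1 %in% indirect_ids) & !(kept$m2 %in% indirect_ids), ,
               drop = FALSE]
  kept <- kept[kept$m1 != kept$m2, , drop = FALSE]
  kept <- kept[!duplicated(kept[, c("rtype", "m1", "m2")]), , drop = FALSE]
  if (nrow(kept) == 0) return(empty_relations())
  data.frame(id = paste0("R", seq_len(nrow(kept))), rtype = kept$rtype,
             arg1 = kept$m1, arg2 = kept$m2, stringsAsFactors = FALSE)
}
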