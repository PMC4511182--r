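## Orchestration of the three stages in the two shared-task settings:
## gold entity mentions provided (task 2: co-reference -> relations) and
## end-to-end (task 3: mention detection -> co-reference -> relations).

strategy_vector <- function(strategy) {
  switch(strategy,
         none = character(0),
         sim = "similarity",
         ana = "anaphora",
         all = c("similarity", "anaphora"),
         stop("unknown co-reference strategy: ", strategy))
}

#' Train a relation model from gold documents
#'
#' Runs the configured co-reference strategy on every training document,
#' generates distance-filtered candidates (including anaphora-created
#' indirect mentions), labels them against the gold relations closed under
#' the predicted equivalence classes, samples balanced negatives, and fits
#' the logistic relation classifier.
#'
#' @param train_docs List of segmented gold [bb_document()]s.
#' @param resources A [load_resources()] bundle.
#' @param strategy One of `"none"`, `"sim"`, `"ana"`, `"all"`.
#' @param rel_config A [relation_config()].
#' @param coref_cfg A [coref_config()] (its `strategies` field is replaced
#'   by `strategy`).
#' @return List with `model` and `counts`.
#' @export
train_relation_pipeline <- function(train_docs, resources = NULL,
                                    strategy = "sim",
                                    rel_config = relation_config(),
                                    coref_cfg = coref_config()) {
  coref_cfg$strategies <- strategy_vector(strategy)
  feats <- list(); labs <- logical()
  counts <- c(mentions = 0L, links = 0L, chains = 0L, candidates = 0L,
              positives = 0L, negatives = 0L)
  pooled <- list()
  for (doc in train_docs) {
    res <- resolve_coreference(doc, config = coref_cfg)
    cands <- generate_candidates(res$mentions, rel_config$s_train,
                                 include_indirect = TRUE)
    lab <- label_candidates(cands, doc, res$chains,
                            union_gold = rel_config$union_gold)
    f <- extract_relation_features(lab, doc, res$mentions, resources,
                                   rel_config)
    pooled[[length(pooled) + 1L]] <- lab
    feats <- c(feats, f)
    counts["mentions"] <- counts["mentions"] + nrow(res$mentions)
    counts["links"] <- counts["links"] + nrow(res$links)
    counts["chains"] <- counts["chains"] + length(res$chains)
    counts["candidates"] <- counts["candidates"] + nrow(lab)
  }
  lab_all <- do.call(rbind, pooled)
  lab_all$idx <- seq_len(nrow(lab_all))
  es <- sample_negatives(lab_all, seed = rel_config$negative_seed)
  sel <- c(es$positives$idx, es$negatives$idx)
  counts["positives"] <- nrow(es$positives)
  counts["negatives"] <- nrow(es$negatives)
  model <- train_relation_model(
    list(features = feats[sel],
         label = c(rep(TRUE, nrow(es$positives)), rep(FALSE, nrow(es$negatives)))),
    rel_config)
  list(model = model, counts = counts)
}

predict_relation_docs <- function(docs, mentions_by_doc, resources, model,
                                  coref_cfg) {
  out <- vector("list", length(docs))
  for (k in seq_along(docs)) {
    doc <- docs[[k]]
    res <- resolve_coreference(doc, mentions = mentions_by_doc[[k]],
                               config = coref_cfg)
    rel <- predict_relations(doc, res$mentions, res$chains, model, resources)
    out[[k]] <- list(doc_id = doc$doc_id, relations = rel,
                     mentions = res$mentions)
  }
  out
}

#' Run the gold-mention setting (task 2)
#'
#' Trains the relation stage on the training documents, then resolves
#' co-reference and predicts relations on the evaluation documents using
#' their gold entity mentions, scoring with equivalence-aware relation
#' matching.
#'
#' @param train_docs,eval_docs Lists of segmented gold [bb_document()]s.
#' @param resources A [load_resources()] bundle.
#' @param strategy Co-reference strategy: `"none"`, `"sim"`, `"ana"`,
#'   `"all"`.
#' @param rel_config A [relation_config()].
#' @param coref_cfg A [coref_config()].
#' @return List with `score` (a [`bb_prf`][new_prf]), `predictions` and
#'   `manifest`.
#' @export
run_task2 <- function(train_docs, eval_docs, resources = NULL,
                      strategy = "sim", rel_config = relation_config(),
                      coref_cfg = coref_config()) {
  if (length(train_docs) == 0 || length(eval_docs) == 0)
    stop("empty corpus")
  if (any(vapply(train_docs, function(d) nrow(d$mentions) == 0, logical(1))) &&
      all(vapply(train_docs, function(d) nrow(d$mentions), integer(1)) == 0))
    stop("gold mentions are required for task 2")
  trained <- train_relation_pipeline(train_docs, resources, strategy,
                                     rel_config, coref_cfg)
  coref_cfg$strategies <- strategy_vector(strategy)
  preds <- predict_relation_docs(eval_docs,
                                 lapply(eval_docs, `[[`, "mentions"),
                                 resources, trained$model, coref_cfg)
  score <- score_relations_equiv(eval_docs, preds)
  manifest <- list(task = "task2", strategy = strategy,
                   rel_config = rel_config, coref_cfg = coref_cfg,
                   n_train = length(train_docs), n_eval = length(eval_docs),
                   counts = c(trained$counts,
                              relations_predicted = sum(vapply(
                                preds, function(p) nrow(p$relations), integer(1)))),
                   score = unclass(score))
  list(score = score, predictions = preds, manifest = manifest,
       model = trained$model)
}

#' Run the end-to-end setting (task 3)
#'
#' Trains (or reuses) a mention detection model on the training documents,
#' predicts mentions on the evaluation documents, then resolves
#' co-reference and predicts relations over the predicted mentions. The
#' relation stage is trained on gold mentions exactly as in task 2.
#'
#' @inheritParams run_task2
#' @param mention_cfg A [mention_config()].
#' @param mention_model Optional pre-trained `bb_mention_model`; trained
#'   from `train_docs` when `NULL`.
#' @return List with `score`, `mention_score`, `predictions` and
#'   `manifest`.
#' @export
run_task3 <- function(train_docs, eval_docs, resources = NULL,
                      strategy = "sim", rel_config = relation_config(),
                      coref_cfg = coref_config(),
                      mention_cfg = mention_config(),
                      mention_model = NULL) {
  if (length(train_docs) == 0 || length(eval_docs) == 0)
    stop("empty corpus")
  if (is.null(mention_model))
    mention_model <- train_mention_model(train_docs, resources, mention_cfg)
  trained <- train_relation_pipeline(train_docs, resources, strategy,
                                     rel_config, coref_cfg)
  coref_cfg$strategies <- strategy_vector(strategy)
  pred_mentions <- lapply(eval_docs, function(d)
    predict_mentions(d, mention_model, resources))
  preds <- predict_relation_docs(eval_docs, pred_mentions, resources,
                                 trained$model, coref_cfg)
  pred_docs <- mapply(function(d, m) { d$mentions <- m; d },
                      eval_docs, pred_mentions, SIMPLIFY = FALSE)
  mention_score <- score_mentions_chunk(eval_docs, pred_docs)
  score <- score_relations_equiv(eval_docs, preds)
  manifest <- list(task = "task3", strategy = strategy,
                   rel_config = rel_config, coref_cfg = coref_cfg,
                   mention_cfg = mention_cfg,
                   n_train = length(train_docs), n_eval = length(eval_docs),
                   counts = c(trained$counts,
                              mentions_predicted = sum(vapply(
                                pred_mentions, nrow, integer(1))),
                              relations_predicted = sum(vapply(
                                preds, function(p) nrow(p$relations), integer(1)))),
                   score = unclass(score),
                   mention_overall = unclass(mention_score$overall))
  list(score = score, mention_score = mention_score, predictions = preds,
       manifest = manifest, mention_model = mention_model,
       model = trained$model)
}

#' Split a corpus into training and evaluation documents
#'
#' @param docs List of documents.
#' @param train_fraction Fraction used for training (front slice; the
#'   generator already randomizes document content, so no shuffling is
#'   needed for a synthetic corpus).
#' @return List with `train` and `eval`.
#' @export
corpus_split <- function(docs, train_fraction = 0.7) {
  n_train <- max(1L, floor(length(docs) * train_fraction))
  n_train <- min(n_train, length(docs) - 1L)
  list(train = docs[seq_len(n_train)], eval = docs[-seq_len(n_train)])
}
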