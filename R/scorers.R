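## Intrinsic and extrinsic evaluation.
##
## * Mention identification: chunk-level micro precision/recall/F per type
##   and overall; a predicted mention is correct iff its type and exact span
##   match a gold mention.
## * Co-reference: MUC (link-based), B-cubed (mention-based) and CEAF
##   (optimal one-to-one entity alignment, mention- or entity-based
##   similarity). Following the CoNLL reference scorer semantics, singletons
##   participate in B-cubed and CEAF but carry no MUC links. Mentions are
##   matched across gold/system by exact span + type.
## * Relations: official-scorer-style matching where co-referring mentions
##   are conflated by the gold Equiv groups.

mention_key <- function(doc_id, mentions) {
  if (nrow(mentions) == 0) return(character(0))
  paste(doc_id, mentions$etype, mentions$frag_spec, sep = "|")
}

#' Chunk-level mention identification score
#'
#' @param gold_docs,pred_docs Named-compatible lists of [bb_document()]s in
#'   the same order (matched by `doc_id`); predictions read from each
#'   document's `mentions`.
#' @return List of [`bb_prf`][new_prf] objects: one per entity type plus
#'   `overall` (micro-averaged).
#' @export
score_mentions_chunk <- function(gold_docs, pred_docs) {
  gids <- vapply(gold_docs, `[[`, character(1), "doc_id")
  pids <- vapply(pred_docs, `[[`, character(1), "doc_id")
  if (!setequal(gids, pids)) stop("gold and predicted document ids differ")
  pred_docs <- pred_docs[match(gids, pids)]
  gold_keys <- character(); pred_keys <- character()
  for (k in seq_along(gold_docs)) {
    g <- gold_docs[[k]]$mentions; p <- pred_docs[[k]]$mentions
    g <- g[!g$indirect, , drop = FALSE]; p <- p[!p$indirect, , drop = FALSE]
    gold_keys <- c(gold_keys, unique(mention_key(gids[k], g)))
    pred_keys <- c(pred_keys, unique(mention_key(gids[k], p)))
  }
  per_type <- function(keys, type) keys[grepl(paste0("\\|", type, "\\|"), keys)]
  out <- list()
  for (ty in ENTITY_TYPES) {
    g <- per_type(gold_keys, ty); p <- per_type(pred_keys, ty)
    out[[ty]] <- prf_from_counts(sum(p %in% g), length(p), length(g))
  }
  out$overall <- prf_from_counts(sum(pred_keys %in% gold_keys),
                                 length(pred_keys), length(gold_keys))
  out
}

#' Build a chain partition from documents
#'
#' Mentions are keyed by document, type and fragment spans. Mentions in an
#' Equiv group (or chain) form one entity; every remaining mention is a
#' singleton entity.
#'
#' @param docs List of [bb_document()]s.
#' @param chains_by_doc Optional list (parallel to `docs`) of chain lists
#'   from [resolve_coreference()]; when `NULL` the documents' gold Equiv
#'   groups are used.
#' @param keep_singletons Include non-co-referring mentions as singleton
#'   entities (default `TRUE`, the reference scorer behavior).
#' @return List of class `bb_partition`: per document, a list of character
#'   vectors of mention keys.
#' @export
chain_partition <- function(docs, chains_by_doc = NULL, keep_singletons = TRUE) {
  out <- list()
  for (k in seq_along(docs)) {
    doc <- docs[[k]]
    men <- doc$mentions
    keys <- stats::setNames(mention_key(doc$doc_id, men), men$id)
    groups <- if (is.null(chains_by_doc)) doc$equiv_groups
              else lapply(chains_by_doc[[k]], `[[`, "members")
    ents <- lapply(groups, function(g) unique(unname(keys[g[g %in% names(keys)]])))
    ents <- ents[lengths(ents) >= 2]
    if (keep_singletons) {
      used <- unlist(ents)
      singles <- setdiff(unique(unname(keys)), used)
      ents <- c(ents, as.list(singles))
    }
    out[[doc$doc_id]] <- ents
  }
  structure(out, class = "bb_partition")
}

#' MUC link-based co-reference score
#'
#' Recall is `sum(|g| - p(g)) / sum(|g| - 1)` over gold chains `g`, where
#' `p(g)` is the number of system entities (plus unaligned mentions)
#' intersecting `g`; precision is symmetric. Singleton entities carry no
#' links and do not contribute.
#'
#' @param gold,sys `bb_partition` objects over the same documents.
#' @return A [`bb_prf`][new_prf].
#' @export
score_muc <- function(gold, sys) {
  side <- function(a, b) {
    num <- 0; den <- 0
    for (d in names(a)) {
      bs <- b[[d]] %||% list()
      for (g in a[[d]]) {
        if (length(g) < 2) next
        hit <- unique(unlist(lapply(seq_along(bs), function(i)
          if (any(g %in% bs[[i]])) i else NULL)))
        p <- length(hit) + sum(!g %in% unlist(bs))
        num <- num + length(g) - p
        den <- den + length(g) - 1
      }
    }
    if (den > 0) num / den else 0
  }
  new_prf(recall = side(gold, sys), precision = side(sys, gold))
}

#' B-cubed co-reference score
#'
#' Per-mention precision/recall averaged over mentions: for each gold
#' mention `m` in gold entity `g` and system entity `s(m)`, recall credit is
#' `|g intersect s(m)| / |g|` (0 when the system lacks `m`); precision is
#' symmetric.
#'
#' @param gold,sys `bb_partition` objects over the same documents.
#' @return A [`bb_prf`][new_prf].
#' @export
score_bcubed <- function(gold, sys) {
  side <- function(a, b) {
    num <- 0; den <- 0
    for (d in names(a)) {
      bs <- b[[d]] %||% list()
      for (g in a[[d]]) {
        for (m in g) {
          den <- den + 1
          sm <- NULL
          for (s in bs) if (m %in% s) { sm <- s; break }
          if (!is.null(sm)) num <- num + length(intersect(g, sm)) / length(g)
        }
      }
    }
    if (den > 0) num / den else 0
  }
  new_prf(recall = side(gold, sys), precision = side(sys, gold))
}

# Exact maximum-weight one-to-one assignment via the O(n^3) Hungarian
# algorithm (shortest augmenting paths with potentials) on the negated
# score matrix, padded to square with zeros. Arrays carry a virtual column
# at index 1 (offset +1 throughout).
max_assignment_value <- function(phi) {
  n <- nrow(phi); m <- ncol(phi)
  if (n == 0 || m == 0) return(0)
  sz <- max(n, m)
  cost <- matrix(0, sz, sz)
  cost[seq_len(n), seq_len(m)] <- -phi
  u <- numeric(sz)
  v <- numeric(sz + 1)
  p <- integer(sz + 1)      # p[j + 1] = row assigned to column j
  way <- integer(sz + 1)
  for (i in seq_len(sz)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, sz + 1)
    used <- rep(FALSE, sz + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(sz)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:sz) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  total <- 0
  for (j in seq_len(sz)) {
    i <- p[j + 1L]
    if (i >= 1 && i <= n && j <= m) total <- total + phi[i, j]
  }
  total
}

ceaf_phi <- function(gold_ents, sys_ents, entity_based) {
  phi <- matrix(0, length(gold_ents), length(sys_ents))
  for (i in seq_along(gold_ents)) for (j in seq_along(sys_ents)) {
    inter <- length(intersect(gold_ents[[i]], sys_ents[[j]]))
    phi[i, j] <- if (entity_based)
      2 * inter / (length(gold_ents[[i]]) + length(sys_ents[[j]]))
    else inter
  }
  phi
}

score_ceaf <- function(gold, sys, entity_based) {
  num <- 0; den_r <- 0; den_p <- 0
  for (d in names(gold)) {
    ge <- gold[[d]]; se <- sys[[d]] %||% list()
    if (length(ge) > 0 && length(se) > 0)
      num <- num + max_assignment_value(ceaf_phi(ge, se, entity_based))
    if (entity_based) {
      den_r <- den_r + length(ge); den_p <- den_p + length(se)
    } else {
      den_r <- den_r + sum(lengths(ge)); den_p <- den_p + sum(lengths(se))
    }
  }
  new_prf(recall = if (den_r > 0) num / den_r else 0,
          precision = if (den_p > 0) num / den_p else 0)
}

#' CEAF co-reference scores
#'
#' Entities are aligned one-to-one so as to maximize total similarity,
#' computed exactly with the Hungarian algorithm. `score_ceaf_m` uses
#' mention-based similarity `phi(g, s) = |g intersect s|`; `score_ceaf_e`
#' uses entity-based similarity `phi(g, s) = 2 |g intersect s| / (|g| +
#' |s|)`.
#'
#' @param gold,sys `bb_partition` objects over the same documents.
#' @return A [`bb_prf`][new_prf].
#' @export
score_ceaf_m <- function(gold, sys) score_ceaf(gold, sys, entity_based = FALSE)

#' @rdname score_ceaf_m
#' @export
score_ceaf_e <- function(gold, sys) score_ceaf(gold, sys, entity_based = TRUE)

#' Score all four co-reference metrics
#'
#' @param gold,sys `bb_partition` objects over the same documents.
#' @return Named list of [`bb_prf`][new_prf]: `muc`, `bcube`, `ceafm`,
#'   `ceafe`.
#' @export
score_coreference <- function(gold, sys) {
  list(muc = score_muc(gold, sys), bcube = score_bcubed(gold, sys),
       ceafm = score_ceaf_m(gold, sys), ceafe = score_ceaf_e(gold, sys))
}

#' Equivalence-aware relation score
#'
#' A predicted relation instance matches a gold one iff the types are equal
#' and each predicted argument conflates with the corresponding gold
#' argument: same mention (exact span + type), or members of the same gold
#' Equiv group. Each gold relation is matched at most once; micro-averaged
#' P/R/F over all documents.
#'
#' @param gold_docs List of gold [bb_document()]s (mentions, relations,
#'   Equiv groups).
#' @param pred List (parallel to `gold_docs`) with per-document `relations`
#'   data frames and `mentions` data frames naming the predicted arguments.
#' @return A [`bb_prf`][new_prf] with attribute `counts`.
#' @export
score_relations_equiv <- function(gold_docs, pred) {
  tp <- 0; n_pred <- 0; n_gold <- 0
  for (k in seq_along(gold_docs)) {
    gdoc <- gold_docs[[k]]
    gmen <- gdoc$mentions
    gkeys <- stats::setNames(mention_key(gdoc$doc_id, gmen), gmen$id)
    cls <- equivalence_classes(gmen$id, gold_groups = gdoc$equiv_groups)
    key2cls <- stats::setNames(cls, unname(gkeys))

    prel <- pred[[k]]$relations
    pmen <- pred[[k]]$mentions
    pkeys <- stats::setNames(mention_key(gdoc$doc_id, pmen), pmen$id)
    n_gold <- n_gold + nrow(gdoc$relations)
    n_pred <- n_pred + nrow(prel)
    if (nrow(prel) == 0 || nrow(gdoc$relations) == 0) next

    gold_sig <- paste(gdoc$relations$rtype,
                      cls[gdoc$relations$arg1], cls[gdoc$relations$arg2])
    matched <- rep(FALSE, length(gold_sig))
    for (r in seq_len(nrow(prel))) {
      c1 <- key2cls[pkeys[prel$arg1[r]]]
      c2 <- key2cls[pkeys[prel$arg2[r]]]
      if (is.na(c1) || is.na(c2)) next
      sig <- paste(prel$rtype[r], c1, c2)
      hit <- which(!matched & gold_sig == sig)
      if (length(hit) > 0) { matched[hit[1]] <- TRUE; tp <- tp + 1 }
    }
  }
  out <- prf_from_counts(tp, n_pred, n_gold)
  attr(out, "counts") <- c(tp = tp, predicted = n_pred, gold = n_gold)
  out
}
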