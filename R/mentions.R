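## Typed entity mention detection as BIO sequence labeling.
##
## Tokens are labeled with {B,I} x {Bacteria, Habitat, Geographical} or O by
## an L1-regularized multinomial log-linear model (glmnet) over surface
## features (token, case shape, digits, punctuation, length) and lexicon
## features (OntoBiotope-style ontology, taxon list, Brown-cluster path,
## Cocoa categories), each replicated over a neighbor window, plus a
## previous-label feature block that is decoded with Viterbi so the model is
## a linear chain. Automatic feature selection happens through the L1
## penalty. A post-processing rule re-injects nested mentions: strings
## observed nested inside larger gold mentions at training time are added
## as additional mentions wherever they occur inside a predicted mention.

BIO_SENTINEL <- "<S>"

#' Mention detector configuration
#'
#' @param window Neighbor window half-width for feature replication
#'   (default 2).
#' @param l1 L1 regularization strength: the per-observation lasso penalty
#'   of the log-linear model (default 0.001, mild feature selection).
#' @param min_count Features seen fewer than this many times in training are
#'   dropped (default 2).
#' @param feature_sets Subset of `c("base", "obo", "taxa", "clusters",
#'   "cocoa")`; `base` is the surface feature set.
#' @return A list of class `bb_mention_config`.
#' @export
mention_config <- function(window = 2L, l1 = 1e-3, min_count = 2L,
                           feature_sets = c("base", "obo", "taxa",
                                            "clusters", "cocoa")) {
  structure(list(window = as.integer(window), l1 = l1,
                 min_count = as.integer(min_count),
                 feature_sets = feature_sets),
            class = "bb_mention_config")
}

token_case_shape <- function(words) {
  out <- rep("mixed", length(words))
  out[grepl("^[a-z]+$", words)] <- "lower"
  out[grepl("^[A-Z][a-z]*$", words)] <- "initcap"
  out[grepl("^[A-Z]+$", words) & nchar(words) > 1] <- "allcaps"
  out[grepl("^[0-9]+$", words)] <- "digits"
  out[grepl("^[^A-Za-z0-9]+$", words)] <- "punct"
  out
}

#' Extract per-token classifier features
#'
#' Computes, for every token of a segmented document, surface features
#' (lowercased token, case shape, has-digit, has-punctuation, bucketed
#' length), lexicon membership features (token occurs in an ontology term /
#' in a taxon name), the Brown-cluster path, and Cocoa categories covering
#' the token. Single-valued features are replicated at offsets
#' `-window ... +window` within the sentence (out-of-sentence slots get a
#' boundary sentinel).
#'
#' @param doc A segmented [bb_document()].
#' @param resources A [load_resources()] bundle (may be `NULL`).
#' @param config A [mention_config()].
#' @return List (one element per token) of character feature strings.
#' @export
extract_token_features <- function(doc, resources = NULL,
                                   config = mention_config()) {
  tok <- doc$tokens
  n <- nrow(tok)
  if (n == 0) return(list())
  fs <- config$feature_sets
  base <- list()
  if ("base" %in% fs) {
    base$w <- tolower(tok$text)
    base$sh <- token_case_shape(tok$text)
    base$dg <- as.character(grepl("[0-9]", tok$text))
    base$pc <- as.character(grepl("[^A-Za-z0-9]", tok$text))
    base$ln <- as.character(pmin(nchar(tok$text), 10L))
  }
  if ("obo" %in% fs && !is.null(resources$obo))
    base$ob <- as.character(lex_has_token(resources$obo, tok$text))
  if ("taxa" %in% fs && !is.null(resources$taxa))
    base$tx <- as.character(lex_has_token(resources$taxa, tok$text))
  if ("clusters" %in% fs && !is.null(resources$clusters))
    base$cl <- cluster_path(resources$clusters, tok$text)

  sent <- tok$sentence_index
  offsets <- -config$window:config$window
  cols <- vector("list", length(base) * length(offsets))
  k <- 0L
  for (nm in names(base)) {
    v <- base[[nm]]
    for (o in offsets) {
      k <- k + 1L
      idx <- seq_len(n) + o
      ok <- idx >= 1L & idx <= n
      val <- rep(BIO_SENTINEL, n)
      val[ok] <- v[idx[ok]]
      val[ok][sent[idx[ok]] != sent[ok]] <- BIO_SENTINEL
      cols[[k]] <- paste0(nm, "[", o, "]=", val)
    }
  }
  mat <- do.call(cbind, cols)
  feats <- lapply(seq_len(n), function(i) mat[i, ])

  if ("cocoa" %in% fs && !is.null(resources) && !is.null(resources$cocoa_dir)) {
    co <- cocoa_for_doc(resources, doc$doc_id)
    if (nrow(co) > 0) {
      for (r in seq_len(nrow(co))) {
        hit <- which(tok$start >= co$start[r] & tok$start < co$end[r])
        for (i in hit) feats[[i]] <- c(feats[[i]], paste0("co=", co$category[r]))
      }
    }
  }
  feats
}

# Outermost direct mentions, deduplicated by span; used for BIO encoding.
outermost_mentions <- function(mentions) {
  men <- mentions[!mentions$indirect, , drop = FALSE]
  if (nrow(men) == 0) return(men)
  men <- men[!duplicated(men[, c("start", "end")]), , drop = FALSE]
  inner <- vapply(seq_len(nrow(men)), function(i) {
    any(men$start <= men$start[i] & men$end >= men$end[i] &
          (men$start < men$start[i] | men$end > men$end[i]))
  }, logical(1))
  men[!inner, , drop = FALSE]
}

# Strictly nested (inner) direct mentions; feed the nested-mention lexicon.
nested_inner_mentions <- function(mentions) {
  men <- mentions[!mentions$indirect, , drop = FALSE]
  if (nrow(men) == 0) return(men)
  inner <- vapply(seq_len(nrow(men)), function(i) {
    any(men$start <= men$start[i] & men$end >= men$end[i] &
          (men$start < men$start[i] | men$end > men$end[i]))
  }, logical(1))
  men[inner, , drop = FALSE]
}

#' BIO-encode gold mentions onto tokens
#'
#' Nested gold mentions are flattened to the outermost span (a linear-chain
#' labeler cannot emit overlapping chunks; inner mentions feed the
#' nested-mention lexicon instead). Mentions whose boundaries do not fall on
#' token boundaries are snapped outward with a warning.
#'
#' @param doc A segmented [bb_document()].
#' @return Character vector of labels, one per token.
#' @export
encode_bio <- function(doc) {
  tok <- doc$tokens
  labels <- rep("O", nrow(tok))
  men <- outermost_mentions(doc$mentions)
  if (nrow(men) == 0) return(labels)
  for (i in seq_len(nrow(men))) {
    cover <- which(tok$end > men$start[i] & tok$start < men$end[i])
    if (length(cover) == 0) {
      warning("mention ", men$id[i], " does not align to any token; skipped",
              call. = FALSE)
      next
    }
    if (tok$start[cover[1]] != men$start[i] ||
        tok$end[cover[length(cover)]] != men$end[i])
      warning("mention ", men$id[i], " snapped outward to token boundaries",
              call. = FALSE)
    labels[cover] <- paste0("I-", men$etype[i])
    labels[cover[1]] <- paste0("B-", men$etype[i])
  }
  labels
}

#' Decode BIO labels into mention spans
#'
#' Illegal transitions are repaired at decode: `I-X` after `O`, after a
#' different type, or at a sentence start is treated as `B-X`.
#'
#' @param tokens Token data frame of a segmented document.
#' @param labels Character vector of BIO labels.
#' @param text Document text (for surfaces).
#' @param id_prefix Prefix for generated mention ids.
#' @return A mentions data frame.
#' @export
decode_bio <- function(tokens, labels, text, id_prefix = "M") {
  men <- empty_mentions()
  open_type <- NULL; open_start <- NULL; open_end <- NULL
  flush <- function() {
    if (is.null(open_type)) return()
    men <<- rbind(men, data.frame(
      id = paste0(id_prefix, nrow(men) + 1L), etype = open_type,
      start = open_start, end = open_end,
      frag_spec = paste(open_start, open_end),
      text = span_text(text, open_start, open_end),
      indirect = FALSE, stringsAsFactors = FALSE))
  }
  prev_sent <- -1L
  for (i in seq_along(labels)) {
    lab <- labels[i]
    new_sent <- tokens$sentence_index[i] != prev_sent
    prev_sent <- tokens$sentence_index[i]
    if (lab == "O") { flush(); open_type <- NULL; next }
    typ <- sub("^[BI]-", "", lab)
    if (startsWith(lab, "B-") || is.null(open_type) || open_type != typ ||
        new_sent) {
      flush()
      open_type <- typ; open_start <- tokens$start[i]; open_end <- tokens$end[i]
    } else {
      open_end <- tokens$end[i]
    }
  }
  flush()
  men
}

#' Build the nested-mention lexicon from gold documents
#'
#' Records the surface string and type of every gold mention that lies
#' strictly inside a larger gold mention of the same document.
#'
#' @param docs List of gold [bb_document()]s.
#' @return Data frame with columns `etype`, `text` (lowercased), unique.
#' @export
build_nested_lexicon <- function(docs) {
  rows <- lapply(docs, function(d) {
    inner <- nested_inner_mentions(d$mentions)
    if (nrow(inner) == 0) return(NULL)
    data.frame(etype = inner$etype, text = tolower(inner$text),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(etype = character(), text = character(),
                      stringsAsFactors = FALSE))
  unique(out)
}

prev_label_features <- function(labels, sentence_index) {
  prev <- c(BIO_SENTINEL, labels[-length(labels)])
  first <- c(TRUE, sentence_index[-1] != sentence_index[-length(sentence_index)])
  prev[first] <- BIO_SENTINEL
  paste0("PL=", prev)
}

features_to_sparse <- function(feats, dict) {
  idx <- lapply(feats, function(f) unique(match(f, dict)))
  idx <- lapply(idx, function(v) v[!is.na(v)])
  lens <- lengths(idx)
  Matrix::sparseMatrix(i = rep(seq_along(feats), lens), j = unlist(idx),
                       x = 1, dims = c(length(feats), length(dict)))
}

#' Train the mention detection model
#'
#' Fits an L1-regularized multinomial log-linear model over BIO labels with
#' gold previous-label features (decoded as a linear chain with Viterbi at
#' prediction time) and builds the nested-mention lexicon from the training
#' documents. Deterministic given the documents and configuration.
#'
#' @param docs List of segmented gold [bb_document()]s.
#' @param resources A [load_resources()] bundle.
#' @param config A [mention_config()].
#' @return A `bb_mention_model`.
#' @export
train_mention_model <- function(docs, resources = NULL,
                                config = mention_config()) {
  feats <- list(); labels <- character()
  for (d in docs) {
    if (is.null(d$tokens)) stop("documents must be segmented")
    f <- extract_token_features(d, resources, config)
    l <- encode_bio(d)
    pl <- prev_label_features(l, d$tokens$sentence_index)
    feats <- c(feats, mapply(c, f, pl, SIMPLIFY = FALSE))
    labels <- c(labels, l)
  }
  if (!any(labels != "O")) stop("no training mention in any document")

  counts <- table(unlist(feats))
  dict <- names(counts)[counts >= config$min_count | startsWith(names(counts), "PL=")]
  x <- features_to_sparse(feats, dict)
  y <- factor(labels)
  # fine geometric path down to the target penalty: glmnet's coordinate
  # descent needs closely spaced warm starts on these sparse indicators
  lam <- config$l1
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 1,
                        lambda = exp(seq(log(1), log(lam), length.out = 50)),
                        standardize = FALSE, thresh = 1e-6, maxit = 3e5)
  K <- length(levels(y))
  W <- matrix(0, length(dict), K, dimnames = list(dict, levels(y)))
  b <- numeric(K)
  for (k in seq_len(K)) {
    cf <- as.matrix(stats::coef(fit, s = lam)[[k]])
    b[k] <- cf[1, 1]
    W[, k] <- cf[-1, 1]
  }
  is_pl <- startsWith(dict, "PL=")
  trans <- W[is_pl, , drop = FALSE]
  rownames(trans) <- sub("^PL=", "", dict[is_pl])
  structure(list(dict = dict[!is_pl], W = W[!is_pl, , drop = FALSE],
                 intercept = b, trans = trans, labels = levels(y),
                 nested = build_nested_lexicon(docs), config = config),
            class = "bb_mention_model")
}

#' @export
print.bb_mention_model <- function(x, ...) {
  cat(sprintf("<bb_mention_model: %d features, labels {%s}, %d nested strings>\n",
              length(x$dict), paste(x$labels, collapse = ", "), nrow(x$nested)))
  invisible(x)
}

viterbi_labels <- function(scores, trans, labels, sentence_index) {
  n <- nrow(scores); K <- ncol(scores)
  out <- character(n)
  trans_row <- function(prev) {
    if (prev %in% rownames(trans)) trans[prev, ] else numeric(K)
  }
  bos <- trans_row(BIO_SENTINEL)
  starts <- which(c(TRUE, sentence_index[-1] != sentence_index[-n]))
  ends <- c(starts[-1] - 1L, n)
  for (s in seq_along(starts)) {
    rng <- starts[s]:ends[s]
    m <- length(rng)
    dp <- matrix(-Inf, m, K); bp <- matrix(0L, m, K)
    dp[1, ] <- scores[rng[1], ] + bos
    if (m > 1) for (t in 2:m) {
      for (k in seq_len(K)) {
        cand <- dp[t - 1, ] + vapply(labels, function(p) trans_row(p)[k],
                                     numeric(1))
        bp[t, k] <- which.max(cand)
        dp[t, k] <- cand[bp[t, k]] + scores[rng[t], k]
      }
    }
    path <- integer(m)
    path[m] <- which.max(dp[m, ])
    if (m > 1) for (t in (m - 1):1) path[t] <- bp[t + 1, path[t + 1]]
    out[rng] <- labels[path]
  }
  out
}

#' Predict entity mentions
#'
#' Scores tokens with the trained model, decodes the best label sequence
#' with Viterbi, repairs any remaining illegal BIO transitions, then applies
#' the nested-mention rule: every token-boundary-aligned occurrence of a
#' nested-lexicon string (any type, matched case-insensitively) strictly
#' inside a predicted mention is added as an additional mention. The output
#' is therefore always a superset of the raw decode.
#'
#' @param doc A segmented [bb_document()].
#' @param model A `bb_mention_model`.
#' @param resources A [load_resources()] bundle (same resources as
#'   training).
#' @param nested Nested-mention lexicon; defaults to the model's.
#' @return A mentions data frame.
#' @export
predict_mentions <- function(doc, model, resources = NULL,
                             nested = model$nested) {
  if (nrow(doc$tokens) == 0) return(empty_mentions())
  feats <- extract_token_features(doc, resources, model$config)
  x <- features_to_sparse(feats, model$dict)
  scores <- as.matrix(x %*% model$W)
  scores <- sweep(scores, 2, model$intercept, `+`)
  labels <- viterbi_labels(scores, model$trans, model$labels,
                           doc$tokens$sentence_index)
  men <- decode_bio(doc$tokens, labels, doc$text)
  men <- inject_nested(men, doc, nested)
  assign_sentences(doc, men)
}

# Append nested-lexicon occurrences found strictly inside predicted spans.
inject_nested <- function(men, doc, nested) {
  if (nrow(men) == 0 || is.null(nested) || nrow(nested) == 0) return(men)
  tok <- doc$tokens
  extra <- list()
  for (i in seq_len(nrow(men))) {
    surface <- tolower(span_text(doc$text, men$start[i], men$end[i]))
    for (r in seq_len(nrow(nested))) {
      pat <- nested$text[r]
      if (nchar(pat) >= nchar(surface)) next
      hits <- gregexpr(pat, surface, fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      for (h in hits) {
        st <- men$start[i] + h - 1L
        en <- st + nchar(pat)
        if (st == men$start[i] && en == men$end[i]) next   # not strictly inside
        if (!any(tok$start == st) || !any(tok$end == en)) next
        extra <- c(extra, list(data.frame(
          id = NA_character_, etype = nested$etype[r], start = st, end = en,
          frag_spec = paste(st, en), text = span_text(doc$text, st, en),
          indirect = FALSE, stringsAsFactors = FALSE)))
      }
    }
  }
  if (length(extra) > 0) {
    men <- rbind(men, do.call(rbind, extra))
    men <- men[!duplicated(men[, c("etype", "start", "end")]), , drop = FALSE]
    men <- men[order(men$start, men$end), , drop = FALSE]
    men$id <- paste0("M", seq_len(nrow(men)))
  }
  men
}
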