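# Key-feature extraction from semi-structured medical text.
#
# The pipeline: look up character word-vectors, run M segmentation
# classifiers that each emit a per-character probability column over the
# BMES labels, fuse the columns with classifier weights WS, decode BMES
# labels into words, derive per-word feature vectors, run N entity taggers
# emitting per-word probability columns over the seven categories CL1-CL7,
# fuse with tagger weights WT, and extract structured key data with named
# regular expressions. Ensemble weights are fitted by minimizing
# Loss = Loss1 + Loss2, the mean fused probability mass missed on the gold
# labels.

#' Build a word-vector dictionary
#'
#' A Z x d dictionary mapping characters (or tokens) to d-dimensional real
#' vectors, with an out-of-vocabulary fallback vector. A seeded random
#' dictionary fulfils the lookup contract; a trained clinical dictionary can
#' be supplied in the same shape.
#'
#' @param tokens character vector of vocabulary entries (size Z)
#' @param d embedding dimension
#' @param seed integer seed for the random vectors
#' @param vectors optional Z x d numeric matrix to use instead of random
#'   vectors (rows aligned to `tokens`)
#' @return object of class `word_vector_dictionary`
#' @export
word_vector_dictionary <- function(tokens, d = 8, seed = 1, vectors = NULL) {
  tokens <- as.character(tokens)
  Z <- length(tokens)
  if (is.null(vectors)) {
    set.seed(seed)
    vectors <- matrix(stats::rnorm(Z * d), nrow = Z, ncol = d)
  }
  stopifnot(is.matrix(vectors), nrow(vectors) == Z, ncol(vectors) == d)
  rownames(vectors) <- tokens
  structure(list(vectors = vectors, fallback = rep(0, d), Z = Z, d = d),
            class = "word_vector_dictionary")
}

#' Embed a character sequence as a P x d matrix
#'
#' Row p is the dictionary vector of the p-th character; out-of-vocabulary
#' characters receive the fallback vector.
#'
#' @param text character vector of single characters/tokens, or a single
#'   string (split into characters)
#' @param dict a [word_vector_dictionary()]
#' @return P x d numeric matrix
#' @export
embed_sentence <- function(text, dict) {
  chars <- as_chars(text)
  if (!length(chars)) stop("text must be non-empty")
  out <- matrix(dict$fallback, nrow = length(chars), ncol = dict$d, byrow = TRUE)
  hit <- chars %in% rownames(dict$vectors)
  if (any(hit)) out[hit, ] <- dict$vectors[chars[hit], , drop = FALSE]
  rownames(out) <- chars
  out
}

as_chars <- function(text) {
  if (length(text) == 1 && nchar(text) > 1) strsplit(text, "")[[1]] else as.character(text)
}

# shared weighted-fusion step: probs = list of (k x m) column-stochastic
# matrices, one per unit; returns list(fused = k x P matrix, labels)
fuse_prob_columns <- function(probs, weights, row_labels) {
  m <- length(weights)
  if (all(weights == 0)) stop("all ensemble weights are zero")
  k <- length(row_labels)
  fused <- vapply(probs, function(h) {
    stopifnot(is.matrix(h), nrow(h) == k, ncol(h) == m)
    v <- as.vector(h %*% weights)   # weight columns, sum across rows
    v / sum(v)                      # column normalization
  }, numeric(k))
  fused <- matrix(fused, nrow = k)
  rownames(fused) <- row_labels
  labels <- row_labels[apply(fused, 2, which.max)]  # ties: lowest row index
  list(fused = fused, labels = labels)
}

#' Fuse multi-classifier BMES segmentation probabilities
#'
#' Each character carries a 4 x M matrix h(p): rows are the BMES labels,
#' columns are per-classifier probability distributions. Each column is
#' multiplied by its classifier weight WS(i), rows are summed and the
#' resulting 4-vector is normalized to sum 1; the label is the row of the
#' largest element, ties broken by fixed row order B < M < E < S.
#'
#' @param probs list of 4 x M matrices, one per character
#' @param WS numeric classifier weights, each in [0, 1], not all zero
#' @return list with `labels` (BMES character vector) and `fused`
#'   (4 x P matrix of fused probability vectors h(c(p)))
#' @export
fuse_segmentation <- function(probs, WS) {
  res <- fuse_prob_columns(probs, WS, BMES_LABELS)
  list(labels = res$labels, fused = res$fused)
}

#' Fuse multi-tagger entity-category probabilities
#'
#' Same multiply-by-weight, row-sum, column-normalize, argmax procedure as
#' [fuse_segmentation()], over the 7 entity categories and N taggers; ties
#' broken by fixed row order CL1 < ... < CL7.
#'
#' @param probs list of 7 x N matrices, one per word
#' @param WT numeric tagger weights, each in [0, 1], not all zero
#' @return list with `labels` (CL category per word) and `fused` (7 x Q matrix)
#' @export
fuse_entity_tags <- function(probs, WT) {
  res <- fuse_prob_columns(probs, WT, ENTITY_CATEGORIES)
  list(labels = res$labels, fused = res$fused)
}

#' Decode a BMES label sequence into words
#'
#' B...E runs and S singletons become words. Malformed runs (an M or E with
#' no open word, a B followed by B or S) are repaired by treating the first
#' character of an unopened run as B and closing a word at each E, S, or new
#' B; the concatenation of the decoded words always reproduces the input
#' text exactly.
#'
#' @param labels character vector over B, M, E, S
#' @param text character vector of the same length
#' @return list with `words` (character vector) and `word_index` (integer
#'   vector mapping each character to its word)
#' @export
decode_words <- function(labels, text) {
  chars <- as_chars(text)
  if (length(labels) != length(chars))
    stop(sprintf("labels (%d) and text (%d) must have the same length",
                 length(labels), length(chars)))
  stopifnot(all(labels %in% BMES_LABELS))
  n <- length(chars)
  word_index <- integer(n)
  w <- 0L; open <- FALSE
  for (p in seq_len(n)) {
    lab <- labels[p]
    if (lab == "S") {
      w <- w + 1L; word_index[p] <- w; open <- FALSE
    } else if (lab == "B") {
      w <- w + 1L; word_index[p] <- w; open <- TRUE
    } else { # M or E: continue the open word, or repair by opening one
      if (!open) w <- w + 1L
      word_index[p] <- w
      open <- lab != "E"
    }
  }
  words <- vapply(split(chars, word_index), paste, character(1), collapse = "")
  names(words) <- NULL
  list(words = words, word_index = word_index)
}

#' Per-word feature vectors from fused character vectors
#'
#' For each word, the fused 4-vectors h(c(p)) of its characters are summed
#' row-wise and normalized to sum 1, yielding the word's feature vector wq.
#'
#' @param fused 4 x P matrix of fused character vectors
#' @param word_index integer vector mapping characters to words
#' @return 4 x Q matrix, one column wq per word, each summing to 1
#' @export
word_feature_vectors <- function(fused, word_index) {
  stopifnot(ncol(fused) == length(word_index))
  if (!length(word_index)) stop("empty word")
  qs <- sort(unique(word_index))
  out <- vapply(qs, function(q) {
    v <- rowSums(fused[, word_index == q, drop = FALSE])
    v / sum(v)
  }, numeric(nrow(fused)))
  matrix(out, nrow = nrow(fused), dimnames = list(rownames(fused), NULL))
}

#' Segmentation loss of fused output against gold BMES labels
#'
#' Loss1 = (1/P) * sum_p (1 - h_true(c(p))), the mean fused probability mass
#' missed on the gold label; in [0, 1], and 0 iff the fused distribution
#' puts probability 1 on every gold label.
#'
#' @param fused 4 x P matrix of fused character vectors (rows B, M, E, S)
#' @param gold character vector of gold BMES labels, length P
#' @return Loss1, a number in [0, 1]
#' @export
segmentation_loss <- function(fused, gold) {
  label_loss(fused, gold, BMES_LABELS)
}

#' Entity-category loss of fused output against gold labels
#'
#' Loss2 = (1/Q) * sum_q (1 - e_true(w(q))); in [0, 1]. The total ensemble
#' loss is Loss = Loss1 + Loss2 (see [total_loss()]).
#'
#' @param fused 7 x Q matrix of fused word vectors (rows CL1..CL7)
#' @param gold character vector of gold categories, length Q
#' @return Loss2, a number in [0, 1]
#' @export
entity_loss <- function(fused, gold) {
  label_loss(fused, gold, ENTITY_CATEGORIES)
}

label_loss <- function(fused, gold, row_labels) {
  if (ncol(fused) != length(gold))
    stop(sprintf("fused has %d columns but gold has length %d", ncol(fused), length(gold)))
  if (!length(gold)) stop("gold sequence must be non-empty")
  stopifnot(all(gold %in% row_labels))
  idx <- match(gold, row_labels)
  ptrue <- fused[cbind(idx, seq_along(gold))]
  mean(1 - ptrue)
}

#' Total ensemble loss
#'
#' Loss = Loss1 + Loss2, in [0, 2].
#' @param loss1,loss2 the segmentation and entity losses
#' @export
total_loss <- function(loss1, loss2) loss1 + loss2

# Evaluate the total loss of an ensemble-weight pair on a labeled corpus.
# corpus: list of documents, each with $seg_probs (list of 4xM matrices),
# $gold_bmes, $ent_probs (list of 7xN matrices), $gold_entities (per word).
corpus_loss <- function(corpus, WS, WT) {
  seg_probs <- do.call(c, lapply(corpus, `[[`, "seg_probs"))
  gold_bmes <- do.call(c, lapply(corpus, `[[`, "gold_bmes"))
  ent_probs <- do.call(c, lapply(corpus, `[[`, "ent_probs"))
  gold_ents <- do.call(c, lapply(corpus, `[[`, "gold_entities"))
  l1 <- segmentation_loss(fuse_segmentation(seg_probs, WS)$fused, gold_bmes)
  l2 <- entity_loss(fuse_entity_tags(ent_probs, WT)$fused, gold_ents)
  c(loss1 = l1, loss2 = l2, loss = l1 + l2)
}

#' Fit ensemble weights by total-loss minimization
#'
#' Minimizes Loss = Loss1 + Loss2 over the classifier weights WS and tagger
#' weights WT by coordinate-wise bounded scalar minimization: each weight in
#' turn is optimized on [0, 1] with [stats::optimize()] in round-robin
#' passes, stopping when a full pass improves Loss by less than `tol` or
#' after `max_passes` passes. Because fusion normalizes, the loss is
#' invariant to scaling all weights of an ensemble by a positive constant;
#' the fitted weights are reported rescaled so the largest weight is 1.
#'
#' @param corpus list of labeled documents; each element has `seg_probs`
#'   (list of 4 x M matrices), `gold_bmes`, `ent_probs` (list of 7 x N
#'   matrices), `gold_entities` (see [gen_emr_corpus()])
#' @param WS,WT initial weights (defaults: all 1)
#' @param tol convergence tolerance on the total loss (default 1e-6)
#' @param max_passes maximum round-robin passes (default 50)
#' @return list with `WS`, `WT`, `trace` (total loss after each pass,
#'   non-increasing) and `loss` (final per-component losses)
#' @export
fit_ensemble_weights <- function(corpus, WS = NULL, WT = NULL,
                                 tol = 1e-6, max_passes = 50) {
  if (!length(corpus)) stop("corpus must be non-empty")
  M <- ncol(corpus[[1]]$seg_probs[[1]])
  N <- ncol(corpus[[1]]$ent_probs[[1]])
  if (is.null(WS)) WS <- rep(1, M)
  if (is.null(WT)) WT <- rep(1, N)
  stopifnot(length(WS) == M, length(WT) == N)
  cur <- corpus_loss(corpus, WS, WT)
  trace <- unname(cur["loss"])
  for (pass in seq_len(max_passes)) {
    prev <- cur["loss"]
    for (i in seq_len(M)) {
      f <- function(v) {
        w <- WS; w[i] <- v
        if (all(w == 0)) return(2)  # infeasible: worst possible loss
        corpus_loss(corpus, w, WT)["loss"]
      }
      opt <- stats::optimize(f, c(0, 1))
      if (opt$objective < cur["loss"]) { WS[i] <- opt$minimum; cur <- corpus_loss(corpus, WS, WT) }
    }
    for (j in seq_len(N)) {
      f <- function(v) {
        w <- WT; w[j] <- v
        if (all(w == 0)) return(2)
        corpus_loss(corpus, WS, w)["loss"]
      }
      opt <- stats::optimize(f, c(0, 1))
      if (opt$objective < cur["loss"]) { WT[j] <- opt$minimum; cur <- corpus_loss(corpus, WS, WT) }
    }
    trace <- c(trace, unname(cur["loss"]))
    if (prev - cur["loss"] < tol) break
  }
  # scale-invariant canonical form: max weight 1 per ensemble
  if (max(WS) > 0) WS <- WS / max(WS)
  if (max(WT) > 0) WT <- WT / max(WT)
  list(WS = WS, WT = WT, trace = trace, loss = corpus_loss(corpus, WS, WT))
}

#' Extract key data with named regular expressions
#'
#' Each pattern names a clinical index (e.g. fasting blood glucose) and must
#' contain a capture group for the numeric value; all non-overlapping
#' matches are returned in text order with the values parsed as numbers.
#'
#' @param text a single string
#' @param patterns named character vector or list of regular expressions;
#'   names are the index names and each regex captures one numeric group
#' @return data.frame with columns `index`, `value`, `start` (match offset),
#'   ordered by position in the text
#' @export
extract_key_data <- function(text, patterns) {
  stopifnot(length(text) == 1)
  if (!length(patterns)) return(data.frame(index = character(0), value = numeric(0),
                                           start = integer(0)))
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
    stop("configuration error: every pattern must be named with its index")
  rows <- list()
  for (nm in names(patterns)) {
    pat <- patterns[[nm]]
    if (!grepl("\\([^?]", pat) && !grepl("\\($", pat))
      stop(sprintf("configuration error: pattern '%s' has no capture group", nm))
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- attr(m, "capture.start")
    lens <- attr(m, "capture.length")
    if (is.null(starts))
      stop(sprintf("configuration error: pattern '%s' has no capture group", nm))
    for (k in seq_along(m)) {
      cap <- substr(text, starts[k, 1], starts[k, 1] + lens[k, 1] - 1)
      val <- suppressWarnings(as.numeric(cap))
      if (is.na(val)) next
      rows[[length(rows) + 1]] <- data.frame(index = nm, value = val,
                                             start = as.integer(m[k]),
                                             stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(index = character(0), value = numeric(0),
                                       start = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a key-feature record for one patient
#'
#' Merges regex-extracted key data with entity-tagged key text under a
#' single patient ID. Duplicate index names keep the last occurrence (a
#' warning is raised).
#'
#' @param key_data data.frame with `index`, `value` columns (see
#'   [extract_key_data()])
#' @param key_text data.frame with `span` (text), `category` (CL1..CL7)
#' @param patient_id the shared patient identifier
#' @param data_patient_id,text_patient_id optional IDs attached to the two
#'   inputs; if supplied they must equal `patient_id`
#' @return list of class `key_feature_record` with `patient_id`, `key_data`
#'   (named numeric vector) and `key_text` (data.frame)
#' @export
assemble_key_features <- function(key_data, key_text, patient_id,
                                  data_patient_id = NULL, text_patient_id = NULL) {
  for (pid in list(data_patient_id, text_patient_id)) {
    if (!is.null(pid) && !identical(pid, patient_id))
      stop(sprintf("patient ID mismatch: '%s' vs '%s'", pid, patient_id))
  }
  kd <- numeric(0)
  if (!is.null(key_data) && nrow(key_data)) {
    if (anyDuplicated(key_data$index)) {
      dups <- unique(key_data$index[duplicated(key_data$index)])
      warning("duplicate key-data index (last occurrence kept): ",
              paste(dups, collapse = ", "))
    }
    kd <- stats::setNames(key_data$value, key_data$index)
    kd <- kd[!duplicated(names(kd), fromLast = TRUE)]
    kd <- kd[unique(key_data$index)]
    if (any(!is.finite(kd))) stop("key-data values must be finite")
  }
  kt <- if (is.null(key_text) || !nrow(key_text)) {
    data.frame(span = character(0), category = character(0))
  } else {
    stopifnot(all(key_text$category %in% ENTITY_CATEGORIES))
    key_text
  }
  structure(list(patient_id = patient_id, key_data = kd, key_text = kt),
            class = "key_feature_record")
}
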