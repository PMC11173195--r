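#' Extract flattened sentence features from a language-model backend
#'
#' A backend is any function `(sentence, layer)` returning a numeric
#' `tokens x width` matrix of per-token hidden states for the requested
#' layer. Each sentence's states are flattened token-major and
#' right-padded with zeros to `max_tokens * width` elements (defaults
#' 21 x 768 = 16128). Extraction is pure: the same sentences and backend
#' always give the same matrix. A real transformer can be plugged in as a
#' backend; the shipped [stub_lm_backend()] is deterministic and needs no
#' model download.
#'
#' @param sentences character vector (UTF-8).
#' @param backend backend function; see Details.
#' @param layer layer index to request (default 8).
#' @param max_tokens maximum token count (default 21); a sentence whose
#'   backend states exceed it is refused with the token count.
#' @param width hidden-state width (default 768).
#' @return numeric matrix `length(sentences) x (max_tokens*width)` with
#'   attributes `token_counts`, `max_tokens`, `width`, `padding`.
#' @export
extract_lm_features <- function(sentences, backend = stub_lm_backend(),
                                layer = 8L, max_tokens = 21L,
                                width = 768L) {
  stopifnot(max_tokens >= 1, width >= 1)
  n <- length(sentences)
  E <- matrix(0, n, max_tokens * width)
  token_counts <- integer(n)
  for (i in seq_len(n)) {
    states <- backend(sentences[i], layer)
    states <- as.matrix(states)
    if (ncol(states) != width)
      stop("backend returned width ", ncol(states), ", expected ", width)
    k <- nrow(states)
    if (k > max_tokens)
      stop(sprintf("sentence %d tokenizes to %d tokens (max %d)", i, k,
                   max_tokens))
    token_counts[i] <- k
    E[i, seq_len(k * width)] <- as.vector(t(states))
  }
  structure(E, token_counts = token_counts, max_tokens = max_tokens,
            width = width, padding = "zero_tail")
}

#' Deterministic stub language-model backend
#'
#' Emulates a transformer backend for tests and offline runs: tokenizes
#' on whitespace and derives each hidden state arithmetically from a hash
#' of the token, its position and the requested layer (no randomness, no
#' downloads).
#'
#' @param width hidden-state width (default 768).
#' @return a backend function `(sentence, layer) -> tokens x width`.
#' @export
stub_lm_backend <- function(width = 768L) {
  function(sentence, layer) {
    tokens <- strsplit(trimws(sentence), "\\s+")[[1]]
    if (!length(tokens)) tokens <- ""
    h <- vapply(tokens, function(tk)
      sum(utf8ToInt(tk) * seq_along(utf8ToInt(tk))) %% 9973, numeric(1))
    t(vapply(seq_along(tokens), function(i)
      sin(h[i] * 0.37 + layer * 1.7 + seq_len(width) * 0.61 + i * 2.3),
      numeric(width)))
  }
}

#' Constant-state stub backend
#'
#' Returns the same value for every hidden-state entry, with a fixed
#' token count per sentence; useful for verifying the padding contract.
#'
#' @param value state value (default 1).
#' @param n_tokens tokens per sentence (default 3).
#' @param width hidden-state width.
#' @return a backend function.
#' @export
constant_lm_backend <- function(value = 1, n_tokens = 3L, width = 768L) {
  function(sentence, layer) matrix(value, n_tokens, width)
}

#' Pair-holdout decoding of a binary dimension from embeddings
#'
#' One fold per (low-class item, high-class item) pair: the linear
#' classifier is trained on the remaining items and scores the held-out
#' pair; the AUC of each two-item fold is 1, 0.5 or 0 depending on
#' whether the high-class item outranks the low-class one. Returns the
#' mean over all `n_low x n_high` folds.
#'
#' @param embeddings items x features matrix.
#' @param labels binary labels (`"high"`/`"low"` or any two levels).
#' @param cost linear SVC margin penalty.
#' @return mean ROC AUC over folds.
#' @export
pair_holdout_decode <- function(embeddings, labels, cost = 1) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2 || min(table(labels)) < 2)
    stop("labels must contain two classes with at least 2 items each")
  positive <- lev[2]
  idx_lo <- which(labels == lev[1])
  idx_hi <- which(labels == lev[2])
  n <- length(labels)
  total <- 0; count <- 0
  for (a in idx_lo) for (b in idx_hi) {
    te <- c(a, b)
    tr <- setdiff(seq_len(n), te)
    std <- .standardize_pair(embeddings[tr, , drop = FALSE],
                             embeddings[te, , drop = FALSE])
    keep <- apply(std$train, 2, sd) > 1e-12
    ytr <- factor(labels[tr])
    fit <- e1071::svm(std$train[, keep, drop = FALSE], ytr,
                      kernel = "linear", cost = cost, scale = FALSE)
    dv <- .oriented_dv(fit, std$test[, keep, drop = FALSE],
                       std$train[, keep, drop = FALSE], ytr, positive)
    total <- total + roc_auc(dv, labels[te], positive = positive)
    count <- count + 1
  }
  total / count
}

#' Permutation p-value for the pair-holdout decoding score
#'
#' Shuffles the feature-label correspondence `n_perm` times, recomputes
#' the pair-holdout mean AUC for each shuffle, and returns
#' `p = (1 + #\{permuted AUC >= observed AUC\}) / (1 + n_perm)`.
#'
#' @inheritParams pair_holdout_decode
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return list with `p_value`, `observed_auc`, `null_auc` (vector).
#' @export
label_permutation_pvalue <- function(embeddings, labels, n_perm = 1000L,
                                     seed = 1L, cost = 1) {
  stopifnot(n_perm >= 1)
  observed <- pair_holdout_decode(embeddings, labels, cost = cost)
  null_auc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b)
      pair_holdout_decode(embeddings, sample(labels), cost = cost),
      numeric(1))
  })
  list(p_value = (1 + sum(null_auc >= observed)) / (1 + n_perm),
       observed_auc = observed, null_auc = null_auc)
}

#' Write / read an embedding matrix as TSV
#' @param embeddings matrix from [extract_lm_features()] or
#'   [simulate_embeddings()].
#' @param path `.tsv` path.
#' @return `path` (write) or the matrix (read).
#' @export
write_embeddings_tsv <- function(embeddings, path) {
  write.table(unclass(embeddings), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings_tsv
#' @export
read_embeddings_tsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}
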