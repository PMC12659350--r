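# Independent brute-force oracles used to check the package's metric and
# search implementations. These are deliberately naive (loops, textbook
# definitions) and share no code with the implementation paths they check.

# Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- m * p[ord][i:m] / (i:m)
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exhaustive threshold sweep for ROC/PR (larger score = more positive).
oracle_curves <- function(scores, truth) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- fp <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tp[i] <- sum(pred & truth)
    fp[i] <- sum(pred & !truth)
  }
  P <- sum(truth)
  N <- sum(!truth)
  roc <- data.frame(threshold = c(Inf, thr), x = c(0, fp / N), y = c(0, tp / P))
  pr <- data.frame(threshold = c(Inf, thr), x = c(0, tp / P),
    y = c(1, tp / (tp + fp)))
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(roc = roc, pr = pr, auroc = trap(roc$x, roc$y), aupr = trap(pr$x, pr$y))
}

# Exhaustive pairwise-distance nearest neighbours.
oracle_nn <- function(Q, R, k = 1L) {
  out <- NULL
  for (i in seq_len(nrow(Q))) {
    d <- numeric(nrow(R))
    for (j in seq_len(nrow(R))) d[j] <- sqrt(sum((Q[i, ] - R[j, ])^2))
    sel <- order(d)[seq_len(k)]
    out <- rbind(out, data.frame(query_id = rownames(Q)[i],
      neighbor_id = rownames(R)[sel], rank = seq_len(k), distance = d[sel],
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# Pair-counting confusion matrix.
oracle_confusion <- function(pred, truth, labels) {
  m <- matrix(0L, length(labels), length(labels),
    dimnames = list(truth = labels, predicted = labels))
  for (i in seq_along(pred)) m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  m
}

macro_f1 <- function(conf) {
  labels <- rownames(conf)
  mean(vapply(seq_along(labels), function(k) {
    tp <- conf[k, k]
    precision_recall_f1(tp, sum(conf[, k]) - tp, sum(conf[k, ]) - tp)[["f1"]]
  }, 1.0))
}

# Row subset of an embedding_set by id.
es_subset <- function(es, ids) {
  embedding_set(es$vectors[ids, , drop = FALSE], es$provenance)
}

# A deterministic mock embedder reading only positions 21..30 (1-based):
# the letter-frequency histogram of that window, dim 20.
window_mock_embedder <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  make_embedder(function(s) {
    as.numeric(table(factor(strsplit(substr(s, 21, 30), "")[[1]], levels = aa)))
  }, dim = 20L, name = "window-mock")
}
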