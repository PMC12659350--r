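#' Inverse-frequency class weights
#'
#' Loss weights for the family stage: the penalty for misclassifying a
#' family is the inverse of its training count, so rare families (for
#' CAZymes, notably the carbohydrate esterases) are not drowned out by the
#' heavily represented ones. Weights are normalized to mean 1 to keep loss
#' magnitudes comparable across ontologies.
#'
#' @param ontology a [family_ontology] with per-label counts >= 1.
#' @return named numeric vector `w` with `w_c` proportional to `1/n_c` and
#'   `mean(w) == 1`.
#' @export
class_weights <- function(ontology) {
  stopifnot(inherits(ontology, "family_ontology"))
  n <- ontology$counts
  if (any(n < 1L)) {
    stop("zero training count for label(s): ",
      paste(names(n)[n < 1L], collapse = ", "))
  }
  w <- 1 / n
  w / mean(w)
}

#' Weighted cross-entropy loss
#'
#' Per-sample loss is `-w[label] * log(p[label])`; predicted probabilities
#' of zero are clamped at `eps` rather than producing infinite loss. Batch
#' reduction `"mean"` is the weighted mean `sum(w_i * -log p_i) / sum(w_i)`
#' (so with uniform weights it equals the ordinary mean cross-entropy);
#' `"sum"` sums the per-sample losses; `"none"` returns them.
#'
#' @param prob numeric probability vector (length K, one sample) or
#'   n x K matrix.
#' @param label class index (1-based) or vector of indices.
#' @param weights length-K positive class weights (default uniform).
#' @param reduction `"none"` (default), `"mean"` or `"sum"`.
#' @param eps clamp for zero probabilities (default 1e-12).
#' @return numeric scalar (or vector for `"none"` on a matrix).
#' @export
weighted_cross_entropy <- function(prob, label, weights = NULL,
                                   reduction = c("none", "mean", "sum"),
                                   eps = 1e-12) {
  reduction <- match.arg(reduction)
  if (!is.matrix(prob)) prob <- matrix(prob, nrow = 1L)
  K <- ncol(prob)
  if (is.null(weights)) weights <- rep(1, K)
  if (length(weights) != K || any(weights <= 0)) {
    stop("weights must be ", K, " positive values")
  }
  label <- as.integer(label)
  if (any(label < 1L | label > K)) stop("label index out of range")
  if (nrow(prob) != length(label)) stop("one label per probability row required")
  if (any(abs(rowSums(prob) - 1) > 1e-6) || any(prob < -1e-9)) {
    stop("rows of prob must be probability vectors")
  }
  p <- prob[cbind(seq_along(label), label)]
  p <- pmax(p, eps)
  w <- weights[label]
  losses <- -w * log(p)
  switch(reduction,
    none = if (length(losses) == 1L) losses[[1L]] else losses,
    sum = sum(losses),
    mean = sum(losses) / sum(w)
  )
}

## ---- network internals (two hidden ReLU layers, softmax output, Adam) ----

mlp_init <- function(d, h1, h2, K, seed) {
  set.seed(seed)
  he <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  }
  params <- list(W1 = he(d, h1), b1 = rep(0, h1),
    W2 = he(h1, h2), b2 = rep(0, h2),
    W3 = he(h2, K), b3 = rep(0, K))
  list(params = params,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L, epoch = 0L, dims = c(input = d, h1 = h1, h2 = h2, K = K))
}

mlp_forward <- function(params, X) {
  Z1 <- sweep(X %*% params$W1, 2L, params$b1, "+")
  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% params$W2, 2L, params$b2, "+")
  A2 <- pmax(Z2, 0)
  Z3 <- sweep(A2 %*% params$W3, 2L, params$b3, "+")
  Z3 <- sweep(Z3, 1L, apply(Z3, 1L, max), "-")
  E <- exp(Z3)
  P <- E / rowSums(E)
  list(A1 = A1, A2 = A2, P = P)
}

mlp_gradients <- function(params, X, y, w) {
  n <- nrow(X)
  fw <- mlp_forward(params, X)
  wy <- w[y]
  # d(weighted mean CE)/dZ3 for softmax: (P - Y) scaled per sample
  dZ3 <- fw$P
  dZ3[cbind(seq_len(n), y)] <- dZ3[cbind(seq_len(n), y)] - 1
  dZ3 <- dZ3 * (wy / sum(wy))
  g <- list()
  g$W3 <- t(fw$A2) %*% dZ3
  g$b3 <- colSums(dZ3)
  dA2 <- dZ3 %*% t(params$W3)
  dZ2 <- dA2 * (fw$A2 > 0)
  g$W2 <- t(fw$A1) %*% dZ2
  g$b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(params$W2)
  dZ1 <- dA1 * (fw$A1 > 0)
  g$W1 <- t(X) %*% dZ1
  g$b1 <- colSums(dZ1)
  g[names(params)]
}

adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(state$params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    state$params[[nm]] <- state$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# Train for additional epochs; resumable and deterministic: the shuffle of
# epoch e is seeded from (seed_base, e) so a paused candidate continues
# exactly as if it had never stopped.
mlp_train_epochs <- function(state, X, y, w, lr, batch_size, n_epochs, seed_base) {
  n <- nrow(X)
  batch_size <- min(batch_size, n)
  for (e in seq_len(n_epochs)) {
    set.seed((seed_base + state$epoch) %% .Machine$integer.max)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      g <- mlp_gradients(state$params, X[idx, , drop = FALSE], y[idx], w)
      state <- adam_step(state, g, lr)
    }
    state$epoch <- state$epoch + 1L
  }
  state
}

mlp_evaluate <- function(params, X, y, w) {
  P <- mlp_forward(params, X)$P
  list(loss = weighted_cross_entropy(P, y, w, reduction = "mean"),
    accuracy = mean(max.col(P, ties.method = "first") == y))
}

align_labels <- function(es, labels, ontology) {
  ids <- embedding_ids(es)
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing)) stop("no label for id(s): ",
      paste(utils::head(missing, 5), collapse = ", "))
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels must be named by id or aligned with the embedding set")
  }
  idx <- match(labels, ontology$labels)
  if (anyNA(idx)) {
    stop("label(s) outside the ontology: ",
      paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Search specification for family-net tuning
#'
#' Declares the random-search space and successive-halving schedule: the
#' number of candidate configurations (default 20), the tuned
#' hyperparameters (hidden sizes, batch size, learning rate) with their
#' sampling ranges, the epoch budget (default 100), and the halving
#' schedule (grace period before the first rung, reduction factor between
#' rungs). Candidate sampling is reproducible from the training seed.
#'
#' @param n_candidates candidate configurations (default 20).
#' @param max_epochs full training budget per surviving candidate
#'   (default 100).
#' @param grace epochs before the first pruning rung (default 5).
#' @param reduction_factor fraction of candidates kept at each rung is
#'   `1/reduction_factor` (default 2).
#' @param h1_range,h2_range inclusive integer ranges for hidden sizes.
#' @param batch_range inclusive integer range for batch size.
#' @param lr_range learning-rate range, sampled log-uniformly.
#' @return an object of class `search_spec`.
#' @export
search_spec <- function(n_candidates = 20L, max_epochs = 100L, grace = 5L,
                        reduction_factor = 2, h1_range = c(128L, 1024L),
                        h2_range = c(128L, 1024L), batch_range = c(32L, 512L),
                        lr_range = c(1e-4, 1e-2)) {
  stopifnot(n_candidates >= 1L, max_epochs >= 1L, grace >= 1L,
    reduction_factor > 1, lr_range[1] > 0)
  structure(list(n_candidates = as.integer(n_candidates),
    max_epochs = as.integer(max_epochs), grace = as.integer(grace),
    reduction_factor = reduction_factor,
    h1_range = as.integer(h1_range), h2_range = as.integer(h2_range),
    batch_range = as.integer(batch_range), lr_range = lr_range),
    class = "search_spec")
}

sample_candidates <- function(spec, seed) {
  set.seed(seed)
  data.frame(
    candidate = seq_len(spec$n_candidates),
    h1 = sample(spec$h1_range[1]:spec$h1_range[2], spec$n_candidates, replace = TRUE),
    h2 = sample(spec$h2_range[1]:spec$h2_range[2], spec$n_candidates, replace = TRUE),
    batch_size = sample(spec$batch_range[1]:spec$batch_range[2],
      spec$n_candidates, replace = TRUE),
    lr = exp(stats::runif(spec$n_candidates, log(spec$lr_range[1]),
      log(spec$lr_range[2])))
  )
}

rung_epochs <- function(spec) {
  e <- spec$grace
  rungs <- integer(0)
  while (e < spec$max_epochs) {
    rungs <- c(rungs, e)
    e <- e * spec$reduction_factor
  }
  c(rungs, spec$max_epochs)
}

#' Fit a single family network
#'
#' Trains the multiclass feed-forward network (input -> h1 -> h2 -> K, ReLU
#' activations, softmax output; defaults h1 = 256, h2 = 512) with weighted
#' cross-entropy and Adam, at fixed hyperparameters. [train_family()] wraps
#' this in the random search; calling it directly is useful for controlled
#' experiments such as weighted-versus-unweighted comparisons.
#'
#' @param train [embedding_set] of training vectors.
#' @param labels family labels for `train` (named by id, or in row order).
#' @param ontology [family_ontology]; derived from `labels` when `NULL`.
#' @param h1,h2 hidden layer sizes.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed integer RNG seed.
#' @param weighted use inverse-frequency class weights (default `TRUE`);
#'   `FALSE` trains with uniform weights.
#' @return an object of class `cazyme_family_net`.
#' @export
fit_family_net <- function(train, labels, ontology = NULL, h1 = 256L, h2 = 512L,
                           lr = 1e-3, batch_size = 64L, epochs = 30L,
                           seed = 1L, weighted = TRUE) {
  stopifnot(inherits(train, "embedding_set"))
  if (is.null(ontology)) {
    lab <- if (!is.null(names(labels))) labels[embedding_ids(train)] else labels
    tab <- table(lab)
    ontology <- family_ontology(names(tab), as.integer(tab))
  }
  y <- align_labels(train, labels, ontology)
  w <- if (weighted) unname(class_weights(ontology)) else rep(1, ontology$K)
  X <- unname(train$vectors)
  state <- mlp_init(ncol(X), h1, h2, ontology$K, seed)
  state <- mlp_train_epochs(state, X, y, w, lr, batch_size, epochs,
    seed_base = seed + 7919L)
  structure(list(
    params = state$params, dims = state$dims, ontology = ontology,
    activation = "relu", optimizer = "adam", weighted = weighted,
    class_weights = w, seed = as.integer(seed),
    hyperparameters = list(h1 = h1, h2 = h2, lr = lr,
      batch_size = batch_size, epochs = state$epoch)
  ), class = "cazyme_family_net")
}

#' Train the family classifier with random search and successive halving
#'
#' Samples `spec$n_candidates` hyperparameter configurations, trains them in
#' rungs (epoch checkpoints at `grace`, `grace * reduction_factor`, ... up
#' to `max_epochs`), and prunes to the best `1/reduction_factor` fraction by
#' validation loss at each rung — successive halving, run synchronously.
#' The returned model is the surviving candidate with the best validation
#' accuracy after full training. Everything (candidate sampling, shuffling,
#' initialization) is reproducible from `seed`.
#'
#' @param train,val [embedding_set]s with disjoint ids; `val` non-empty.
#' @param train_labels,val_labels family labels (named by id or row order).
#'   Every validation label must occur in training.
#' @param spec a [search_spec()].
#' @param seed integer RNG seed.
#' @param weighted use inverse-frequency class weights (default `TRUE`).
#' @return the best `cazyme_family_net`; attribute `search_report` is a
#'   per-candidate data.frame (hyperparameters, epochs survived, final
#'   validation loss/accuracy) and attribute `rung_counts` the number of
#'   candidates evaluated at each rung.
#' @export
train_family <- function(train, train_labels, val, val_labels,
                         spec = search_spec(), seed = 1L, weighted = TRUE) {
  stopifnot(inherits(train, "embedding_set"), inherits(val, "embedding_set"))
  if (nrow(val$vectors) == 0L) stop("validation set is empty")
  if (length(intersect(embedding_ids(train), embedding_ids(val)))) {
    stop("train and validation ids overlap")
  }
  lab_tr <- if (!is.null(names(train_labels))) {
    train_labels[embedding_ids(train)]
  } else train_labels
  tab <- table(lab_tr)
  ontology <- family_ontology(names(tab), as.integer(tab))
  y_tr <- align_labels(train, train_labels, ontology)
  y_val <- tryCatch(align_labels(val, val_labels, ontology),
    error = function(e) stop("validation label absent from training: ",
      conditionMessage(e)))
  w <- if (weighted) unname(class_weights(ontology)) else rep(1, ontology$K)
  X <- unname(train$vectors)
  Xv <- unname(val$vectors)

  cand <- sample_candidates(spec, seed)
  rungs <- rung_epochs(spec)
  states <- lapply(seq_len(nrow(cand)), function(i) {
    mlp_init(ncol(X), cand$h1[i], cand$h2[i], ontology$K,
      seed = (seed + 1000L * i) %% .Machine$integer.max)
  })
  alive <- seq_len(nrow(cand))
  cand$epochs_trained <- 0L
  cand$val_loss <- NA_real_
  cand$val_accuracy <- NA_real_
  cand$rungs_survived <- 0L
  rung_counts <- integer(length(rungs))

  for (r in seq_along(rungs)) {
    rung_counts[r] <- length(alive)
    target <- rungs[r]
    for (i in alive) {
      add <- target - states[[i]]$epoch
      if (add > 0L) {
        states[[i]] <- mlp_train_epochs(states[[i]], X, y_tr, w,
          cand$lr[i], cand$batch_size[i], add,
          seed_base = (seed + 1000L * i + 7919L) %% .Machine$integer.max)
      }
      ev <- mlp_evaluate(states[[i]]$params, Xv, y_val, w)
      cand$epochs_trained[i] <- states[[i]]$epoch
      cand$val_loss[i] <- ev$loss
      cand$val_accuracy[i] <- ev$accuracy
      cand$rungs_survived[i] <- r
    }
    if (r < length(rungs)) {
      keep <- max(1L, floor(length(alive) / spec$reduction_factor))
      alive <- alive[order(cand$val_loss[alive])][seq_len(keep)]
    }
  }

  finished <- which(cand$epochs_trained == spec$max_epochs)
  best <- finished[which.max(cand$val_accuracy[finished])]
  model <- structure(list(
    params = states[[best]]$params, dims = states[[best]]$dims,
    ontology = ontology, activation = "relu", optimizer = "adam",
    weighted = weighted, class_weights = w, seed = as.integer(seed),
    hyperparameters = list(h1 = cand$h1[best], h2 = cand$h2[best],
      lr = cand$lr[best], batch_size = cand$batch_size[best],
      epochs = cand$epochs_trained[best])
  ), class = "cazyme_family_net")
  attr(model, "search_report") <- cand
  attr(model, "rung_counts") <- rung_counts
  attr(model, "rung_epochs") <- rungs
  attr(model, "best_candidate") <- cand$candidate[best]
  model
}

#' @export
print.cazyme_family_net <- function(x, ...) {
  d <- x$dims
  cat("CAZyme family network:", d["input"], "->", d["h1"], "->", d["h2"],
    "->", d["K"], "(ReLU, softmax)\n")
  cat("  ", if (x$weighted) "inverse-frequency weighted" else "unweighted",
    "cross-entropy;", x$hyperparameters$epochs, "epochs; seed", x$seed, "\n")
  invisible(x)
}

#' Predict family labels
#'
#' Runs the network over a query embedding set. The assigned label is the
#' argmax of the softmax output (ties broken toward the lowest class
#' index); the full probability vectors are attached for downstream use
#' (e.g. prioritization).
#'
#' @param model a `cazyme_family_net`.
#' @param query [embedding_set] with the model's input dimension.
#' @return data.frame `id`, `family`, `probability` (top-class probability),
#'   in input order, with attribute `probabilities` (n x K matrix, columns
#'   named by label).
#' @export
family_predict <- function(model, query) {
  stopifnot(inherits(model, "cazyme_family_net"), inherits(query, "embedding_set"))
  if (nrow(query$vectors) == 0L) {
    out <- data.frame(id = character(0), family = character(0),
      probability = numeric(0), stringsAsFactors = FALSE)
    attr(out, "probabilities") <- matrix(numeric(0), 0, model$ontology$K,
      dimnames = list(NULL, model$ontology$labels))
    return(out)
  }
  if (query$dim != model$dims[["input"]]) {
    stop("query dim ", query$dim, " does not match model input dim ",
      model$dims[["input"]])
  }
  P <- mlp_forward(model$params, unname(query$vectors))$P
  colnames(P) <- model$ontology$labels
  rownames(P) <- embedding_ids(query)
  top <- max.col(P, ties.method = "first")
  out <- data.frame(id = embedding_ids(query),
    family = model$ontology$labels[top],
    probability = P[cbind(seq_len(nrow(P)), top)],
    stringsAsFactors = FALSE)
  attr(out, "probabilities") <- P
  out
}

#' @export
predict.cazyme_family_net <- function(object, newdata, ...) {
  family_predict(object, newdata)
}
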