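#' Train the CAZyme/non-CAZyme gate
#'
#' The binary first stage: a random forest over embedding vectors voting
#' CAZyme versus non-CAZyme, with 200 trees by default and a fixed seed so
#' that training twice on identical inputs yields identical predictions.
#' The score of a query is the fraction of trees voting CAZyme, so
#' thresholding and ROC/PR construction behave as with any probability.
#'
#' @param pos [embedding_set] of CAZyme (positive) training vectors.
#' @param neg [embedding_set] of non-CAZyme (negative) training vectors;
#'   same dimension as `pos`, ids disjoint.
#' @param n_trees number of trees (default 200).
#' @param seed integer RNG seed.
#' @param class_weighted optionally reweight classes inversely to size
#'   (default `FALSE`; off unless the gate-training imbalance warrants it).
#' @return an object of class `cazyme_gate`.
#' @importFrom randomForest randomForest
#' @export
train_gate <- function(pos, neg, n_trees = 200L, seed = 1L,
                       class_weighted = FALSE) {
  stopifnot(inherits(pos, "embedding_set"), inherits(neg, "embedding_set"))
  if (pos$dim != neg$dim) {
    stop("dimension mismatch: positives ", pos$dim, ", negatives ", neg$dim)
  }
  if (nrow(pos$vectors) < 2L || nrow(neg$vectors) < 2L) {
    stop("need at least 2 examples per class")
  }
  shared <- intersect(embedding_ids(pos), embedding_ids(neg))
  if (length(shared)) stop("ids in both classes: ", paste(utils::head(shared, 5), collapse = ", "))
  x <- rbind(pos$vectors, neg$vectors)
  colnames(x) <- paste0("e", seq_len(ncol(x)))
  y <- factor(rep(c("cazyme", "other"), c(nrow(pos$vectors), nrow(neg$vectors))),
    levels = c("cazyme", "other"))
  cw <- if (class_weighted) {
    w <- 1 / table(y)
    as.numeric(w / sum(w) * 2)
  } else NULL
  set.seed(seed)
  forest <- randomForest::randomForest(x, y, ntree = n_trees, classwt = cw)
  structure(list(
    forest = forest,
    dim = pos$dim,
    n_trees = as.integer(n_trees),
    seed = as.integer(seed),
    n_pos = nrow(pos$vectors),
    n_neg = nrow(neg$vectors),
    provenance = pos$provenance
  ), class = "cazyme_gate")
}

#' @export
print.cazyme_gate <- function(x, ...) {
  cat("CAZyme gate: random forest,", x$n_trees, "trees, input dim", x$dim, "\n")
  cat("  trained on", x$n_pos, "positives /", x$n_neg, "negatives (seed",
    x$seed, ")\n")
  invisible(x)
}

#' Score queries with the gate
#'
#' @param model a [train_gate()] model.
#' @param query [embedding_set] with the model's input dimension.
#' @param threshold decision threshold tau in `[0,1]` (default 0.5);
#'   `decision = score >= tau`.
#' @return data.frame `id`, `score` (CAZyme vote fraction in `[0,1]`),
#'   `decision` (logical), in input order.
#' @export
gate_scores <- function(model, query, threshold = 0.5) {
  stopifnot(inherits(model, "cazyme_gate"), inherits(query, "embedding_set"))
  if (query$dim != model$dim && nrow(query$vectors) > 0L) {
    stop("query dim ", query$dim, " does not match model dim ", model$dim)
  }
  if (nrow(query$vectors) == 0L) {
    return(data.frame(id = character(0), score = numeric(0),
      decision = logical(0), stringsAsFactors = FALSE))
  }
  x <- query$vectors
  colnames(x) <- paste0("e", seq_len(ncol(x)))
  votes <- predict(model$forest, x, type = "prob")
  score <- as.numeric(votes[, "cazyme"])
  data.frame(id = embedding_ids(query), score = score,
    decision = score >= threshold, stringsAsFactors = FALSE)
}

#' @export
predict.cazyme_gate <- function(object, newdata, threshold = 0.5, ...) {
  gate_scores(object, newdata, threshold = threshold)
}

#' Save / load fitted models with a manifest
#'
#' Serializes a gate or family model together with a manifest describing
#' its configuration (dimensions, seed, label map, hyperparameters), so a
#' loaded model can be sanity-checked before use.
#'
#' @param model a `cazyme_gate` or `cazyme_family_net`.
#' @param path file path.
#' @return `save_model` the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("cazyme_gate", "cazyme_family_net")))
  saveRDS(list(manifest = model_manifest(model), model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !all(c("manifest", "model") %in% names(obj))) {
    stop("not a cazkit model archive: ", path)
  }
  obj$model
}

model_manifest <- function(model) {
  if (inherits(model, "cazyme_gate")) {
    list(type = "gate", dim = model$dim, n_trees = model$n_trees,
      seed = model$seed, n_pos = model$n_pos, n_neg = model$n_neg)
  } else {
    list(type = "family", dims = model$dims, K = model$ontology$K,
      labels = model$ontology$labels, seed = model$seed,
      hyperparameters = model$hyperparameters)
  }
}
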