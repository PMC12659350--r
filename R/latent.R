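#' Exact Euclidean nearest neighbours in embedding space
#'
#' Finds, for every query vector, the k reference vectors at smallest
#' Euclidean distance by exhaustive search — no approximation, so the
#' result is the true minimum over the reference set. Ties are broken by
#' reference row order.
#'
#' @param query,reference [embedding_set]s of equal dimension; reference
#'   non-empty.
#' @param k neighbours per query (default 1); must not exceed the usable
#'   reference size.
#' @param exclude_self drop a reference entry whose id equals the query id
#'   (for searches of a set against itself).
#' @param reference_labels optional named character vector (reference id ->
#'   family label) copied onto hits.
#' @return data.frame `query_id`, `neighbor_id`, `rank`, `distance`, and
#'   `neighbor_family` when labels were supplied; queries in input order.
#' @export
nearest_neighbors <- function(query, reference, k = 1L, exclude_self = FALSE,
                              reference_labels = NULL) {
  stopifnot(inherits(query, "embedding_set"), inherits(reference, "embedding_set"))
  if (nrow(reference$vectors) == 0L) stop("reference set is empty")
  if (query$dim != reference$dim) {
    stop("dimension mismatch: query ", query$dim, ", reference ", reference$dim)
  }
  n_ref <- nrow(reference$vectors) - if (exclude_self) 1L else 0L
  if (k > n_ref) stop("k = ", k, " exceeds usable reference size ", n_ref)
  Q <- query$vectors
  R <- reference$vectors
  # ||q - r||^2 = ||q||^2 + ||r||^2 - 2 q.r, computed blockwise
  rn <- rowSums(R^2)
  out <- vector("list", nrow(Q))
  for (i in seq_len(nrow(Q))) {
    d2 <- rn - 2 * as.numeric(R %*% Q[i, ]) + sum(Q[i, ]^2)
    d2 <- pmax(d2, 0)
    if (exclude_self) d2[rownames(R) == rownames(Q)[i]] <- Inf
    sel <- order(d2)[seq_len(k)]
    out[[i]] <- data.frame(
      query_id = rownames(Q)[i], neighbor_id = rownames(R)[sel],
      rank = seq_len(k), distance = sqrt(d2[sel]),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  if (!is.null(reference_labels)) {
    hits$neighbor_family <- unname(reference_labels[hits$neighbor_id])
  }
  hits
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The BLOSUM62 substitution matrix (canonical residues)
#'
#' The standard 20 x 20 BLOSUM62 score table, taken from the Biostrings
#' distribution and checked at load: symmetric, with each residue's
#' self-score at least as large as any substitution score in its row.
#'
#' @return 20 x 20 integer matrix over the canonical amino acids.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  stopifnot(isSymmetric(unname(m)), all(diag(m) >= apply(m, 1L, max)))
  m
}

#' Most distant substitution for a residue
#'
#' The amino acid (other than the residue itself) with the minimal
#' substitution score against it — the strongest single-residue
#' perturbation under the matrix. Ties are broken alphabetically.
#'
#' @param residue single canonical amino-acid letter.
#' @param matrix substitution matrix (default [blosum62()]).
#' @return a single amino-acid letter, never equal to `residue`.
#' @export
most_distant_substitution <- function(residue, matrix = blosum62()) {
  if (!residue %in% rownames(matrix)) {
    stop("non-canonical residue: ", residue)
  }
  row <- matrix[residue, setdiff(colnames(matrix), residue)]
  names(row)[order(row, names(row))[1L]]
}

#' Sliding-window substitution probe
#'
#' In-silico mutagenesis along a protein: for each window of `window`
#' residues (0-based, half-open coordinates, step `step`), every canonical
#' residue in the window is replaced by its most distant BLOSUM62
#' substitution, the mutant is re-embedded, and the family network's
#' probability for `target_class` is recorded. Regions whose perturbation
#' sharply drops that probability are the ones the embedding — and hence
#' the classification — depends on. The `"identity"` mode is a no-op
#' control: windows are "substituted" by themselves, so the trace must sit
#' exactly at the unmutated baseline.
#'
#' @param record single-row [protein_records] (or list with `id`,
#'   `sequence`).
#' @param embedder an [make_embedder()] embedder.
#' @param family a family model from [train_family()] / [fit_family_net()].
#' @param target_class ontology label whose probability is tracked.
#' @param window window width in residues (default 10).
#' @param step window stride (default 1).
#' @param mode `"blosum"` (default) or `"identity"` (control).
#' @param noncanonical `"skip"` (default: leave non-canonical residues
#'   unsubstituted, with a note) or `"x"` (treat as X: no substitution
#'   available either, but unflagged).
#' @param pool pooling for per-residue embedder output.
#' @return data.frame of class `probe_trace` with `window_start`,
#'   `window_end` (0-based half-open), `probability`, `delta` (baseline
#'   minus window probability); attributes `baseline`, `target_class`.
#' @export
sliding_window_probe <- function(record, embedder, family, target_class,
                                 window = 10L, step = 1L,
                                 mode = c("blosum", "identity"),
                                 noncanonical = c("skip", "x"), pool = "mean") {
  mode <- match.arg(mode)
  noncanonical <- match.arg(noncanonical)
  stopifnot(inherits(family, "cazyme_family_net"))
  seq_str <- if (is.data.frame(record)) record$sequence[[1L]] else record$sequence
  id <- if (is.data.frame(record)) record$id[[1L]] else record$id
  L <- nchar(seq_str)
  if (L < window) stop("sequence shorter than the probe window")
  if (!target_class %in% family$ontology$labels) {
    stop("target class ", target_class, " not in the model ontology")
  }
  B <- blosum62()
  sub_table <- vapply(AA20, most_distant_substitution, "", matrix = B)

  embed_one <- function(s, what) {
    out <- tryCatch(embedder$fun(s), error = function(e) {
      stop("embedder failed at ", what, ": ", conditionMessage(e))
    })
    if (is.matrix(out)) out <- pool_residue_embeddings(out, pool)
    as.numeric(out)
  }
  prob_of <- function(vec) {
    m <- matrix(vec, nrow = 1L, dimnames = list("q", NULL))
    p <- attr(family_predict(family, embedding_set(m, embedder$name)),
      "probabilities")
    p[1L, target_class]
  }

  baseline <- prob_of(embed_one(seq_str, "baseline"))
  chars <- strsplit(seq_str, "")[[1L]]
  starts0 <- seq(0L, L - window, by = step)
  probs <- numeric(length(starts0))
  skipped <- 0L
  for (j in seq_along(starts0)) {
    i0 <- starts0[j]
    idx <- (i0 + 1L):(i0 + window)
    mut <- chars
    if (mode == "blosum") {
      for (p in idx) {
        r <- chars[p]
        if (r %in% AA20) {
          mut[p] <- sub_table[[r]]
        } else if (noncanonical == "skip") {
          skipped <- skipped + 1L
        }
      }
    }
    probs[j] <- prob_of(embed_one(paste(mut, collapse = ""),
      paste0("window [", i0, ",", i0 + window, ")")))
  }
  out <- data.frame(window_start = starts0, window_end = starts0 + window,
    probability = probs, delta = baseline - probs)
  class(out) <- c("probe_trace", "data.frame")
  attr(out, "baseline") <- baseline
  attr(out, "target_class") <- target_class
  attr(out, "id") <- id
  attr(out, "noncanonical_skipped") <- skipped
  out
}

#' @export
print.probe_trace <- function(x, ...) {
  cat("Substitution probe of", attr(x, "id"), "for",
    attr(x, "target_class"), ":", nrow(x), "windows, baseline p =",
    signif(attr(x, "baseline"), 4), "\n")
  top <- x[order(-x$delta), ][1L, ]
  cat("  largest drop", signif(top$delta, 4), "at [",
    top$window_start, ",", top$window_end, ")\n")
  invisible(x)
}

#' @method plot probe_trace
#' @export
plot.probe_trace <- function(x, ...) {
  graphics::plot(x$window_start, x$probability, type = "l",
    xlab = "window start (0-based)",
    ylab = paste("P(", attr(x, "target_class"), ")"), ...)
  graphics::abline(h = attr(x, "baseline"), lty = 2)
  invisible(x)
}
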