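#' Two-stage CAZyme annotation
#'
#' Chains the gate and family stages over a query embedding set: every
#' protein is scored by the random-forest gate; those at or above the gate
#' threshold are passed to the family network for a family/subfamily call.
#' Every input id appears exactly once in the output, in input order;
#' family fields are present iff the protein was gated as a CAZyme.
#'
#' @param query [embedding_set] to annotate.
#' @param gate a [train_gate()] model.
#' @param family a [train_family()] / [fit_family_net()] model.
#' @param threshold gate decision threshold tau (default 0.5). At
#'   `threshold = 0` every protein is family-annotated.
#' @param families_only bypass the gate entirely for pre-vetted inputs
#'   (every record treated as a CAZyme, gate score still reported).
#' @return data.frame of class `cazyme_predictions` with columns `id`,
#'   `gate_score`, `is_cazyme`, `family` (NA for non-CAZymes),
#'   `family_probability` (NA for non-CAZymes).
#' @export
annotate <- function(query, gate, family, threshold = 0.5,
                     families_only = FALSE) {
  stopifnot(inherits(query, "embedding_set"), inherits(gate, "cazyme_gate"),
    inherits(family, "cazyme_family_net"))
  if (nrow(query$vectors) > 0L &&
      (query$dim != gate$dim || query$dim != family$dims[["input"]])) {
    stop("dimension mismatch across query (", query$dim, "), gate (",
      gate$dim, ") and family model (", family$dims[["input"]], ")")
  }
  gs <- gate_scores(gate, query, threshold = threshold)
  out <- data.frame(id = gs$id, gate_score = gs$score,
    is_cazyme = if (families_only) rep(TRUE, nrow(gs)) else gs$decision,
    family = NA_character_, family_probability = NA_real_,
    stringsAsFactors = FALSE)
  pos_ids <- out$id[out$is_cazyme]
  if (length(pos_ids)) {
    fp <- family_predict(family, subset_embeddings(query, pos_ids))
    m <- match(fp$id, out$id)
    out$family[m] <- fp$family
    out$family_probability[m] <- fp$probability
  }
  class(out) <- c("cazyme_predictions", "data.frame")
  out
}

#' @export
print.cazyme_predictions <- function(x, ...) {
  cat("CAZyme predictions:", nrow(x), "proteins,", sum(x$is_cazyme),
    "gated as CAZymes\n")
  if (any(x$is_cazyme)) {
    cat("  top families:", paste(utils::head(names(sort(table(x$family),
      decreasing = TRUE)), 5), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read predictions as TSV
#'
#' Fixed, versioned column set (`id`, `gate_score`, `is_cazyme`, `family`,
#' `family_probability`) so downstream analyses — in particular the
#' differential-abundance prioritization, which consumes
#' `family_probability` — can rely on the layout.
#'
#' @param predictions a `cazyme_predictions` data.frame.
#' @param path output path.
#' @return the path (write) or the predictions (read).
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, colClasses = c(id = "character"))
  needed <- c("id", "gate_score", "is_cazyme", "family", "family_probability")
  missing <- setdiff(needed, names(out))
  if (length(missing)) stop("predictions file lacks column(s): ",
    paste(missing, collapse = ", "))
  class(out) <- c("cazyme_predictions", "data.frame")
  out
}
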