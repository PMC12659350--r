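#' @keywords internal
"_PACKAGE"

CAZY_CLASSES <- c("GH", "GT", "CE", "PL")

#' Parse CAZy family labels
#'
#' A family label names a CAZy class (`GH`, `GT`, `CE`, `PL`), a family
#' number, and optionally a subfamily number, rendered canonically as
#' e.g. `"GH43"` or `"GH43_18"`. Parsing and formatting round-trip.
#'
#' @param x character vector of labels.
#' @param strict error on unparsable labels (default) instead of returning
#'   `NA` rows.
#' @return a data.frame with columns `label` (canonical form), `cazy_class`,
#'   `family` (integer) and `subfamily` (integer or `NA`).
#' @examples
#' parse_family_label(c("GH43_18", "CE17"))
#' @export
parse_family_label <- function(x, strict = TRUE) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^(GH|GT|CE|PL)([0-9]+)(_([0-9]+))?$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad) && strict) {
    stop("unparsable family label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  cls <- ifelse(bad, NA_character_, vapply(m, function(g) if (length(g)) g[2] else NA_character_, ""))
  fam <- ifelse(bad, NA_integer_, as.integer(vapply(m, function(g) if (length(g)) g[3] else NA_character_, "")))
  sub <- vapply(m, function(g) if (length(g) && nzchar(g[5])) g[5] else NA_character_, "")
  sub <- as.integer(sub)
  data.frame(
    label = format_family_label(cls, fam, sub),
    cazy_class = cls, family = fam, subfamily = sub,
    stringsAsFactors = FALSE
  )
}

#' Render a family label canonically
#'
#' @param cazy_class one of `"GH"`, `"GT"`, `"CE"`, `"PL"`.
#' @param family positive integer family number.
#' @param subfamily optional positive integer subfamily number (`NA` for none).
#' @return character vector of canonical labels (e.g. `"PL9_1"`).
#' @export
format_family_label <- function(cazy_class, family, subfamily = NA_integer_) {
  out <- ifelse(is.na(cazy_class) | is.na(family), NA_character_,
    paste0(cazy_class, family, ifelse(is.na(subfamily), "", paste0("_", subfamily))))
  out
}

is_family_label <- function(x) {
  grepl("^(GH|GT|CE|PL)[0-9]+(_[0-9]+)?$", x)
}

#' Family ontology
#'
#' The ordered label space of the multiclass family stage: the distinct
#' family/subfamily labels seen in training together with their training
#' sequence counts. The label set is always data-driven, never hard-coded;
#' its size K is whatever the curated training set supports.
#'
#' @param labels character vector of canonical family labels (distinct).
#' @param counts integer vector of per-label training counts (all >= 1),
#'   recycled names from `labels` if unnamed.
#' @return an object of class `family_ontology` with fields `labels`,
#'   `counts` and `K`.
#' @export
family_ontology <- function(labels, counts) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("ontology labels must be distinct")
  bad <- !is_family_label(labels)
  if (any(bad)) stop("invalid family label(s): ", paste(labels[bad], collapse = ", "))
  counts <- as.integer(counts)
  if (length(counts) != length(labels)) stop("counts must align with labels")
  if (any(is.na(counts) | counts < 1L)) {
    stop("every trainable label needs count >= 1; offending: ",
      paste(labels[is.na(counts) | counts < 1L], collapse = ", "))
  }
  names(counts) <- labels
  structure(list(labels = labels, counts = counts, K = length(labels)),
    class = "family_ontology")
}

#' Build a family ontology from labeled protein records
#'
#' Counts, per label, the number of records carrying that label
#' (multi-label records contribute to each of their labels).
#'
#' @param records a `protein_records` object with at least one labeled record.
#' @return a `family_ontology`.
#' @export
ontology_from_records <- function(records) {
  labs <- unlist(records$labels, use.names = FALSE)
  if (length(labs) == 0L) stop("no labeled records")
  tab <- table(labs)
  family_ontology(names(tab), as.integer(tab))
}

#' @export
print.family_ontology <- function(x, ...) {
  cat("Family ontology: K =", x$K, "labels,",
    sum(x$counts), "training sequences\n")
  cls <- substr(x$labels, 1, 2)
  print(table(cls))
  invisible(x)
}

#' Protein record sets
#'
#' A light container for protein sequences: a data.frame with columns
#' `id` (unique, non-empty), `sequence` (amino-acid string, length >= 1)
#' and `labels` (list column of canonical family labels, possibly empty).
#'
#' @param id character vector of unique sequence identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param labels list of character vectors of family labels (optional).
#' @return an object of class `protein_records` (a data.frame).
#' @export
protein_records <- function(id, sequence, labels = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) stop("id and sequence lengths differ")
  if (length(id)) {
    if (any(!nzchar(id))) stop("empty ids are not allowed")
    dup <- unique(id[duplicated(id)])
    if (length(dup)) stop("duplicate ids: ", paste(dup, collapse = ", "))
    if (any(nchar(sequence) < 1L)) {
      stop("zero-length sequences: ", paste(id[nchar(sequence) < 1L], collapse = ", "))
    }
  }
  if (is.null(labels)) labels <- rep(list(character(0)), length(id))
  if (length(labels) != length(id)) stop("labels must align with ids")
  labels <- lapply(labels, as.character)
  out <- data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
  out$labels <- labels
  class(out) <- c("protein_records", "data.frame")
  out
}

#' @export
print.protein_records <- function(x, ...) {
  n_lab <- sum(vapply(x$labels, length, 1L) > 0L)
  cat("Protein records:", nrow(x), "sequences (", n_lab, "labeled )\n")
  if (nrow(x)) {
    len <- nchar(x$sequence)
    cat("  length range:", min(len), "-", max(len), "\n")
  }
  invisible(x)
}
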