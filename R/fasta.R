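#' Read a labeled FASTA file
#'
#' Reads protein FASTA where headers may carry CAZy family labels in the
#' dialect used by CAZy-derived databases: the first token (up to the first
#' delimiter) is the sequence id and any further pipe- or
#' whitespace-delimited tokens matching the family-label grammar (e.g.
#' `GH43_18`) become labels. Records whose headers carry no parsable label
#' get an empty label set.
#'
#' @param path path to a FASTA file.
#' @param label_delim regular expression splitting header tokens
#'   (default: pipe or whitespace).
#' @return a [protein_records] set, one record per FASTA entry.
#' @export
parse_labeled_fasta <- function(path, label_delim = "[|[:space:]]+") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(protein_records(character(0), character(0)))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence data before first header at line ", first)
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  tokens <- strsplit(headers, label_delim)
  ids <- vapply(tokens, `[`, "", 1L)
  bad_seq <- which(Biostrings::width(aa) == 0L)
  if (length(bad_seq)) {
    stop("malformed FASTA: empty sequence for entries: ",
      paste(ids[bad_seq], collapse = ", "))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate ids in FASTA: ", paste(dup, collapse = ", "))
  labels <- lapply(tokens, function(tk) {
    tk <- tk[-1L]
    unique(tk[is_family_label(tk)])
  })
  protein_records(ids, as.character(aa), labels)
}

#' Write protein records as FASTA
#'
#' Headers are `id|label1|label2...` for labeled records, bare `id`
#' otherwise, so that [parse_labeled_fasta()] round-trips.
#'
#' @param records a [protein_records] set.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_labeled_fasta <- function(records, path) {
  headers <- vapply(seq_len(nrow(records)), function(i) {
    labs <- records$labels[[i]]
    if (length(labs)) paste(c(records$id[i], labs), collapse = "|") else records$id[i]
  }, "")
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
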