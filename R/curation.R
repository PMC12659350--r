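#' Filter protein records by length and class
#'
#' Removes sequences longer than `max_len` amino acids (strictly greater:
#' a sequence of exactly `max_len` residues is kept). When `require_label`
#' is `TRUE` (positive-set curation), records must additionally retain at
#' least one label whose CAZy class is not in `drop_classes`.
#'
#' @param records a [protein_records] set.
#' @param max_len maximum retained length in residues (default 5000, the
#'   cap used when generating embeddings).
#' @param drop_classes character vector of CAZy classes or full labels to
#'   discard from records' label sets.
#' @param require_label if `TRUE`, drop records left without any label.
#' @return the filtered [protein_records]; attribute `removed` holds counts
#'   removed per reason (`overlength`, `no_label`).
#' @export
filter_records <- function(records, max_len = 5000L, drop_classes = character(0),
                           require_label = FALSE) {
  stopifnot(max_len >= 1L)
  over <- nchar(records$sequence) > max_len
  kept <- records[!over, , drop = FALSE]
  if (length(drop_classes)) {
    kept$labels <- lapply(kept$labels, function(labs) {
      cls <- substr(labs, 1L, 2L)
      labs[!(cls %in% drop_classes | labs %in% drop_classes)]
    })
  }
  no_label <- rep(FALSE, nrow(kept))
  if (require_label) {
    no_label <- vapply(kept$labels, length, 1L) == 0L
    kept <- kept[!no_label, , drop = FALSE]
  }
  class(kept) <- c("protein_records", "data.frame")
  attr(kept, "removed") <- c(overlength = sum(over), no_label = sum(no_label))
  kept
}

#' Remove duplicate sequences
#'
#' Keeps exactly one representative per identical sequence string (100%
#' identity). The representative is the record with the lexicographically
#' smallest id, for determinism; its labels become the union of the
#' duplicates' labels.
#'
#' @param records a [protein_records] set.
#' @return deduplicated [protein_records], in order of first occurrence of
#'   each sequence.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0L) return(records)
  groups <- split(seq_len(nrow(records)), factor(records$sequence,
    levels = unique(records$sequence)))
  keep_idx <- integer(length(groups))
  labels <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    keep_idx[g] <- idx[order(records$id[idx])[1L]]
    labels[[g]] <- unique(unlist(records$labels[idx], use.names = FALSE))
  }
  out <- records[keep_idx, , drop = FALSE]
  out$labels <- labels
  rownames(out) <- NULL
  class(out) <- c("protein_records", "data.frame")
  out
}

# Ambiguity letters are kept in stored sequences but folded to X before
# alignment so that identity is computed over the 20-letter alphabet.
fold_ambiguity <- function(seq) {
  chartr("BZJUO", "XXXXX", seq)
}

#' Pairwise sequence identity
#'
#' Global (Needleman-Wunsch) or local (Smith-Waterman) alignment via
#' Biostrings, scored with BLOSUM62. Identity is matches divided by
#' alignment length (alignment columns, gaps included); for local
#' alignments, coverage is the aligned fraction of the query (first)
#' sequence.
#'
#' @param a,b amino-acid sequence strings.
#' @param type `"global"` or `"local"`.
#' @return a list with `identity`, `matches`, `alignment_length`, and
#'   (for local) `coverage` of `a`.
#' @export
pairwise_identity <- function(a, b, type = c("global", "local")) {
  type <- match.arg(type)
  aln <- Biostrings::pairwiseAlignment(
    fold_ambiguity(a), fold_ambiguity(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = type
  )
  alen <- nchar(as.character(Biostrings::pattern(aln)))
  m <- Biostrings::nmatch(aln)
  out <- list(identity = if (alen > 0) m / alen else 0,
    matches = m, alignment_length = alen)
  if (type == "local") out$coverage <- alen / nchar(a)
  out
}

#' Greedy identity clustering
#'
#' Clusters sequences so that no two cluster representatives share pairwise
#' identity above `threshold` — the longest-first greedy strategy used by
#' standard redundancy-reduction tools. Sequences are sorted by decreasing
#' length; each is assigned to the first existing representative with
#' identity strictly greater than `threshold`, else it seeds a new cluster.
#'
#' @param records a [protein_records] set.
#' @param threshold identity threshold in (0,1); default 0.60, the
#'   redundancy level used for the non-redundant training database.
#' @param identity_fn function `(a, b) -> identity in [0,1]`; defaults to
#'   global [pairwise_identity()].
#' @return a list with `members` (data.frame `member_id`,
#'   `representative_id`, `identity`) and `representatives`
#'   (a [protein_records] subset).
#' @export
cluster_identity <- function(records, threshold = 0.60, identity_fn = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(identity_fn)) {
    identity_fn <- function(a, b) pairwise_identity(a, b, type = "global")$identity
  }
  ord <- order(-nchar(records$sequence), records$id)
  rep_idx <- integer(0)
  member <- character(nrow(records))
  ident <- numeric(nrow(records))
  for (i in ord) {
    assigned <- FALSE
    for (r in rep_idx) {
      idv <- identity_fn(records$sequence[i], records$sequence[r])
      if (idv > threshold) {
        member[i] <- records$id[r]
        ident[i] <- idv
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      member[i] <- records$id[i]
      ident[i] <- 1
    }
  }
  reps <- records[sort(rep_idx), , drop = FALSE]
  rownames(reps) <- NULL
  class(reps) <- c("protein_records", "data.frame")
  list(
    members = data.frame(member_id = records$id,
      representative_id = member, identity = ident, stringsAsFactors = FALSE),
    representatives = reps
  )
}

#' Shared k-mer homology screen
#'
#' Built-in stand-in for an external sensitive homology search: flags any
#' query sharing at least one exact k-mer with the reference set, then
#' confirms candidates by local alignment at a configurable identity and
#' query-coverage cutoff.
#'
#' @param query,reference [protein_records] sets.
#' @param k k-mer size (default 8).
#' @param min_identity alignment identity needed to confirm a hit
#'   (default 0.30).
#' @param min_coverage query coverage needed to confirm a hit (default 0.5).
#' @param confirm confirm k-mer candidates by local alignment (default
#'   `TRUE`); with `FALSE` a shared k-mer alone counts as a hit.
#' @return character vector of query ids with at least one hit.
#' @export
kmer_homology_search <- function(query, reference, k = 8L,
                                 min_identity = 0.30, min_coverage = 0.5,
                                 confirm = TRUE) {
  kmers_of <- function(seq) {
    seq <- fold_ambiguity(seq)
    n <- nchar(seq) - k + 1L
    if (n < 1L) return(character(0))
    unique(substring(seq, seq_len(n), seq_len(n) + k - 1L))
  }
  ref_kmers <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_len(nrow(reference))) {
    for (km in kmers_of(reference$sequence[j])) {
      assign(km, c(get0(km, envir = ref_kmers, ifnotfound = integer(0)), j),
        envir = ref_kmers)
    }
  }
  hits <- character(0)
  for (i in seq_len(nrow(query))) {
    cand <- unique(unlist(lapply(kmers_of(query$sequence[i]), get0,
      envir = ref_kmers, ifnotfound = integer(0))))
    if (length(cand) == 0L) next
    if (!confirm) {
      hits <- c(hits, query$id[i])
      next
    }
    for (j in cand) {
      al <- pairwise_identity(query$sequence[i], reference$sequence[j],
        type = "local")
      if (al$identity >= min_identity && al$coverage >= min_coverage) {
        hits <- c(hits, query$id[i])
        break
      }
    }
  }
  hits
}

#' Purge homologs of the positive set from the negative set
#'
#' Removes from the negative training set every sequence that registers a
#' homology hit against the positive (CAZyme) set, so the gate classifier
#' never trains on mislabeled negatives. The search is pluggable; the
#' default is the built-in k-mer screen with alignment confirmation
#' ([kmer_homology_search()]).
#'
#' @param negatives,positives [protein_records] sets with disjoint ids.
#' @param search function `(query, reference) -> ids with hits`; must be
#'   deterministic for fixed inputs.
#' @param ... passed to the default search.
#' @return negatives minus all hit ids; attribute `removed_ids` lists what
#'   was purged. A search failure aborts — negatives are never kept
#'   unpurged silently.
#' @export
purge_homologs <- function(negatives, positives, search = kmer_homology_search, ...) {
  if (length(intersect(negatives$id, positives$id))) {
    stop("negative and positive sets share ids: ",
      paste(utils::head(intersect(negatives$id, positives$id), 5), collapse = ", "))
  }
  hit_ids <- tryCatch(search(negatives, positives, ...),
    error = function(e) stop("homology search failed, aborting purge: ",
      conditionMessage(e)))
  out <- negatives[!negatives$id %in% hit_ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_records", "data.frame")
  attr(out, "removed_ids") <- intersect(negatives$id, hit_ids)
  out
}
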