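#' Embedding sets
#'
#' A fixed-dimension per-protein embedding collection: a numeric matrix
#' with one row per protein (rownames are ids), all values finite, plus a
#' provenance string naming the embedder that produced it. The paper-scale
#' embedder produces 1024-dimensional vectors; the dimension here is
#' whatever the plugged-in embedder declares.
#'
#' @param vectors numeric matrix, rows = proteins (rownames = unique ids),
#'   columns = embedding dimensions.
#' @param provenance free-text embedder name/version.
#' @return an object of class `embedding_set` with fields `vectors`, `dim`,
#'   `provenance`.
#' @export
embedding_set <- function(vectors, provenance = "unknown") {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) > 0L) {
    if (is.null(rownames(vectors))) stop("vectors need rownames (protein ids)")
    dup <- unique(rownames(vectors)[duplicated(rownames(vectors))])
    if (length(dup)) stop("duplicate embedding ids: ", paste(dup, collapse = ", "))
    if (!all(is.finite(vectors))) {
      bad <- rownames(vectors)[!apply(is.finite(vectors), 1L, all)]
      stop("non-finite embedding values for: ", paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  structure(list(vectors = vectors, dim = ncol(vectors), provenance = provenance),
    class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("Embedding set:", nrow(x$vectors), "proteins x", x$dim,
    "dims (", x$provenance, ")\n")
  invisible(x)
}

#' @export
dim.embedding_set <- function(x) dim(x$vectors)

embedding_ids <- function(es) rownames(es$vectors)

subset_embeddings <- function(es, ids) {
  missing <- setdiff(ids, embedding_ids(es))
  if (length(missing)) stop("ids absent from embedding set: ",
    paste(utils::head(missing, 5), collapse = ", "))
  embedding_set(es$vectors[ids, , drop = FALSE], es$provenance)
}

#' Write / read an embedding set as HDF5
#'
#' The default on-disk dialect is one float dataset per protein at the file
#' root, keyed by id (the layout produced by common embedding pipelines);
#' `layout = "matrix"` instead writes a single `embeddings` matrix plus an
#' `ids` vector. Values are stored as 32-bit floats by default
#' (`precision = "float64"` keeps full doubles). Provenance is kept in a
#' root attribute and restored on read.
#'
#' @param embeddings an [embedding_set].
#' @param path HDF5 file path (overwritten if present).
#' @param layout `"per_id"` (default) or `"matrix"`.
#' @param precision `"float32"` (default) or `"float64"`.
#' @return `write_embeddings_h5` returns the path invisibly;
#'   `read_embeddings_h5` returns an [embedding_set]. Reading a file whose
#'   datasets disagree in dimension is an error naming the offending id.
#' @export
write_embeddings_h5 <- function(embeddings, path, layout = c("per_id", "matrix"),
                                precision = c("float32", "float64")) {
  layout <- match.arg(layout)
  precision <- match.arg(precision)
  h5type <- if (precision == "float32") "H5T_IEEE_F32LE" else "H5T_IEEE_F64LE"
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  v <- embeddings$vectors
  if (layout == "per_id") {
    for (id in rownames(v)) {
      rhdf5::h5createDataset(path, id, dims = ncol(v), H5type = h5type)
      rhdf5::h5write(as.numeric(v[id, ]), path, id)
    }
  } else {
    rhdf5::h5createDataset(path, "embeddings", dims = dim(v), H5type = h5type)
    if (nrow(v)) rhdf5::h5write(unname(v), path, "embeddings")
    rhdf5::h5write(rownames(v), path, "ids")
  }
  rhdf5::h5closeAll()
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(embeddings$provenance, fid, "provenance")
  rhdf5::h5writeAttribute(layout, fid, "layout")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_embeddings_h5
#' @export
read_embeddings_h5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rhdf5::h5closeAll()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path, recursive = FALSE)
  dsets <- contents$name[contents$otype == "H5I_DATASET"]
  prov <- tryCatch(rhdf5::h5readAttributes(path, "/")$provenance,
    error = function(e) NULL)
  prov <- if (is.null(prov)) "unknown" else as.character(prov)[1]
  if (all(c("embeddings", "ids") %in% dsets)) {
    m <- rhdf5::h5read(path, "embeddings")
    ids <- as.character(rhdf5::h5read(path, "ids"))
    if (nrow(m) != length(ids)) stop("matrix layout: ids do not match rows")
    rownames(m) <- ids
    return(embedding_set(m, prov))
  }
  if (length(dsets) == 0L) {
    return(embedding_set(matrix(numeric(0), 0, 0), prov))
  }
  vecs <- lapply(dsets, function(d) as.numeric(rhdf5::h5read(path, d)))
  dims <- vapply(vecs, length, 1L)
  if (length(unique(dims)) > 1L) {
    off <- dsets[dims != dims[1L]][1L]
    stop("dimension mismatch in ", path, ": dataset '", off, "' has length ",
      dims[dsets == off][1L], ", expected ", dims[1L])
  }
  m <- do.call(rbind, vecs)
  rownames(m) <- dsets
  embedding_set(m, prov)
}

#' Pool per-residue embeddings into a per-protein vector
#'
#' Collapses an L x dim per-residue embedding matrix to a single
#' fixed-length vector. The default is the arithmetic mean over residues,
#' the usual convention for deriving per-protein vectors from per-residue
#' language-model output; sum and max pooling are available.
#'
#' @param matrix numeric L x dim matrix, L >= 1.
#' @param method `"mean"` (default), `"sum"` or `"max"`.
#' @return numeric vector of length dim.
#' @export
pool_residue_embeddings <- function(matrix, method = c("mean", "sum", "max")) {
  method <- match.arg(method)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 1L || ncol(matrix) < 1L) stop("empty residue matrix")
  switch(method,
    mean = colMeans(matrix),
    sum = colSums(matrix),
    max = apply(matrix, 2L, max)
  )
}

#' Declare an embedder
#'
#' An embedder is any deterministic function from an amino-acid sequence to
#' either a per-protein numeric vector of the declared dimension or a
#' per-residue L x dim matrix (pooled downstream). This contract is the
#' pluggable stand-in for a protein language model.
#'
#' @param fun function `(sequence) -> numeric vector or matrix`.
#' @param dim declared output dimension.
#' @param name provenance string.
#' @return an object of class `embedder`.
#' @export
make_embedder <- function(fun, dim, name = "custom") {
  stopifnot(is.function(fun), dim >= 1L)
  structure(list(fun = fun, dim = as.integer(dim), name = name),
    class = "embedder")
}

#' Embed protein records
#'
#' Runs the embedder over every record, pooling per-residue output via
#' [pool_residue_embeddings()]. No record is ever skipped silently: any
#' embedder failure is recorded per id and the run errors unless
#' `allow_partial = TRUE`. Sequences longer than `max_len` are rejected to
#' match the training distribution of the curated sets.
#'
#' @param records a [protein_records] set.
#' @param embedder an [make_embedder()] object.
#' @param pool pooling method for per-residue output.
#' @param allow_partial keep going past per-record failures (default
#'   `FALSE`).
#' @param max_len reject sequences longer than this (default 5000).
#' @return an [embedding_set]; attribute `failures` is a named character
#'   vector of error messages per failed id (empty when all succeeded).
#' @export
embed_records <- function(records, embedder, pool = "mean",
                          allow_partial = FALSE, max_len = 5000L) {
  stopifnot(inherits(embedder, "embedder"))
  n <- nrow(records)
  vecs <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    id <- records$id[i]
    res <- tryCatch({
      if (nchar(records$sequence[i]) > max_len) {
        stop("sequence longer than max_len (", max_len, ")")
      }
      out <- embedder$fun(records$sequence[i])
      if (is.matrix(out)) out <- pool_residue_embeddings(out, pool)
      out <- as.numeric(out)
      if (length(out) != embedder$dim) {
        stop("embedder returned length ", length(out), ", declared ", embedder$dim)
      }
      out
    }, error = function(e) structure(conditionMessage(e), class = "cazkit_fail"))
    if (inherits(res, "cazkit_fail")) {
      failures[id] <- unclass(res)
    } else {
      vecs[[i]] <- res
    }
  }
  if (length(failures) && !allow_partial) {
    stop("embedding failed for ", length(failures), " record(s): ",
      paste(utils::head(names(failures), 5), collapse = ", "),
      " (use allow_partial to keep successes)")
  }
  ok <- !vapply(vecs, is.null, TRUE)
  m <- if (any(ok)) do.call(rbind, vecs[ok]) else matrix(numeric(0), 0, embedder$dim)
  if (any(ok)) rownames(m) <- records$id[ok]
  out <- embedding_set(m, embedder$name)
  attr(out, "failures") <- failures
  out
}
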