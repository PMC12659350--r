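#' Prevalence filter
#'
#' Removes genes detected (nonzero) in fewer than `min_prev` of samples.
#' The removal is strict: a gene at exactly the threshold prevalence is
#' retained.
#'
#' @param counts gene x sample matrix of non-negative counts (rownames =
#'   gene ids, colnames = sample ids).
#' @param min_prev minimum prevalence fraction in (0, 1] (default 0.10).
#' @return the filtered matrix; attribute `removed` lists dropped genes.
#' @export
prevalence_filter <- function(counts, min_prev = 0.10) {
  stopifnot(min_prev > 0, min_prev <= 1)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  prev <- rowMeans(counts > 0)
  keep <- prev >= min_prev
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}

#' Zero-inflation imputation
#'
#' Replaces every zero in a gene's row by half that gene's minimum nonzero
#' value, leaving nonzero entries untouched. Genes must each have at least
#' one nonzero value — guaranteed when [prevalence_filter()] ran first; an
#' all-zero gene reaching this stage is a pipeline-order violation and an
#' error.
#'
#' @param counts gene x sample matrix after prevalence filtering.
#' @return matrix of the same shape with all entries strictly positive.
#' @export
zero_impute <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  all_zero <- rowSums(counts > 0) == 0L
  if (any(all_zero)) {
    stop("all-zero gene(s) reached imputation (run prevalence_filter first): ",
      paste(utils::head(rownames(counts)[all_zero], 5), collapse = ", "))
  }
  t(apply(counts, 1L, function(row) {
    row[row == 0] <- min(row[row > 0]) / 2
    row
  }))
}

#' Log2 fold change between groups
#'
#' `log2(mean(disease) / mean(control))` per gene, computed on the imputed
#' (strictly positive) matrix.
#'
#' @param counts imputed gene x sample matrix.
#' @param disease_samples,control_samples non-empty vectors of column ids.
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
log_fold_change <- function(counts, disease_samples, control_samples) {
  counts <- as.matrix(counts)
  if (!length(disease_samples) || !length(control_samples)) {
    stop("both groups must be non-empty")
  }
  if (any(counts <= 0)) stop("log_fold_change expects the imputed (positive) matrix")
  md <- rowMeans(counts[, disease_samples, drop = FALSE])
  mc <- rowMeans(counts[, control_samples, drop = FALSE])
  log2(md / mc)
}

#' Per-gene linear models on log2 z-scored abundances
#'
#' For each gene: log2-transform the imputed counts, z-score them within
#' the gene (sample standard deviation, n-1 denominator), and fit an
#' ordinary least-squares model of the transformed value on the disease
#' indicator plus the named covariates. The reported p-value is the
#' two-sided t-test on the disease coefficient; covariates act as
#' adjusters only. Genes with zero variance after transformation are
#' dropped (noted in the `dropped` attribute) rather than yielding NaN
#' statistics.
#'
#' @param counts imputed gene x sample matrix (strictly positive).
#' @param metadata data.frame with one row per sample (rownames = sample
#'   ids matching `colnames(counts)`), no missing values.
#' @param disease_col name of the binary disease column.
#' @param covariates character vector of covariate column names (numeric
#'   or binary).
#' @return data.frame `gene`, `estimate` (disease coefficient on the
#'   z-scale), `p`; collinear designs and missing metadata are errors.
#' @export
fit_gene_models <- function(counts, metadata, disease_col = "disease",
                            covariates = character(0)) {
  counts <- as.matrix(counts)
  if (any(counts <= 0)) {
    stop("fit_gene_models expects the imputed (strictly positive) matrix; ",
      "run prevalence_filter and zero_impute first")
  }
  need <- c(disease_col, covariates)
  missing_cols <- setdiff(need, names(metadata))
  if (length(missing_cols)) stop("metadata lacks column(s): ",
    paste(missing_cols, collapse = ", "))
  md <- metadata[colnames(counts), need, drop = FALSE]
  if (anyNA(md)) {
    bad <- need[vapply(md, anyNA, TRUE)]
    stop("missing metadata values in: ", paste(bad, collapse = ", "),
      " (no silent imputation)")
  }
  X <- stats::model.matrix(~ ., data = md)
  if (nrow(X) <= ncol(X)) stop("fewer samples than model parameters")
  if (qr(X)$rank < ncol(X)) {
    # name the aliased columns for the user
    qrX <- qr(X)
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("collinear design; aliased column(s): ",
      paste(aliased, collapse = ", "))
  }
  disease_term <- grep(paste0("^", disease_col), colnames(X), value = TRUE)[1L]
  logm <- log2(counts)
  sds <- apply(logm, 1L, stats::sd)
  dropped <- rownames(counts)[sds == 0]
  if (length(dropped)) {
    message(length(dropped), " zero-variance gene(s) dropped before modeling")
  }
  keep <- sds > 0
  logm <- logm[keep, , drop = FALSE]
  genes <- rownames(logm)
  est <- p <- numeric(length(genes))
  for (i in seq_along(genes)) {
    z <- (logm[i, ] - mean(logm[i, ])) / sds[keep][i]
    fit <- stats::lm(z ~ ., data = md)
    co <- summary(fit)$coefficients
    est[i] <- co[disease_term, "Estimate"]
    p[i] <- co[disease_term, "Pr(>|t|)"]
  }
  out <- data.frame(gene = genes, estimate = est, p = p,
    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotone enforcement, as
#' implemented by `stats::p.adjust(method = "BH")`, plus the significance
#' call at the chosen FDR.
#'
#' @param p numeric p-values, all in `[0, 1]`.
#' @param fdr significance level on the adjusted scale (default 0.25).
#' @return numeric q-values; attribute `significant` is the logical call
#'   `q <= fdr`.
#' @export
bh_adjust <- function(p, fdr = 0.25) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  attr(q, "significant") <- q <= fdr
  q
}

#' Volcano label rule sets
#'
#' A rule set is an ordered disjunction of clauses over (logFC, p); a gene
#' is labeled iff any clause holds. Two presets reproduce the labeling
#' criteria used for the Crohn's disease and IgG4-related disease
#' catalogs.
#'
#' @param name `"cd"`, `"igg4"`, or `"custom"` (then supply `clauses`).
#' @param clauses for `"custom"`: a list of lists with fields `logfc_op`
#'   (`">"` or `"<"`), `logfc_cut`, and optionally `p_cut` (p must be
#'   strictly below it).
#' @return an object of class `volcano_ruleset`.
#' @export
volcano_ruleset <- function(name = c("cd", "igg4", "custom"), clauses = NULL) {
  name <- match.arg(name)
  clause <- function(op, cut, p_cut = NULL) {
    list(logfc_op = op, logfc_cut = cut, p_cut = p_cut)
  }
  clauses <- switch(name,
    cd = list(
      clause(">", 0),
      clause("<", 0, 1e-8),
      clause("<", -4.5, 1e-3)
    ),
    igg4 = list(
      clause(">", 2, 1e-5),
      clause("<", -2, 10^-3.5),
      clause(">", 3, 10^-2.5),
      clause("<", -3.5, 1e-2)
    ),
    custom = {
      if (is.null(clauses)) stop("custom ruleset needs clauses")
      clauses
    }
  )
  structure(list(name = name, clauses = clauses), class = "volcano_ruleset")
}

#' Apply volcano labeling rules
#'
#' @param logfc,p aligned numeric vectors.
#' @param ruleset a [volcano_ruleset()].
#' @return logical vector: `TRUE` where any clause matches.
#' @export
volcano_labels <- function(logfc, p, ruleset) {
  stopifnot(inherits(ruleset, "volcano_ruleset"), length(logfc) == length(p))
  out <- rep(FALSE, length(logfc))
  for (cl in ruleset$clauses) {
    hit <- if (cl$logfc_op == ">") logfc > cl$logfc_cut else logfc < cl$logfc_cut
    if (!is.null(cl$p_cut)) hit <- hit & p < cl$p_cut
    out <- out | hit
  }
  out
}

#' Prioritize predicted CAZymes by fold change and prediction confidence
#'
#' For every gene with a family prediction, the priority is the mean of
#' (a) the percentile rank of its logFC among *all* genes in the result
#' set (rank normalized to `[0, 1]` as `(rank - 1) / (n - 1)`, average
#' ranks for ties) and (b) the predicted family probability. Genes without
#' a prediction are excluded (and noted).
#'
#' @param results data.frame with columns `gene` and `logFC` (the full
#'   result set; the percentile is computed over all of it).
#' @param predictions a `cazyme_predictions` data.frame (or any frame with
#'   `id`, `family`, `family_probability`).
#' @return data.frame `gene`, `logFC`, `logfc_percentile`, `family`,
#'   `family_probability`, `priority`, sorted by decreasing priority.
#' @export
prioritize <- function(results, predictions) {
  stopifnot(all(c("gene", "logFC") %in% names(results)))
  n <- nrow(results)
  pct <- if (n > 1) (rank(results$logFC, ties.method = "average") - 1) / (n - 1)
    else rep(1, n)
  m <- match(results$gene, predictions$id)
  fam_p <- predictions$family_probability[m]
  keep <- !is.na(m) & !is.na(fam_p)
  n_skipped <- sum(!keep)
  if (n_skipped) {
    message(n_skipped, " gene(s) without a family prediction excluded ",
      "from prioritization")
  }
  out <- data.frame(gene = results$gene[keep], logFC = results$logFC[keep],
    logfc_percentile = pct[keep],
    family = predictions$family[m[keep]],
    family_probability = fam_p[keep],
    priority = (pct[keep] + fam_p[keep]) / 2,
    stringsAsFactors = FALSE)
  out[order(-out$priority, out$gene), , drop = FALSE]
}

#' Differential-abundance workflow for a gene catalog
#'
#' Runs the full pipeline in its enforced order: prevalence filter ->
#' zero-inflation imputation -> per-group log2 fold change -> per-gene
#' OLS on log2 z-scored abundances with covariates -> Benjamini-Hochberg
#' correction -> volcano labels, and (when predictions are supplied)
#' CAZyme prioritization.
#'
#' @param counts gene x sample count matrix.
#' @param metadata sample metadata (rownames = sample ids); the
#'   `disease_col` column must be binary (0/1 or logical).
#' @param disease_col,covariates model terms, as in [fit_gene_models()].
#' @param min_prev prevalence threshold (default 0.10).
#' @param fdr FDR level for the significance call (default 0.25).
#' @param ruleset a [volcano_ruleset()] (default the CD preset).
#' @param predictions optional `cazyme_predictions` for prioritization.
#' @return an object of class `diff_result`: a data.frame `gene`, `logFC`,
#'   `estimate`, `p`, `q`, `significant`, `volcano_label`, plus attribute
#'   `priorities` when predictions were given.
#' @export
diff_abundance <- function(counts, metadata, disease_col = "disease",
                           covariates = character(0), min_prev = 0.10,
                           fdr = 0.25, ruleset = volcano_ruleset("cd"),
                           predictions = NULL) {
  m <- prevalence_filter(counts, min_prev)
  m <- zero_impute(m)
  disease <- metadata[colnames(m), disease_col]
  if (is.logical(disease)) disease <- as.integer(disease)
  if (!all(disease %in% c(0, 1))) stop(disease_col, " must be binary")
  lfc <- log_fold_change(m, colnames(m)[disease == 1], colnames(m)[disease == 0])
  fits <- fit_gene_models(m, metadata, disease_col, covariates)
  q <- bh_adjust(fits$p, fdr)
  out <- data.frame(gene = fits$gene, logFC = unname(lfc[fits$gene]),
    estimate = fits$estimate, p = fits$p, q = as.numeric(q),
    significant = attr(q, "significant"),
    stringsAsFactors = FALSE)
  out$volcano_label <- volcano_labels(out$logFC, out$p, ruleset)
  class(out) <- c("diff_result", "data.frame")
  attr(out, "fdr") <- fdr
  attr(out, "dropped") <- attr(fits, "dropped")
  if (!is.null(predictions)) {
    attr(out, "priorities") <- prioritize(out, predictions)
  }
  out
}

#' @export
print.diff_result <- function(x, ...) {
  cat("Differential abundance:", nrow(x), "genes tested;",
    sum(x$significant), "significant at q <=", attr(x, "fdr"), ";",
    sum(x$volcano_label), "volcano-labeled\n")
  invisible(x)
}
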