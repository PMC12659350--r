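#' Simulate Gaussian family clusters in embedding space
#'
#' The minimal structure under which both classifier stages should
#' succeed: class means placed on a sphere so that every pair of means is
#' at least `separation` within-class standard deviations apart, with
#' points drawn i.i.d. isotropic Gaussian (optionally heavier-tailed)
#' around their mean. Deterministic given the seed.
#'
#' @param n_classes number of planted families (>= 1).
#' @param n_per_class points per family (scalar or per-class vector).
#' @param dim embedding dimension (>= 2).
#' @param separation minimum pairwise mean distance in units of the
#'   within-class sigma.
#' @param sigma within-class standard deviation (default 1).
#' @param seed integer RNG seed.
#' @param labels class labels (default `GH1 ... GHn` style canonical
#'   family labels).
#' @param heavy_tailed draw points from a t distribution (df = 3) instead
#'   of Gaussian.
#' @param prefix id prefix for generated proteins.
#' @return list with `embeddings` ([embedding_set]), `labels` (named
#'   character vector id -> label), `ontology`, and `means`.
#' @export
simulate_embeddings <- function(n_classes, n_per_class, dim, separation,
                                sigma = 1, seed = 1L, labels = NULL,
                                heavy_tailed = FALSE, prefix = "prot") {
  stopifnot(n_classes >= 1L, dim >= 2L, separation >= 0, sigma > 0)
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, n_classes)
  stopifnot(length(n_per_class) == n_classes, all(n_per_class >= 1L))
  if (is.null(labels)) labels <- paste0("GH", seq_len(n_classes))
  set.seed(seed)
  if (n_classes == 1L) {
    means <- matrix(0, 1L, dim)
  } else {
    dirs <- matrix(stats::rnorm(n_classes * dim), n_classes, dim)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    d2 <- as.matrix(stats::dist(dirs))
    min_unit <- min(d2[upper.tri(d2)])
    if (min_unit < 1e-3) {
      stop("separation infeasible: drawn class directions nearly coincide ",
        "for n_classes = ", n_classes, ", dim = ", dim)
    }
    radius <- if (separation > 0) separation * sigma / min_unit else 1
    means <- dirs * radius
  }
  n_total <- sum(n_per_class)
  cls <- rep(seq_len(n_classes), n_per_class)
  noise <- if (heavy_tailed) {
    matrix(stats::rt(n_total * dim, df = 3) / sqrt(3), n_total, dim)
  } else {
    matrix(stats::rnorm(n_total * dim), n_total, dim)
  }
  X <- means[cls, , drop = FALSE] + sigma * noise
  ids <- sprintf("%s%04d", prefix, seq_len(n_total))
  rownames(X) <- ids
  lab <- stats::setNames(labels[cls], ids)
  list(
    embeddings = embedding_set(X, "simulated-gaussian"),
    labels = lab,
    ontology = family_ontology(labels, n_per_class),
    means = means
  )
}

#' Simulate protein sequences
#'
#' Random sequences over the 20 canonical amino acids, with optional
#' planted structure: mutated copies of seed sequences (for clustering
#' tests), a shared segment spliced into a subset (for homology-purge
#' tests), or a motif at a fixed position in a subset (for probe tests).
#' The truth of every planted feature is returned alongside the records.
#'
#' @param n number of base random sequences.
#' @param length sequence length (>= 10).
#' @param seed integer RNG seed.
#' @param n_seeds,copies_per_seed,mutation_rate when `n_seeds > 0`,
#'   additionally generate `n_seeds` seed sequences and
#'   `copies_per_seed` mutated copies of each, each position substituted
#'   independently with probability `mutation_rate`.
#' @param segment optional amino-acid string planted (substituted in at a
#'   random position) into `segment_ids` of the base sequences.
#' @param segment_ids how many base sequences receive the segment.
#' @param motif,motif_position optional motif planted at a fixed 1-based
#'   position in all base sequences.
#' @param prefix id prefix.
#' @return list with `records` ([protein_records]) and `truth`
#'   (data.frame `id`, `kind`, `seed_id`, `start`; one row per planted
#'   feature).
#' @export
simulate_sequences <- function(n = 0L, length = 100L, seed = 1L,
                               n_seeds = 0L, copies_per_seed = 0L,
                               mutation_rate = 0.1,
                               segment = NULL, segment_ids = 0L,
                               motif = NULL, motif_position = 1L,
                               prefix = "seq") {
  stopifnot(length >= 10L)
  len <- as.integer(length)
  rm(length)  # restore base::length inside this scope
  if (!is.null(segment) && nchar(segment) > len) {
    stop("segment longer than sequence")
  }
  if (!is.null(motif) && motif_position + nchar(motif) - 1L > len) {
    stop("motif longer than sequence at that position")
  }
  set.seed(seed)
  rand_seq <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")
  ids <- character(0)
  seqs <- character(0)
  truth <- list()
  if (n > 0L) {
    ids <- sprintf("%s%04d", prefix, seq_len(n))
    seqs <- vapply(seq_len(n), function(i) rand_seq(len), "")
    if (!is.null(motif)) {
      for (i in seq_len(n)) {
        substr(seqs[i], motif_position, motif_position + nchar(motif) - 1L) <- motif
        truth[[length(truth) + 1L]] <- data.frame(id = ids[i], kind = "motif",
          seed_id = NA_character_, start = motif_position,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(segment) && segment_ids > 0L) {
      pick <- sample.int(n, min(segment_ids, n))
      for (i in pick) {
        pos <- sample.int(len - nchar(segment) + 1L, 1L)
        substr(seqs[i], pos, pos + nchar(segment) - 1L) <- segment
        truth[[length(truth) + 1L]] <- data.frame(id = ids[i], kind = "segment",
          seed_id = NA_character_, start = pos, stringsAsFactors = FALSE)
      }
    }
  }
  if (n_seeds > 0L) {
    for (s in seq_len(n_seeds)) {
      seed_seq <- rand_seq(len)
      sid <- sprintf("%s_seed%02d", prefix, s)
      ids <- c(ids, sid)
      seqs <- c(seqs, seed_seq)
      for (cp in seq_len(copies_per_seed)) {
        chars <- strsplit(seed_seq, "")[[1L]]
        hit <- stats::runif(len) < mutation_rate
        if (any(hit)) {
          chars[hit] <- vapply(chars[hit], function(r) {
            sample(setdiff(AA20, r), 1L)
          }, "")
        }
        cid <- sprintf("%s_seed%02d_copy%02d", prefix, s, cp)
        ids <- c(ids, cid)
        seqs <- c(seqs, paste(chars, collapse = ""))
        truth[[length(truth) + 1L]] <- data.frame(id = cid, kind = "copy",
          seed_id = sid, start = NA_integer_, stringsAsFactors = FALSE)
      }
    }
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(0), kind = character(0),
      seed_id = character(0), start = integer(0), stringsAsFactors = FALSE)
  list(records = protein_records(ids, seqs), truth = truth_df)
}

#' Simulate a metagenomic gene-count matrix with planted effects
#'
#' Negative-binomial baseline counts (overdispersed, metagenome-like) with
#' lognormal per-gene abundances and per-sample depth factors. A stated
#' fraction of genes receives a multiplicative disease effect — a known
#' log2 fold change, or an effect calibrated per gene in units of its
#' log2-scale standard deviation (`effect_scale = "standardized"`).
#' Optional covariate effects and a planted low-prevalence gene subset
#' (for filter tests) are supported; the truth table records every
#' planted feature.
#'
#' @param n_genes,n_disease,n_control matrix dimensions (genes >= 2,
#'   samples >= 2 total).
#' @param seed integer RNG seed.
#' @param frac_differential fraction of genes given a disease effect.
#' @param effect effect size: log2 fold change (`effect_scale =
#'   "log2fc"`, default) or standardized effect on the log2 scale.
#' @param effect_scale `"log2fc"` or `"standardized"`.
#' @param baseline_meanlog,baseline_sdlog lognormal gene-abundance
#'   parameters.
#' @param dispersion negative-binomial dispersion (1/size); must be > 0.
#' @param depth_sdlog lognormal sd of per-sample depth factors.
#' @param covariate_effect optional multiplicative log2 effect of a
#'   simulated binary covariate (`cov1`) applied to the differential genes.
#' @param n_low_prevalence,low_prevalence plant this many genes whose
#'   detection rate is forced down to `low_prevalence`.
#' @return list with `counts` (gene x sample matrix), `metadata`
#'   (data.frame `disease`, `cov1`), and `truth` (data.frame `gene`,
#'   `log2fc`, `low_prevalence`).
#' @export
simulate_counts <- function(n_genes = 500L, n_disease = 40L, n_control = 40L,
                            seed = 1L, frac_differential = 0,
                            effect = 0, effect_scale = c("log2fc", "standardized"),
                            baseline_meanlog = log(50), baseline_sdlog = 1,
                            dispersion = 0.1, depth_sdlog = 0.2,
                            covariate_effect = 0,
                            n_low_prevalence = 0L, low_prevalence = 0.05) {
  effect_scale <- match.arg(effect_scale)
  stopifnot(n_genes >= 2L, n_disease + n_control >= 2L, dispersion > 0)
  set.seed(seed)
  n_samples <- n_disease + n_control
  samples <- sprintf("s%03d", seq_len(n_samples))
  genes <- sprintf("g%04d", seq_len(n_genes))
  disease <- rep(c(1L, 0L), c(n_disease, n_control))
  cov1 <- stats::rbinom(n_samples, 1L, 0.5)
  lambda <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  depth <- stats::rlnorm(n_samples, 0, depth_sdlog)
  n_diff <- round(frac_differential * n_genes)
  diff_idx <- if (n_diff > 0) sample.int(n_genes, n_diff) else integer(0)
  size <- 1 / dispersion

  mu <- outer(lambda, depth)
  counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = size),
    n_genes, n_samples, dimnames = list(genes, samples))
  counts <- counts * 1.0

  log2fc <- stats::setNames(rep(0, n_genes), genes)
  if (length(diff_idx) && effect != 0) {
    if (effect_scale == "log2fc") {
      delta <- rep(effect, length(diff_idx))
    } else {
      # calibrate per gene: effect in units of the gene's log2-scale sd,
      # measured on the imputed baseline counts
      delta <- vapply(diff_idx, function(g) {
        row <- counts[g, ]
        row[row == 0] <- min(row[row > 0], 1) / 2
        effect * stats::sd(log2(row))
      }, 1.0)
    }
    counts[diff_idx, disease == 1L] <-
      counts[diff_idx, disease == 1L] * 2^delta
    log2fc[diff_idx] <- delta
  }
  if (covariate_effect != 0 && length(diff_idx)) {
    counts[diff_idx, cov1 == 1L] <-
      counts[diff_idx, cov1 == 1L] * 2^covariate_effect
  }
  low_idx <- integer(0)
  if (n_low_prevalence > 0L) {
    low_idx <- setdiff(seq_len(n_genes), diff_idx)
    low_idx <- sample(low_idx, min(n_low_prevalence, length(low_idx)))
    for (g in low_idx) {
      zero_out <- stats::runif(n_samples) > low_prevalence
      counts[g, zero_out] <- 0
    }
  }
  metadata <- data.frame(disease = disease, cov1 = cov1, row.names = samples)
  truth <- data.frame(gene = genes, log2fc = unname(log2fc),
    low_prevalence = seq_len(n_genes) %in% low_idx,
    stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata, truth = truth)
}
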