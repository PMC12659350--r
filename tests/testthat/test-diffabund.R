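test_that("prevalence filter uses a strict <10% removal boundary", {
  m <- matrix(0, 3, 100, dimnames = list(c("nine", "ten", "zero"), paste0("s", 1:100)))
  m["nine", 1:9] <- 5
  m["ten", 1:10] <- 5
  out <- prevalence_filter(m, 0.10)
  expect_equal(rownames(out), "ten")
  expect_setequal(attr(out, "removed"), c("nine", "zero"))
})

test_that("prevalence filter counts match planted low-prevalence truth", {
  sim <- simulate_counts(n_genes = 500, n_disease = 50, n_control = 50,
    seed = 300, n_low_prevalence = 60, low_prevalence = 0.04)
  out <- prevalence_filter(sim$counts, 0.10)
  low <- sim$truth$gene[sim$truth$low_prevalence]
  # sparse genes fall below the filter; dense baseline genes survive
  expect_true(all(setdiff(rownames(sim$counts), low) %in% rownames(out)))
  expect_equal(sort(attr(out, "removed")), sort(setdiff(rownames(sim$counts),
    rownames(out))))
  expect_gt(length(intersect(attr(out, "removed"), low)), 50)
})

test_that("zero imputation replaces zeros by half the row minimum nonzero", {
  m <- matrix(c(0, 4, 8), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  expect_equal(unname(zero_impute(m)[1, ]), c(2, 4, 8))
  # rows without zeros are untouched
  m2 <- matrix(c(1, 4, 8, 0, 3, 9), 2, 3, byrow = TRUE,
    dimnames = list(c("a", "b"), paste0("s", 1:3)))
  imp <- zero_impute(m2)
  expect_equal(unname(imp["a", ]), c(1, 4, 8))
  expect_equal(unname(imp["b", ]), c(1.5, 3, 9))
  # random sparse matrix against a loop oracle
  set.seed(301)
  m3 <- matrix(rpois(50 * 20, 2), 50, 20,
    dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  m3 <- m3[rowSums(m3 > 0) > 0, ]
  imp3 <- zero_impute(m3)
  for (g in rownames(m3)) {
    row <- m3[g, ]
    want <- ifelse(row == 0, min(row[row > 0]) / 2, row)
    expect_equal(unname(imp3[g, ]), unname(want))
  }
  # all-zero gene reaching imputation is a pipeline-order violation
  bad <- rbind(m3, allzero = 0)
  expect_error(zero_impute(bad), "prevalence_filter")
})

test_that("log2 fold change is the log ratio of group means", {
  m <- matrix(c(8, 8, 2, 2, 5, 5, 5, 5), 2, 4, byrow = TRUE,
    dimnames = list(c("up", "flat"), paste0("s", 1:4)))
  lfc <- log_fold_change(m, c("s1", "s2"), c("s3", "s4"))
  expect_equal(unname(lfc["up"]), 2)
  expect_equal(unname(lfc["flat"]), 0)
  expect_error(log_fold_change(m, character(0), c("s1")), "non-empty")
  # planted 4x effect recovered within simulation error
  sim <- simulate_counts(n_genes = 400, n_disease = 40, n_control = 40,
    seed = 302, frac_differential = 0.25, effect = 2)
  m2 <- zero_impute(prevalence_filter(sim$counts))
  disease <- rownames(sim$metadata)[sim$metadata$disease == 1]
  control <- rownames(sim$metadata)[sim$metadata$disease == 0]
  lfc2 <- log_fold_change(m2, disease, control)
  planted <- intersect(sim$truth$gene[sim$truth$log2fc == 2], names(lfc2))
  expect_equal(mean(lfc2[planted]), 2, tolerance = 0.15)
  expect_equal(mean(lfc2[setdiff(names(lfc2), planted)]), 0, tolerance = 0.1)
})

test_that("per-gene models report the disease coefficient and catch bad designs", {
  sim <- simulate_counts(n_genes = 100, n_disease = 20, n_control = 20, seed = 303)
  m <- zero_impute(prevalence_filter(sim$counts))
  fits <- fit_gene_models(m, sim$metadata, "disease", "cov1")
  expect_true(all(c("gene", "estimate", "p") %in% names(fits)))
  expect_true(all(fits$p >= 0 & fits$p <= 1))
  # a covariate equal to the disease indicator is collinear
  md_bad <- sim$metadata
  md_bad$dup <- md_bad$disease
  expect_error(fit_gene_models(m, md_bad, "disease", "dup"), "collinear|aliased")
  # missing metadata is an error, never silently imputed
  md_na <- sim$metadata
  md_na$cov1[3] <- NA
  expect_error(fit_gene_models(m, md_na, "disease", "cov1"), "missing metadata")
  expect_error(fit_gene_models(m, sim$metadata, "disease", "nope"), "lacks column")
  # z-scoring: the reported p equals a plain two-sample regression t-test
  g <- rownames(m)[1]
  z <- scale(log2(m[g, ]))[, 1]
  ref <- summary(lm(z ~ disease + cov1, data = sim$metadata))$coefficients
  expect_equal(fits$p[fits$gene == g], ref["disease", "Pr(>|t|)"])
  expect_equal(fits$estimate[fits$gene == g], ref["disease", "Estimate"])
})

test_that("BH adjustment equals the textbook step-up oracle exactly", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(as.numeric(bh_adjust(p)), rep(0.04, 4))
  expect_equal(as.numeric(bh_adjust(0.37)), 0.37)
  set.seed(304)
  for (i in 1:10) {
    pv <- runif(100)
    expect_equal(as.numeric(bh_adjust(pv)), oracle_bh(pv))
  }
  pv1000 <- runif(1000)
  expect_equal(as.numeric(bh_adjust(pv1000)), oracle_bh(pv1000))
  # q is monotone in p ranks and never below p
  q <- as.numeric(bh_adjust(pv1000))
  expect_true(all(q[order(pv1000)] == cummax(q[order(pv1000)])))
  expect_true(all(q >= pv1000))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("volcano rule presets match their documented clauses", {
  cd <- volcano_ruleset("cd")
  expect_true(volcano_labels(0.5, 0.9, cd))          # logFC > 0 alone
  expect_false(volcano_labels(-1, 1e-7, cd))         # needs p < 1e-8
  expect_true(volcano_labels(-1, 1e-9, cd))
  expect_true(volcano_labels(-5, 1e-4, cd))          # logFC < -4.5 & p < 1e-3
  expect_false(volcano_labels(-5, 1e-2, cd))

  igg4 <- volcano_ruleset("igg4")
  expect_true(volcano_labels(2.5, 1e-6, igg4))       # logFC > 2 & p < 1e-5
  expect_false(volcano_labels(2.5, 1e-4, igg4))
  expect_true(volcano_labels(3.5, 1e-3, igg4))       # logFC > 3 & p < 1e-2.5
  expect_true(volcano_labels(-2.5, 1e-4, igg4))      # logFC < -2 & p < 1e-3.5
  expect_false(volcano_labels(-2.5, 10^-3.2, igg4))
  expect_true(volcano_labels(-4, 10^-2.5, igg4))     # logFC < -3.5 & p < 1e-2

  custom <- volcano_ruleset("custom",
    clauses = list(list(logfc_op = ">", logfc_cut = 1, p_cut = 0.05)))
  expect_equal(volcano_labels(c(2, 2, 0), c(0.01, 0.1, 0.01), custom),
    c(TRUE, FALSE, FALSE))
})

test_that("prioritization is the mean of logFC percentile and family probability", {
  res <- data.frame(gene = paste0("g", 1:5), logFC = c(3, 1, -1, 0, 2))
  preds <- data.frame(id = paste0("g", 1:5),
    family = "CE17", family_probability = c(1, 0.5, 0, 0.2, 0.8),
    stringsAsFactors = FALSE)
  pri <- prioritize(res, preds)
  # max logFC with probability 1 -> priority 1
  expect_equal(pri$priority[pri$gene == "g1"], 1)
  # min logFC with probability 0 -> priority 0
  expect_equal(pri$priority[pri$gene == "g3"], 0)
  # hand-computed mean of percentile and probability for the rest
  pct <- (rank(res$logFC) - 1) / 4
  want <- (pct + preds$family_probability) / 2
  expect_equal(pri$priority[match(res$gene, pri$gene)], want)
  expect_true(all(diff(pri$priority) <= 0))  # sorted descending
  # genes without a prediction are excluded with a message
  expect_message(pri2 <- prioritize(res, preds[1:3, ]), "excluded")
  expect_equal(nrow(pri2), 3L)
})

test_that("prioritization is monotone in both components", {
  set.seed(305)
  res <- data.frame(gene = paste0("g", 1:100), logFC = rnorm(100))
  prob <- runif(100)
  preds <- data.frame(id = res$gene, family = "GH1",
    family_probability = prob, stringsAsFactors = FALSE)
  pri <- prioritize(res, preds)
  # oracle: mean of rank-percentile and probability
  pct <- (rank(res$logFC, ties.method = "average") - 1) / 99
  expect_equal(pri$priority[match(res$gene, pri$gene)], (pct + prob) / 2)
  # increasing a component never decreases priority
  preds2 <- preds
  preds2$family_probability[7] <- min(1, preds$family_probability[7] + 0.1)
  pri2 <- prioritize(res, preds2)
  expect_gte(pri2$priority[pri2$gene == "g7"], pri$priority[pri$gene == "g7"])
})

test_that("the full workflow runs in order and flags significance at the FDR", {
  sim <- simulate_counts(n_genes = 300, n_disease = 30, n_control = 30,
    seed = 306, frac_differential = 0.1, effect = 3)
  res <- diff_abundance(sim$counts, sim$metadata, covariates = "cov1",
    ruleset = volcano_ruleset("cd"))
  expect_s3_class(res, "diff_result")
  expect_true(all(res$q >= res$p))
  expect_identical(res$significant, res$q <= 0.25)
  planted <- sim$truth$gene[sim$truth$log2fc != 0]
  expect_gt(mean(res$significant[res$gene %in% planted]), 0.9)
  # the imputed matrix is required downstream: raw zeros error out
  expect_error(fit_gene_models(prevalence_filter(sim$counts), sim$metadata,
    "disease", "cov1"), "imputed")
  expect_error(log_fold_change(prevalence_filter(sim$counts),
    rownames(sim$metadata)[1:5], rownames(sim$metadata)[6:10]), "imputed")
})
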