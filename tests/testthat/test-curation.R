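test_that("labeled FASTA parsing handles labels, counts and malformed input", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1|GH43_18", "MKV", ">seq2", "MAAA", ">seq3|GH1|CE2", "MML"), tf)
  r <- parse_labeled_fasta(tf)
  expect_equal(r$id, c("seq1", "seq2", "seq3"))
  expect_equal(r$labels[[1]], "GH43_18")
  expect_equal(r$labels[[2]], character(0))
  expect_equal(sort(r$labels[[3]]), c("CE2", "GH1"))

  # empty file -> empty set
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_equal(nrow(parse_labeled_fasta(empty)), 0L)

  # sequence before first header -> parse error with line number
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKVVV", ">s1", "MA"), bad)
  expect_error(parse_labeled_fasta(bad), "line 1")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "MA", ">s1", "ML"), dup)
  expect_error(parse_labeled_fasta(dup), "duplicate.*s1")
})

test_that("a generated multi-label FASTA round-trips with the right label counts", {
  sim <- simulate_sequences(n = 100, length = 40, seed = 31)
  recs <- sim$records
  # plant labels: 3 records multi-label, the rest single or none
  recs$labels[[5]] <- c("GH1", "GH2")
  recs$labels[[10]] <- c("CE2", "PL1_2")
  recs$labels[[20]] <- c("GT4", "GH13_5")
  for (i in c(1, 2, 3)) recs$labels[[i]] <- "GH5"
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_labeled_fasta(recs, tf)
  back <- parse_labeled_fasta(tf)
  expect_equal(nrow(back), 100L)
  expect_equal(sum(vapply(back$labels, length, 1L) > 1L), 3L)
  # independent text scan of the written file agrees
  headers <- grep("^>", readLines(tf), value = TRUE)
  expect_equal(sum(lengths(regmatches(headers, gregexpr("\\|", headers))) > 1L), 3L)
  expect_equal(back$sequence, recs$sequence)
})

test_that("length filter removes strictly-overlength sequences only", {
  r <- protein_records(c("keep", "drop"),
    c(strrep("A", 5000), strrep("A", 5001)))
  out <- filter_records(r, max_len = 5000)
  expect_equal(out$id, "keep")
  expect_equal(unname(attr(out, "removed")["overlength"]), 1L)
  expect_equal(nrow(filter_records(protein_records(character(0), character(0)))), 0L)
})

test_that("length filter counts match a brute-force scan on a generated set", {
  sim <- simulate_sequences(n = 200, length = 60, seed = 7)
  recs <- sim$records
  # make 13 of them overlength
  set.seed(8)
  long_idx <- sample(200, 13)
  recs$sequence[long_idx] <- strrep("M", 120)
  out <- filter_records(recs, max_len = 100)
  expect_equal(nrow(out), 187L)
  expect_equal(nrow(out), sum(nchar(recs$sequence) <= 100))
})

test_that("class dropping keeps records with at least one other label", {
  r <- protein_records(c("a", "b", "c"), c("MK", "ML", "MV"),
    labels = list("GT2", c("GT2", "GH1"), "GH3"))
  out <- filter_records(r, drop_classes = "GT", require_label = TRUE)
  expect_equal(out$id, c("b", "c"))
  expect_equal(out$labels[[1]], "GH1")
})

test_that("deduplication keeps one representative per sequence and is idempotent", {
  r <- protein_records(c("b", "a"), c("MKV", "MKV"))
  out <- deduplicate(r)
  expect_equal(out$id, "a")  # lexicographically smallest id wins

  distinct <- protein_records(c("x", "y"), c("MA", "ML"))
  expect_equal(deduplicate(distinct)$id, c("x", "y"))

  # 50 records with 10 planted duplicate pairs -> 40 survivors (hash oracle)
  sim <- simulate_sequences(n = 40, length = 30, seed = 12)
  recs <- sim$records
  dup <- protein_records(paste0("dup", 1:10), recs$sequence[1:10])
  all50 <- protein_records(c(recs$id, dup$id), c(recs$sequence, dup$sequence))
  out50 <- deduplicate(all50)
  expect_equal(nrow(out50), length(unique(all50$sequence)))
  expect_equal(nrow(out50), 40L)
  expect_identical(deduplicate(out50), out50)
})

test_that("deduplication merges labels of identical sequences", {
  r <- protein_records(c("a", "b"), c("MKV", "MKV"),
    labels = list("GH1", "CE2"))
  expect_equal(sort(deduplicate(r)$labels[[1]]), c("CE2", "GH1"))
})

test_that("identity clustering recovers planted cluster structure", {
  # two identical sequences -> one cluster
  same <- protein_records(c("a", "b"), rep(strrep("MKVLIDEW", 8), 2))
  expect_equal(nrow(cluster_identity(same)$representatives), 1L)

  # two random length-100 sequences -> identity far below 0.6 -> 2 clusters
  rnd <- simulate_sequences(n = 2, length = 100, seed = 44)$records
  idv <- pairwise_identity(rnd$sequence[1], rnd$sequence[2])$identity
  expect_lt(idv, 0.6)
  expect_equal(nrow(cluster_identity(rnd)$representatives), 2L)

  # 30 sequences = 3 seeds x (1 + 9 mutated copies, <= 20% mutations)
  sim <- simulate_sequences(n_seeds = 3, copies_per_seed = 9,
    mutation_rate = 0.15, length = 80, seed = 45)
  cl <- cluster_identity(sim$records, threshold = 0.60)
  expect_equal(nrow(cl$representatives), 3L)
  # members cluster with their own seed family
  fam_of <- function(id) sub("_copy[0-9]+$", "", id)
  expect_equal(fam_of(cl$members$member_id), fam_of(cl$members$representative_id))
  # post-hoc: no two representatives above threshold (same identity_fn)
  reps <- cl$representatives$sequence
  for (i in seq_along(reps)) for (j in seq_len(i - 1L)) {
    expect_lte(pairwise_identity(reps[i], reps[j])$identity, 0.60)
  }
  # every non-representative is above threshold to its representative
  mem <- cl$members[!cl$members$member_id %in% cl$representatives$id, ]
  expect_true(all(mem$identity > 0.60))
})

test_that("homolog purge removes planted chimeras and spares unrelated negatives", {
  pos <- simulate_sequences(n = 10, length = 100, seed = 50, prefix = "pos")$records
  pos$labels <- rep(list("GH1"), nrow(pos))

  # a negative identical to a positive is removed
  neg0 <- protein_records(c("n1", "n2"), c(pos$sequence[1],
    simulate_sequences(n = 1, length = 100, seed = 51)$records$sequence))
  purged0 <- purge_homologs(neg0, pos)
  expect_equal(purged0$id, "n2")

  # random unrelated negatives survive untouched; no shared 8-mers exist
  neg1 <- simulate_sequences(n = 30, length = 80, seed = 52, prefix = "neg")$records
  expect_length(kmer_homology_search(neg1, pos, confirm = FALSE), 0L)
  expect_equal(purge_homologs(neg1, pos)$id, neg1$id)

  # 100 negatives, 15 with a planted 40-aa positive segment -> 85 retained
  segment <- substr(pos$sequence[3], 11, 50)
  sim <- simulate_sequences(n = 100, length = 80, seed = 53,
    segment = segment, segment_ids = 15, prefix = "neg")
  purged <- purge_homologs(sim$records, pos)
  expect_equal(nrow(purged), 85L)
  expect_setequal(attr(purged, "removed_ids"),
    sim$truth$id[sim$truth$kind == "segment"])
})

test_that("purge aborts on search failure instead of keeping negatives silently", {
  pos <- protein_records("p", strrep("MKVLY", 10), labels = list("GH1"))
  neg <- protein_records("n", strrep("AWDEF", 10))
  expect_error(
    purge_homologs(neg, pos, search = function(...) stop("boom")),
    "aborting purge")
  expect_error(purge_homologs(pos, pos), "share ids")
})

test_that("ambiguity letters fold to X for identity computation", {
  a <- "MKVLIDEWMKVLIDEW"
  b <- "MKVLIDEBMKVLIDEZ"  # B/Z are ambiguity codes
  idv <- pairwise_identity(a, b)$identity
  expect_equal(idv, 14 / 16)
})
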