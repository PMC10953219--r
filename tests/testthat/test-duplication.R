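test_that("paralog calling applies the identity and e-value thresholds", {
  set.seed(41)
  a <- random_protein(200)
  recs <- data.frame(id = c("g2", "g1"), sequence = c(a, a),
                     stringsAsFactors = FALSE)
  pairs <- call_paralog_pairs(recs)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$gene_a, "g1")   # lexicographic order
  expect_equal(pairs$identity, 1.0)

  unrelated <- data.frame(id = c("u1", "u2"),
                          sequence = c(random_protein(200), random_protein(200)),
                          stringsAsFactors = FALSE)
  expect_equal(nrow(call_paralog_pairs(unrelated)), 0)

  # borderline engineering: exactly 160/200 = 80.0% identity is called,
  # one extra mismatch (159/200 = 79.5%) is not
  b80 <- mutate_protein(a, 40)
  expect_equal(global_align(a, b80)$identity, 0.80)
  called <- call_paralog_pairs(
    data.frame(id = c("a", "b"), sequence = c(a, b80), stringsAsFactors = FALSE)
  )
  expect_equal(nrow(called), 1)
  b79 <- mutate_protein(b80, 1)
  while (global_align(a, b79)$identity != 159 / 200) b79 <- mutate_protein(b80, 1)
  not_called <- call_paralog_pairs(
    data.frame(id = c("a", "b"), sequence = c(a, b79), stringsAsFactors = FALSE)
  )
  expect_equal(nrow(not_called), 0)
})

test_that("duplication classes follow the single 5 Mb boundary", {
  mk <- function(id, chrom, s, e) gene_model(id, chrom, s, e)
  a <- mk("a", "2", 1e6, 1.01e6)
  expect_equal(classify_duplication(a, mk("b", "2", 2.01e6, 2.02e6)), "tandem")
  expect_equal(classify_duplication(a, mk("b", "2", 7.02e6, 7.03e6)), "segmental")
  expect_equal(classify_duplication(a, mk("b", "7", 1e6, 1.01e6)), "segmental")
  expect_equal(classify_duplication(a, mk("b", "0", 1e6, 1.01e6)), "segmental")
  # nearest-edge rule: exactly at the cutoff is tandem
  b <- mk("b", "2", 1.01e6 + 5e6, 1.02e6 + 5e6)
  expect_equal(classify_duplication(a, b), "tandem")
  # overlapping genes have zero edge distance
  expect_equal(classify_duplication(a, mk("b", "2", 1.005e6, 1.02e6)), "tandem")
})

test_that("synthetic family pairs are fully recovered with true classes", {
  fam <- simulate_family(list(n_decoys = 2L), seed = 7)
  truth <- fam$truth$pair_truth
  # layout combinatorics: 2 clusters of 3 -> 2*C(3,2) = 6 tandem + 2 segmental
  expect_equal(sum(truth$true_class == "tandem"), 6)
  expect_equal(sum(truth$true_class == "segmental"), 2)
  expect_equal(nrow(truth), 8)
  for (i in seq_len(nrow(truth))) {
    got <- classify_duplication(fam$genes[[truth$gene_a[i]]],
                                fam$genes[[truth$gene_b[i]]])
    expect_equal(got, truth$true_class[i])
  }
  # referential integrity of the truth file
  expect_true(all(truth$gene_a %in% fam$proteins$id))
  expect_true(all(truth$gene_b %in% fam$cds$id))
  expect_true(all(rownames(fam$truth$element_truth) %in% names(fam$contigs)))
})

test_that("paralog table carries coordinates, class, Ka/Ks and dating", {
  fam <- simulate_family(list(n_decoys = 0L, n_tandem_clusters = 1L,
                              tandem_cluster_size = 2L,
                              n_segmental_pairs = 1L), seed = 8)
  tab <- paralog_pair_table(fam$proteins, fam$cds, fam$genes)
  truth <- fam$truth$pair_truth
  expect_true(nrow(tab) >= nrow(truth))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(truth$gene_a, truth$gene_b), key(tab$gene_1, tab$gene_2))
  expect_false(anyNA(m))
  expect_equal(tab$dup_class[m], truth$true_class)
  expect_true(all(tab$t_years >= 0))
  expect_equal(tab$t_years, tab$ks / (2 * 6.5e-9))
  expect_true(all(tab$evalue <= 1e-10))
  expect_true(all(tab$identity >= 0.8))
})

test_that("reciprocal best hits recover a known one-to-one mapping", {
  set.seed(44)
  anc <- replicate(5, random_protein(80))
  A <- data.frame(id = paste0("a", 1:5),
                  sequence = vapply(anc, function(s) mutate_protein(s, 4), ""),
                  stringsAsFactors = FALSE)
  B <- data.frame(id = paste0("b", 1:5),
                  sequence = vapply(anc, function(s) mutate_protein(s, 4), ""),
                  stringsAsFactors = FALSE)
  # decoy with no partner
  B <- rbind(B, data.frame(id = "b_decoy", sequence = random_protein(80)))
  rbh <- reciprocal_best_hits(A, B)
  expect_equal(nrow(rbh), 5)
  expect_equal(rbh$id_b[match(paste0("a", 1:5), rbh$id_a)], paste0("b", 1:5))

  ident <- data.frame(id = c("p1", "p2"),
                      sequence = c(random_protein(60), random_protein(60)),
                      stringsAsFactors = FALSE)
  self <- reciprocal_best_hits(ident, transform(ident, id = c("q1", "q2")))
  expect_equal(nrow(self), 2)
  expect_equal(self$id_b, c("q1", "q2"))
})
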