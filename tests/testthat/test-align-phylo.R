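test_that("global alignment matches identity case and tiny DP oracle", {
  B62 <- blosum62()
  p <- "MKVLINWAGRE"
  al <- global_align(p, p)
  expect_equal(al$identity, 1.0)
  expect_equal(al$score,
               sum(diag(B62[strsplit(p, "")[[1]], strsplit(p, "")[[1]]])))

  # single-column gap case against a plain DP oracle (gap column costs
  # open + extend)
  al2 <- global_align("ACDEFG", "ACDFG", gap_open = 10, gap_extend = 1)
  oracle <- nw_score_oracle("ACDEFG", "ACDFG", B62, gap_col_cost = 11)
  expect_equal(al2$score, oracle)
  expect_equal(nchar(al2$aligned_a), nchar(al2$aligned_b))
  expect_equal(gsub("-", "", al2$aligned_b), "ACDFG")

  # symmetry of score and identity
  set.seed(11)
  for (k in 1:5) {
    a <- random_protein(40); b <- mutate_protein(a, 8)
    f <- global_align(a, b); r <- global_align(b, a)
    expect_equal(f$score, r$score)
    expect_equal(f$identity, r$identity)
  }
  expect_error(global_align("ACGT", "MKVW"), "mixed")
})

test_that("e-value proxy follows the Karlin-Altschul form", {
  e1 <- evalue_proxy(100, 500, 500)
  e2 <- evalue_proxy(150, 500, 500)
  expect_gt(e1, e2)
  expect_equal(evalue_proxy(200, 500, 500, 1, 0.267, 0.041),
               0.041 * 250000 * exp(-53.4))
  expect_equal(evalue_proxy(1e6, 10, 10), 0)
  expect_error(evalue_proxy(10, 0, 5), ">= 1")
})

test_that("distance matrix implements p and Poisson models", {
  msa <- rbind(
    a = strsplit("AAAAAAAAAA", "")[[1]],
    b = strsplit("AAAAAAAAAC", "")[[1]],
    c = strsplit("AAAAAAAAAA", "")[[1]]
  )
  D <- distance_matrix(msa, "p")
  expect_equal(D["a", "b"], 0.1)
  expect_equal(D["a", "c"], 0)
  expect_true(isSymmetric(D))
  Dp <- distance_matrix(msa, "poisson")
  expect_equal(Dp["a", "b"], -log(0.9))

  gapped <- rbind(a = c("A", "-"), b = c("-", "A"))
  expect_error(distance_matrix(gapped, "p"), "comparable")
  sat <- rbind(a = c("A", "A"), b = c("C", "C"))
  expect_error(distance_matrix(sat, "poisson"), "undefined")
})

test_that("neighbor joining: closed forms and exactness on additive matrices", {
  D2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(D2)
  expect_equal(sort(t2$edge.length), c(0.5, 0.5))

  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(D3)
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  set.seed(99)
  for (rep in 1:10) {
    cs <- random_additive_case(sample(6:10, 1))
    nj <- neighbor_joining(cs$D)
    expect_setequal(tree_bipartitions(nj), tree_bipartitions(cs$tree))
    Dhat <- ape::cophenetic.phylo(nj)
    Dhat <- Dhat[rownames(cs$D), colnames(cs$D)]
    expect_lt(max(abs(Dhat - cs$D)), 1e-9)
    # independent reconstruction cross-check
    ref <- ape::nj(cs$D)
    expect_setequal(tree_bipartitions(nj), tree_bipartitions(ref))
  }
  bad <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(bad), "NaN|NA")
})

test_that("bootstrap supports behave with strong and absent signal", {
  # 20 congruent binary columns split (a,b) | (c,d): every resample keeps it
  strong <- rbind(
    a = rep(c("A", "C"), 10), b = rep(c("A", "C"), 10),
    c = rep(c("T", "G"), 10), d = rep(c("T", "G"), 10)
  )
  tr <- bootstrap_support(strong, n_reps = 50, seed = 3, model = "p")
  sup <- suppressWarnings(as.integer(tr$node.label[nzchar(tr$node.label)]))
  expect_true(all(sup == 100))
  expect_true(all(sup >= 0 & sup <= 100))

  # determinism under the seed
  tr2 <- bootstrap_support(strong, n_reps = 50, seed = 3, model = "p")
  expect_identical(tr$node.label, tr2$node.label)

  # mean support strictly higher with signal than with random columns
  set.seed(5)
  mean_sup <- function(m, seeds) {
    mean(vapply(seeds, function(s) {
      t <- bootstrap_support(m, n_reps = 30, seed = s, model = "p")
      v <- suppressWarnings(as.integer(t$node.label[nzchar(t$node.label)]))
      if (length(v) == 0) 0 else mean(v)
    }, 0))
  }
  noise <- matrix(sample(c("A", "C", "G", "T"), 4 * 20, replace = TRUE), 4, 20,
                  dimnames = list(c("a", "b", "c", "d"), NULL))
  expect_gt(mean_sup(strong, 1:10), mean_sup(noise, 1:10))
  expect_error(bootstrap_support(strong[1:3, ], 10, 1), ">= 4")
})

test_that("two-group split at the longest internal edge labels every leaf", {
  tr <- ape::read.tree(text = "((A:1,B:1):5,(C:1,(D:1,E:1):0.5):1);")
  g <- group_by_longest_edge(tr)
  expect_setequal(names(g), c("A", "B", "C", "D", "E"))
  expect_equal(sort(unique(g)), c("main", "sub"))
  # the long edge separates {A,B}; the larger side is main
  expect_true(all(g[c("C", "D", "E")] == "main"))
  expect_true(all(g[c("A", "B")] == "sub"))
})
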