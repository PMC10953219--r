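test_that("molecular weight matches the mass table and is additive", {
  expect_equal(molecular_weight("G"), (57.0519 + 18.0153) / 1000)
  expect_equal(molecular_weight("GG"), (2 * 57.0519 + 18.0153) / 1000)
  set.seed(31)
  a <- random_protein(25); b <- random_protein(40)
  expect_equal(molecular_weight(paste0(a, b)),
               molecular_weight(a) + molecular_weight(b) - 18.0153 / 1000)
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("GXG"), "undefined.*'X'")
})

test_that("isoelectric point solves the charge equation", {
  set.seed(32)
  for (seq in c("GG", "KKKKKK", "DDDDDD", random_protein(80))) {
    pi <- isoelectric_point(seq)
    expect_lt(abs(protein_charge(seq, pi)), 1e-4)
  }
  expect_gt(isoelectric_point("KKKKKK"), isoelectric_point("DDDDDD"))

  # composition-only: invariant under permutation
  s <- "MKDDERHYACK"
  s2 <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(isoelectric_point(s), isoelectric_point(s2))

  # termini-only case against an independent root finder
  root <- uniroot(function(ph) protein_charge("GG", ph),
                  c(0, 14), tol = 1e-10)$root
  expect_equal(isoelectric_point("GG"), root, tolerance = 1e-3)
})

test_that("redundancy reduction clusters by identity, order-independently", {
  a <- random_protein(60)
  recs <- data.frame(id = c("x", "y"), sequence = c(a, a),
                     stringsAsFactors = FALSE)
  r <- reduce_redundancy(recs, 1.0)
  expect_equal(nrow(r$kept), 1)
  expect_setequal(r$clusters[[1]], c("x", "y"))

  set.seed(33)
  b <- mutate_protein(a, 30)    # ~50% identity
  r2 <- reduce_redundancy(
    data.frame(id = c("x", "y"), sequence = c(a, b), stringsAsFactors = FALSE),
    0.9
  )
  expect_equal(nrow(r2$kept), 2)

  # A ~ B at ~95%, C distinct; brute-force identities confirm the clusters
  A <- random_protein(100); B <- mutate_protein(A, 5); C <- random_protein(100)
  idAB <- global_align(A, B)$identity
  idAC <- global_align(A, C)$identity
  expect_gt(idAB, 0.9); expect_lt(idAC, 0.9)
  df <- data.frame(id = c("A", "B", "C"), sequence = c(A, B, C),
                   stringsAsFactors = FALSE)
  r3 <- reduce_redundancy(df, 0.9)
  expect_equal(nrow(r3$kept), 2)
  perm <- df[c(3, 1, 2), ]
  r4 <- reduce_redundancy(perm, 0.9)
  expect_setequal(r3$kept$id, r4$kept$id)

  empty <- df[0, ]
  expect_equal(nrow(reduce_redundancy(empty, 1.0)$kept), 0)
})

test_that("domain scanner finds planted consensus windows and nothing else", {
  prof <- domain_profile("DEXDC", "LDEADRMW", 8L)
  set.seed(34)
  left <- random_protein(40); right <- random_protein(40)
  target <- paste0(left, "LDEADRMW", right)
  hits <- scan_domains(target, list(prof))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$matches, 8)
  expect_equal(hits$start, 41)
  expect_equal(hits$end, 48)

  # mismatch-tolerant profile: plant 2 mismatches, lower min_score
  prof2 <- domain_profile("DEXDC", "LDEADRMW", 6L)
  mut <- paste0(left, "LDEVDRMA", right)  # 2 mismatches
  hits2 <- scan_domains(mut, list(prof2))
  # enumerate all windows by hand to confirm uniqueness of the best hit
  win_scores <- vapply(seq_len(nchar(mut) - 7), function(s) {
    sum(strsplit(substr(mut, s, s + 7), "")[[1]] ==
          strsplit("LDEADRMW", "")[[1]])
  }, 0)
  expect_equal(nrow(hits2), sum(win_scores >= 6))
  expect_equal(hits2$matches, 6)

  # rejection-checked background yields zero hits
  repeat {
    bg <- random_protein(120)
    sc <- vapply(seq_len(nchar(bg) - 7), function(s) {
      sum(strsplit(substr(bg, s, s + 7), "")[[1]] ==
            strsplit("LDEADRMW", "")[[1]])
    }, 0)
    if (max(sc) < 6) break
  }
  expect_equal(nrow(scan_domains(bg, list(prof2))), 0)

  # X wildcard matches anything; profile longer than protein is no hit
  profx <- domain_profile("W", "AXXXA", 5L)
  expect_equal(scan_domains("CCAGGGACC", list(profx))$matches, 5)
  expect_equal(nrow(scan_domains("AG", list(prof))), 0)
})

test_that("chromosome distribution reports counts, percents and unassigned", {
  labs <- c(rep("A", 4), rep("B", 4))
  d <- chromosome_distribution(labs)
  expect_equal(d$counts$percent, c(50, 50))
  expect_equal(d$unassigned, 0)

  set.seed(35)
  labs2 <- c(sample(as.character(1:7), 60, replace = TRUE), rep("0", 3))
  d2 <- chromosome_distribution(labs2)
  expect_equal(sum(d2$counts$count), 60)
  expect_equal(d2$unassigned, 3)
  expect_true(abs(sum(d2$counts$percent) - 100) <= 1 + nrow(d2$counts) / 2)
  expect_error(chromosome_distribution(character(0)), "empty")
})

test_that("protein properties table combines length, MW and pI", {
  df <- data.frame(id = c("p1", "p2"),
                   sequence = c("GG", "KKKKKK"), stringsAsFactors = FALSE)
  pr <- protein_properties(df)
  expect_equal(pr$length_aa, c(2, 6))
  expect_equal(pr$mw_kda[1], molecular_weight("GG"))
  expect_true(all(pr$pi > 0 & pr$pi < 14))
})
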