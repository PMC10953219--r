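# Shared oracles and generators, independent of the implementation paths
# they check.

# plain Needleman-Wunsch where a gap column costs open + extend (adequate
# oracle for tiny cases whose optimal gaps have length 1)
nw_score_oracle <- function(a, b, mat, gap_col_cost) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  F <- matrix(-Inf, n + 1, m + 1)
  F[1, ] <- -(0:m) * gap_col_cost
  F[, 1] <- -(0:n) * gap_col_cost
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      F[i + 1, j + 1] <- max(
        F[i, j] + mat[ca[i], cb[j]],
        F[i, j + 1] - gap_col_cost,
        F[i + 1, j] - gap_col_cost
      )
    }
  }
  F[n + 1, m + 1]
}

# 9-neighbor site enumeration using Biostrings' genetic code table
# (independent of the package's own code table)
ng86_sites_oracle <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == b) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (gc[[mut]] == aa) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

sense_codons_oracle <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# random unrooted tree with strictly positive branch lengths and its
# additive (path-length) distance matrix
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

random_cds_oracle <- function(n_codons) {
  paste(sample(sense_codons_oracle(), n_codons, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","E","Q","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")
}

# mutate exactly k positions of a protein to different residues
mutate_protein <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(chars), k)
  aas <- c("A","R","N","D","C","E","Q","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  for (p in pos) chars[p] <- sample(setdiff(aas, chars[p]), 1)
  paste(chars, collapse = "")
}
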