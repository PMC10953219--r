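#' Optimal global pairwise alignment under affine gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment (via Biostrings). A gap of length L
#' costs `gap_open + L * gap_extend`. Identity is the fraction of
#' identical columns over aligned columns, excluding terminal-gap columns
#' from the denominator (full-length homologs of different lengths are not
#' penalized for overhangs).
#'
#' @param a,b sequences of one alphabet (both protein or both DNA).
#' @param substitution_matrix scoring matrix; default BLOSUM62 for protein,
#'   +1/-1 match/mismatch for DNA.
#' @param gap_open,gap_extend affine gap parameters (positive costs).
#' @param alphabet `"protein"` or `"dna"`; guessed from the residues when
#'   missing.
#' @return list of class `pairwise_alignment`: `aligned_a`, `aligned_b`,
#'   `score`, `identity`, `n_identical`, `n_aligned_cols`.
#' @export
global_align <- function(a, b, substitution_matrix = NULL,
                         gap_open = 10, gap_extend = 1,
                         alphabet = NULL) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  if (is.null(alphabet)) {
    is_dna <- function(x) all(strsplit(x, "")[[1]] %in% c("A", "C", "G", "T"))
    da <- is_dna(a); db <- is_dna(b)
    if (da != db) stop("mixed alphabets", call. = FALSE)
    alphabet <- if (da) "dna" else "protein"
  }
  if (is.null(substitution_matrix)) {
    if (alphabet == "protein") {
      substitution_matrix <- blosum62()
    } else {
      substitution_matrix <- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE
      )
    }
  }
  xs <- if (alphabet == "protein") Biostrings::AAString(a) else Biostrings::DNAString(a)
  ys <- if (alphabet == "protein") Biostrings::AAString(b) else Biostrings::DNAString(b)
  al <- Biostrings::pairwiseAlignment(
    xs, ys, type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aa <- as.character(Biostrings::pattern(al))
  ab <- as.character(Biostrings::subject(al))
  id <- alignment_identity(aa, ab)
  structure(
    list(aligned_a = aa, aligned_b = ab,
         score = Biostrings::score(al),
         identity = id$identity,
         n_identical = id$n_identical,
         n_aligned_cols = id$n_cols),
    class = "pairwise_alignment"
  )
}

#' BLOSUM62 substitution matrix
#' @return the BLOSUM62 matrix shipped with Biostrings.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Identity of an aligned pair
#'
#' Identical columns / aligned columns, where terminal-gap columns (a
#' leading or trailing run of gaps in either row) and dual-gap columns are
#' excluded from the denominator.
#'
#' @param aligned_a,aligned_b equal-length gapped strings.
#' @return list `identity`, `n_identical`, `n_cols`.
#' @export
alignment_identity <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  if (length(ca) != length(cb)) stop("aligned strings differ in length", call. = FALSE)
  n <- length(ca)
  core <- rep(TRUE, n)
  for (ch in list(ca, cb)) {
    nong <- which(ch != "-")
    if (length(nong) == 0) { core[] <- FALSE; break }
    core[seq_len(n) < min(nong) | seq_len(n) > max(nong)] <- FALSE
  }
  core <- core & !(ca == "-" & cb == "-")
  ident <- sum(core & ca == cb)
  cols <- sum(core)
  list(identity = if (cols == 0) 0 else ident / cols,
       n_identical = ident, n_cols = cols)
}

#' Karlin-Altschul style e-value proxy for a global alignment score
#'
#' `E = K * len_a * len_b * n_comparisons * exp(-lambda * score)`. This is
#' an explicit stand-in for a BLAST e-value with gapped BLOSUM62 folklore
#' constants as defaults; the survey's 1e-10 cutoff is applied to it.
#'
#' @param score alignment score.
#' @param len_a,len_b sequence lengths (>= 1).
#' @param n_comparisons database-size factor.
#' @param ka_lambda,ka_k Karlin-Altschul parameters.
#' @return e-value (positive real).
#' @export
evalue_proxy <- function(score, len_a, len_b, n_comparisons = 1,
                         ka_lambda = 0.267, ka_k = 0.041) {
  if (any(c(len_a, len_b) < 1)) stop("lengths must be >= 1", call. = FALSE)
  ka_k * len_a * len_b * n_comparisons * exp(-ka_lambda * score)
}

#' Column-wise stack of equal-length sequences as an MSA
#'
#' For families evolved without indels every member has the same length
#' and the alignment is the identity mapping. Errors if lengths differ.
#'
#' @param seqs data.frame with `id` and `sequence` (as from [read_fasta]).
#' @return character matrix, rows = sequences, columns = sites, with
#'   rownames from `id`.
#' @export
msa_stack <- function(seqs) {
  lens <- nchar(seqs$sequence)
  if (length(unique(lens)) != 1) {
    stop("sequences differ in length; supply an externally aligned FASTA",
         call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(seqs$sequence), ""))
  rownames(m) <- seqs$id
  m
}

#' Read an aligned FASTA into an MSA matrix
#' @param path aligned FASTA (rows of equal gapped length).
#' @param alphabet passed to [read_fasta]; gaps are stripped for the check.
#' @return character matrix as in [msa_stack].
#' @export
read_msa <- function(path, alphabet = "protein") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  grp <- cumsum(hdr)
  ids <- character(0); seqs <- character(0)
  for (g in unique(grp)) {
    block <- lines[grp == g]
    ids <- c(ids, strsplit(sub("^>", "", block[1]), "\\s+")[[1]][1])
    seqs <- c(seqs, toupper(paste0(block[-1], collapse = "")))
  }
  for (i in seq_along(seqs)) {
    check_alphabet(gsub("-", "", seqs[i]), alphabet, ids[i])
  }
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned FASTA rows differ in length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- ids
  m
}

#' Align sequences with mafft (external tool), if available
#'
#' Thin wrapper for real data sets; the synthetic pipeline does not need it.
#' @param seqs data.frame with `id`, `sequence`.
#' @return MSA matrix as in [msa_stack].
#' @export
align_msa_mafft <- function(seqs) {
  if (Sys.which("mafft") == "") stop("mafft not found on PATH", call. = FALSE)
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  write_fasta(seqs, fin)
  status <- system2("mafft", c("--auto", "--quiet", fin), stdout = fout)
  if (status != 0) stop("mafft failed", call. = FALSE)
  read_msa(fout)
}
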