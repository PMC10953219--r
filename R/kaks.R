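#' Standard genetic code as a named vector codon -> amino acid ('*' = stop)
#' @keywords internal
GENETIC_CODE_1 <- {
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0
  )))
  setNames(aas, codons)
}

SENSE_CODONS <- names(GENETIC_CODE_1)[GENETIC_CODE_1 != "*"]
STOP_CODONS <- names(GENETIC_CODE_1)[GENETIC_CODE_1 == "*"]

translate_codon <- function(codon) unname(GENETIC_CODE_1[codon])

#' Translate a CDS with the standard code
#' @param cds in-frame coding sequence (length a multiple of 3, no stops
#'   except optionally the final codon, which is dropped).
#' @return amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length not a multiple of 3", call. = FALSE)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- translate_codon(codons)
  if (any(is.na(aa))) {
    stop("ambiguous codon at position ", which(is.na(aa))[1], call. = FALSE)
  }
  if (length(aa) > 1 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1], call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Nei-Gojobori synonymous and nonsynonymous site counts of one codon
#'
#' Each of the 9 single-nucleotide neighbors contributes 1/3 of a site:
#' to `s` if the change is synonymous, to `n` otherwise (changes to stop
#' codons count as nonsynonymous). `s + n = 3` for every sense codon.
#'
#' @param codon a sense codon (3 letters, ACGT).
#' @return named numeric `c(s =, n =)`.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% SENSE_CODONS) {
    stop("not a sense codon: ", codon, call. = FALSE)
  }
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == b) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (translate_codon(mut) == aa) s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

# all orderings of the differing positions between two codons
.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

#' Pathway-averaged synonymous/nonsynonymous differences of one codon pair
#'
#' All minimal mutational pathways between the codons are enumerated;
#' pathways passing through a stop codon are excluded; synonymous and
#' nonsynonymous step counts are averaged with equal weight over the
#' remaining pathways. A pair with no stop-free pathway returns `NA`s
#' (the caller skips it).
#'
#' @param a,b sense codons.
#' @return named numeric `c(sd =, nd =)`, or NAs when no pathway survives.
#' @export
ng86_differences <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!a %in% SENSE_CODONS || !b %in% SENSE_CODONS) {
    stop("both codons must be sense codons", call. = FALSE)
  }
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffpos) == 0) return(c(sd = 0, nd = 0))
  tot_s <- 0; tot_n <- 0; n_path <- 0
  for (ord in .permutations(diffpos)) {
    cur <- a
    path_s <- 0; path_n <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (translate_codon(nxt) == "*") { ok <- FALSE; break }
      if (translate_codon(nxt) == translate_codon(cur)) {
        path_s <- path_s + 1
      } else {
        path_n <- path_n + 1
      }
      cur <- nxt
    }
    if (ok) {
      tot_s <- tot_s + path_s; tot_n <- tot_n + path_n
      n_path <- n_path + 1
    }
  }
  if (n_path == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = tot_s / n_path, nd = tot_n / n_path)
}

#' Thread a protein alignment back onto the coding sequences
#'
#' Each aligned protein column expands to a codon column; a protein gap
#' becomes `---`. Codons must translate to the aligned residues under the
#' standard code. Columns containing a gap (or, downstream, any ambiguity)
#' are flagged and excluded from Ka/Ks counting.
#'
#' @param aln_a,aln_b equal-length gapped protein strings.
#' @param cds_a,cds_b ungapped CDS, `3 x` the ungapped protein lengths.
#' @return list with codon matrices `codons_a`, `codons_b` (one column per
#'   protein column) and logical `comparable` (no gap in either codon).
#' @export
thread_codon_alignment <- function(aln_a, aln_b, cds_a, cds_b) {
  if (nchar(aln_a) != nchar(aln_b)) {
    stop("aligned strings must have equal length", call. = FALSE)
  }
  thread1 <- function(aln, cds, label) {
    cds <- toupper(cds)
    res <- strsplit(aln, "")[[1]]
    ungapped <- res[res != "-"]
    if (nchar(cds) != 3 * length(ungapped)) {
      stop(sprintf("CDS %s length %d is not 3 x %d (ungapped protein)",
                   label, nchar(cds), length(ungapped)), call. = FALSE)
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- translate_codon(codons)
    mism <- which(is.na(aa) | aa != ungapped)
    if (length(mism) > 0) {
      stop(sprintf("CDS %s: codon %d ('%s') does not translate to residue '%s'",
                   label, mism[1], codons[mism[1]], ungapped[mism[1]]),
           call. = FALSE)
    }
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    out
  }
  ca <- thread1(aln_a, cds_a, "a")
  cb <- thread1(aln_b, cds_b, "b")
  list(codons_a = ca, codons_b = cb,
       comparable = ca != "---" & cb != "---")
}

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Sites `S`, `N` are averaged over the two sequences; differences are
#' pathway-averaged per codon pair ([ng86_differences]); proportions are
#' corrected as `d = -(3/4) log(1 - (4/3) p)`. `omega = Ka/Ks`, reported
#' as 0 when `Ka = Ks = 0` and as `NA` (undefined) when `Ks = 0 < Ka`.
#'
#' @param codon_aln output of [thread_codon_alignment], or a list with
#'   `codons_a`, `codons_b`, `comparable`.
#' @return list of class `kaks_result` with fields `S, N, Sd, Nd, pS, pN,
#'   Ks, Ka, omega, n_codons, n_skipped`.
#' @export
ng86_kaks <- function(codon_aln) {
  keep <- which(codon_aln$comparable)
  if (length(keep) == 0) stop("no comparable codon columns", call. = FALSE)
  ca <- codon_aln$codons_a[keep]
  cb <- codon_aln$codons_b[keep]
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; skipped <- 0
  for (i in seq_along(ca)) {
    sa <- ng86_sites(ca[i]); sb <- ng86_sites(cb[i])
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    d <- ng86_differences(ca[i], cb[i])
    if (anyNA(d)) {
      skipped <- skipped + 1
      log_msg("WARN", "kaks",
              sprintf("codon pair %s/%s has no stop-free pathway; skipped",
                      ca[i], cb[i]))
      next
    }
    Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
  }
  pS <- as.numeric(Sd / S); pN <- as.numeric(Nd / N)
  jc <- function(p) {
    if (p >= 3 / 4) {
      stop(sprintf("proportion %.4f >= 3/4: Jukes-Cantor correction undefined", p),
           call. = FALSE)
    }
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  omega <- if (Ks == 0 && Ka == 0) 0 else if (Ks == 0) NA_real_ else Ka / Ks
  structure(
    list(S = as.numeric(S), N = as.numeric(N),
         Sd = as.numeric(Sd), Nd = as.numeric(Nd),
         pS = pS, pN = pN, Ks = Ks, Ka = Ka, omega = omega,
         n_codons = length(ca), n_skipped = skipped),
    class = "kaks_result"
  )
}

#' Ka/Ks between two in-frame CDS via a protein-threaded alignment
#'
#' Convenience wrapper: globally aligns the translations, threads the
#' codon alignment and applies [ng86_kaks].
#'
#' @param cds_a,cds_b in-frame coding sequences.
#' @param ... passed to [global_align].
#' @return a `kaks_result`.
#' @export
kaks_pair <- function(cds_a, cds_b, ...) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  aln <- global_align(pa, pb, ...)
  ng86_kaks(thread_codon_alignment(aln$aligned_a, aln$aligned_b, cds_a, cds_b))
}

#' Divergence time from Ks under a strict synonymous clock
#'
#' `T = Ks / (2 * lambda)` years since duplication/divergence, with the
#' study's clock rate `lambda = 6.5e-9` substitutions per synonymous site
#' per year as default.
#'
#' @param Ks synonymous distance (>= 0).
#' @param lambda clock rate (> 0), substitutions/site/year per lineage.
#' @return list with `t_years` and `t_mya`.
#' @export
divergence_time <- function(Ks, lambda = 6.5e-9) {
  if (any(is.na(Ks)) || any(Ks < 0)) stop("Ks must be >= 0", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  t_years <- Ks / (2 * lambda)
  list(t_years = t_years, t_mya = t_years / 1e6)
}
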