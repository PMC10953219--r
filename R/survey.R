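#' Average residue masses (Da) of the 20 standard amino acids
#'
#' Average-isotope residue masses as used by ProtParam-style calculators;
#' a free water (18.0153 Da) is added per chain.
#' @keywords internal
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' EMBOSS-style pKa constants for the protein charge model
#' @keywords internal
PKA_EMBOSS <- c(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)

#' Molecular weight of a protein in kDa
#'
#' Sum of average residue masses plus one water, reported in kDa.
#' Additive up to the water term: `MW(ab) = MW(a) + MW(b) - water`.
#'
#' @param seq amino-acid sequence (20 standard letters; `X` has no mass
#'   and is an error).
#' @return mass in kDa.
#' @export
molecular_weight <- function(seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% names(AA_RESIDUE_MASS))
  if (length(bad) > 0) {
    stop(sprintf("mass undefined for residue '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  (sum(AA_RESIDUE_MASS[chars]) + WATER_MASS) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch terms for the N-terminus, C-terminus and the
#' side chains of D, E, C, Y, H, K, R. Composition-only (permutation
#' invariant), strictly decreasing in pH.
#'
#' @param seq amino-acid sequence.
#' @param pH evaluation pH.
#' @param pka named pKa set (defaults to the EMBOSS-style constants).
#' @return net charge.
#' @export
protein_charge <- function(seq, pH, pka = PKA_EMBOSS) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  cnt <- function(a) sum(chars == a)
  pos <- c(Nterm = 1, H = cnt("H"), K = cnt("K"), R = cnt("R"))
  neg <- c(Cterm = 1, D = cnt("D"), E = cnt("E"), C = cnt("C"), Y = cnt("Y"))
  chg <- 0
  for (g in names(pos)) chg <- chg + pos[[g]] / (1 + 10^(pH - pka[[g]]))
  for (g in names(neg)) chg <- chg - neg[[g]] / (1 + 10^(pka[[g]] - pH))
  chg
}

#' Isoelectric point by bisection
#'
#' pH at which [protein_charge] is zero, found by bisection on `[0, 14]`
#' until `|charge| < tol`.
#'
#' @param seq amino-acid sequence (non-empty).
#' @param pka pKa set.
#' @param tol charge tolerance (default 1e-4).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = PKA_EMBOSS, tol = 1e-4) {
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    ch <- protein_charge(seq, mid, pka)
    if (abs(ch) < tol || (hi - lo) < 1e-12) return(mid)
    if (ch > 0) lo <- mid else hi <- mid
  }
}

#' Greedy redundancy reduction of a protein set
#'
#' Records are visited in descending length order (ties broken by id); a
#' record joins the first kept representative to which its global-
#' alignment identity is at least `identity_cutoff`, otherwise it becomes
#' a new representative. Output is independent of input order.
#'
#' @param records data.frame with `id`, `sequence`.
#' @param identity_cutoff in (0, 1]; default 1.0 removes exact duplicates
#'   (and identical-over-overlap sequences) only.
#' @param ... passed to [global_align].
#' @return list with `kept` (data.frame of representatives) and
#'   `clusters` (named list: representative id -> member ids).
#' @export
reduce_redundancy <- function(records, identity_cutoff = 1.0, ...) {
  if (identity_cutoff <= 0 || identity_cutoff > 1) {
    stop("identity cutoff must be in (0, 1]", call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(list(kept = records, clusters = list()))
  }
  ord <- order(-nchar(records$sequence), records$id)
  records <- records[ord, , drop = FALSE]
  reps <- integer(0)
  clusters <- list()
  for (i in seq_len(nrow(records))) {
    placed <- FALSE
    for (r in reps) {
      ident <- if (records$sequence[r] == records$sequence[i]) 1 else {
        global_align(records$sequence[r], records$sequence[i], ...)$identity
      }
      if (ident >= identity_cutoff) {
        clusters[[records$id[r]]] <- c(clusters[[records$id[r]]], records$id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      clusters[[records$id[i]]] <- records$id[i]
    }
  }
  list(kept = records[reps, , drop = FALSE], clusters = clusters)
}

#' Domain profile for the consensus-pattern scanner
#'
#' @param name profile name (e.g. `DEXDC`, `HELICC`).
#' @param consensus amino-acid consensus with `X` as wildcard; length >= 5.
#' @param min_score minimum matching positions required (<= length).
#' @return list of class `domain_profile`.
#' @export
domain_profile <- function(name, consensus, min_score = nchar(consensus)) {
  consensus <- toupper(consensus)
  if (nchar(consensus) < 5) stop("consensus length must be >= 5", call. = FALSE)
  if (min_score > nchar(consensus)) stop("min_score exceeds consensus length", call. = FALSE)
  structure(list(name = name, consensus = consensus, min_score = min_score),
            class = "domain_profile")
}

#' Scan a protein for consensus-pattern domains
#'
#' Sliding-window match count of each profile consensus against the
#' sequence (`X` in the consensus matches anything); windows reaching
#' `min_score` matches are reported, overlapping hits of one profile
#' merged to the best-scoring (earliest on tie) window.
#'
#' @param protein amino-acid sequence.
#' @param profiles list of [domain_profile] objects.
#' @return data.frame `profile`, `start`, `end`, `matches` (1-based,
#'   inclusive); zero rows when nothing is found.
#' @export
scan_domains <- function(protein, profiles) {
  protein <- toupper(protein)
  pchars <- strsplit(protein, "")[[1]]
  out <- data.frame(profile = character(0), start = integer(0),
                    end = integer(0), matches = integer(0))
  for (pf in profiles) {
    k <- nchar(pf$consensus)
    if (k > length(pchars)) next
    cons <- strsplit(pf$consensus, "")[[1]]
    wild <- cons == "X"
    hits <- data.frame(start = integer(0), matches = integer(0))
    for (s in seq_len(length(pchars) - k + 1)) {
      win <- pchars[s:(s + k - 1)]
      m <- sum(wild | win == cons)
      if (m >= pf$min_score) {
        hits <- rbind(hits, data.frame(start = s, matches = m))
      }
    }
    if (nrow(hits) == 0) next
    # merge overlapping windows, keep best-scoring (earliest on tie)
    hits <- hits[order(hits$start), , drop = FALSE]
    flush <- function(block) {
      best <- block[order(-block$matches, block$start), , drop = FALSE][1, ]
      data.frame(profile = pf$name, start = best$start,
                 end = best$start + k - 1, matches = best$matches)
    }
    block <- hits[1, , drop = FALSE]
    if (nrow(hits) > 1) {
      for (i in 2:nrow(hits)) {
        if (hits$start[i] <= block$start[nrow(block)] + k - 1) {
          block <- rbind(block, hits[i, ])
        } else {
          out <- rbind(out, flush(block))
          block <- hits[i, , drop = FALSE]
        }
      }
    }
    out <- rbind(out, flush(block))
  }
  out
}

#' Per-chromosome gene counts and percentages
#'
#' Percentages are over assigned genes (chromosome label != "0"),
#' rounded to the nearest integer with ties away from zero; unassigned
#' genes are counted separately.
#'
#' @param genes list of `gene_model` (or a character vector of
#'   chromosome labels).
#' @return list with `counts` (data.frame `chromosome`, `count`,
#'   `percent`, assigned chromosomes only, sorted by decreasing count)
#'   and `unassigned` (integer).
#' @export
chromosome_distribution <- function(genes) {
  chroms <- if (is.character(genes)) genes else {
    vapply(genes, `[[`, "", "chromosome")
  }
  if (length(chroms) == 0) stop("empty gene list", call. = FALSE)
  unassigned <- sum(chroms == "0")
  chroms <- chroms[chroms != "0"]
  tab <- table(chroms)
  round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  df <- data.frame(
    chromosome = names(tab),
    count = as.integer(tab),
    percent = as.integer(round_half_away(100 * as.integer(tab) / sum(tab))),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$count, df$chromosome), , drop = FALSE]
  rownames(df) <- NULL
  list(counts = df, unassigned = unassigned)
}

#' Intron count of a gene model
#'
#' Number of exons minus one.
#' @param gene a `gene_model` with at least one exon.
#' @return integer.
#' @export
intron_count <- function(gene) {
  nrow(gene$exons) - 1L
}

#' Characterize a protein set: length, MW, pI
#'
#' @param proteins data.frame with `id`, `sequence`.
#' @return data.frame `protein_id`, `length_aa`, `mw_kda`, `pi`.
#' @export
protein_properties <- function(proteins) {
  data.frame(
    protein_id = proteins$id,
    length_aa = nchar(proteins$sequence),
    mw_kda = vapply(proteins$sequence, molecular_weight, 0, USE.NAMES = FALSE),
    pi = vapply(proteins$sequence, isoelectric_point, 0, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}
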