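IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Default cis-element library
#'
#' The stress-responsive elements named in the survey with their printed
#' patterns: S000415 (ACGTG, drought), S000453 (GAAAAA, salinity),
#' S000030 (CCAAT, heat). Elements whose patterns the survey does not
#' print (S000133, S000173, S000418, S000407) must come from a
#' user-supplied library.
#'
#' @return data.frame `element_id`, `pattern`, `category`.
#' @export
default_element_library <- function() {
  data.frame(
    element_id = c("S000415", "S000453", "S000030"),
    pattern = c("ACGTG", "GAAAAA", "CCAAT"),
    category = c("drought", "salinity", "heat"),
    stringsAsFactors = FALSE
  )
}

#' Read a cis-element library TSV
#' @param path TSV with columns `element_id`, `pattern`, `category`.
#' @return validated data.frame.
#' @export
read_element_library <- function(path) {
  df <- read.delim(path, colClasses = "character")
  stopifnot(all(c("element_id", "pattern") %in% names(df)))
  df$pattern <- toupper(df$pattern)
  for (i in seq_len(nrow(df))) {
    chars <- strsplit(df$pattern[i], "")[[1]]
    bad <- which(!chars %in% IUPAC_DNA)
    if (length(bad) > 0) {
      stop(sprintf("element %s: illegal IUPAC letter '%s'",
                   df$element_id[i], chars[bad[1]]), call. = FALSE)
    }
  }
  df
}

#' Extract the upstream promoter region of a gene
#'
#' Plus strand: `contig[start - length, start)`. Minus strand: reverse
#' complement of `contig[end, end + length)`. Truncated at the contig
#' boundary, with the flag set.
#'
#' @param gene a `gene_model` whose coordinates lie on `contig_seq`
#'   (0-based, end-exclusive, as everywhere in the package).
#' @param contig_seq DNA string of the contig the gene sits on.
#' @param length upstream length in bp (default 2000).
#' @return list `sequence`, `truncated`.
#' @export
extract_upstream <- function(gene, contig_seq, length = 2000L) {
  L <- nchar(contig_seq)
  if (gene$end > L || gene$start < 0) {
    stop(sprintf("gene '%s' not on contig (contig length %d)", gene$gene_id, L),
         call. = FALSE)
  }
  if (gene$strand == "+") {
    from <- max(0, gene$start - length)
    seq <- substr(contig_seq, from + 1, gene$start)
    truncated <- (gene$start - length) < 0
  } else {
    to <- min(L, gene$end + length)
    fwd <- substr(contig_seq, gene$end + 1, to)
    seq <- revcomp(fwd)
    truncated <- (gene$end + length) > L
  }
  list(sequence = toupper(seq), truncated = truncated)
}

#' Reverse complement of a DNA string
#' @param seq DNA string (IUPAC letters allowed).
#' @return reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Count cis-element occurrences in a sequence
#'
#' Every start position is tested, so overlapping matches are counted.
#' With `both_strands = TRUE` matches of each pattern on the reverse
#' complement strand are added (palindromic patterns double-count by
#' construction; use `both_strands = FALSE` for a forward-only scan).
#'
#' @param seq DNA string.
#' @param elements element library data.frame (`element_id`, `pattern`).
#' @param both_strands scan both strands (default TRUE).
#' @return named integer vector of counts per element_id.
#' @export
scan_elements <- function(seq, elements, both_strands = TRUE) {
  seq <- toupper(seq)
  counts <- setNames(integer(nrow(elements)), elements$element_id)
  if (!nzchar(seq)) return(counts)
  subj <- Biostrings::DNAString(seq)
  rc <- if (both_strands) Biostrings::reverseComplement(subj) else NULL
  for (i in seq_len(nrow(elements))) {
    pat <- toupper(elements$pattern[i])
    chars <- strsplit(pat, "")[[1]]
    bad <- which(!chars %in% IUPAC_DNA)
    if (length(bad) > 0) {
      stop(sprintf("element %s: illegal IUPAC letter '%s'",
                   elements$element_id[i], chars[bad[1]]), call. = FALSE)
    }
    if (nchar(pat) > nchar(seq)) next
    k <- Biostrings::countPattern(pat, subj, fixed = FALSE)
    if (both_strands) k <- k + Biostrings::countPattern(pat, rc, fixed = FALSE)
    counts[i] <- k
  }
  counts
}

#' Promoter hit table over a set of genes
#'
#' @param promoters named list of promoter records (as from
#'   [extract_upstream]): each with `sequence` and `truncated`.
#' @param elements element library.
#' @param both_strands passed to [scan_elements].
#' @return list with `hits` (data.frame gene x element counts plus
#'   `truncated` flag) and `totals` (named vector, column sums).
#' @export
promoter_hit_table <- function(promoters, elements, both_strands = TRUE) {
  mat <- t(vapply(promoters, function(p) {
    scan_elements(p$sequence, elements, both_strands)
  }, setNames(integer(nrow(elements)), elements$element_id)))
  hits <- data.frame(gene = names(promoters), mat,
                     truncated = vapply(promoters, `[[`, FALSE, "truncated"),
                     row.names = NULL, check.names = FALSE,
                     stringsAsFactors = FALSE)
  totals <- colSums(mat)
  list(hits = hits, totals = totals)
}

#' Ranked element totals
#'
#' Totals per element sorted descending, ties broken by element id.
#' @param hit_table output of [promoter_hit_table].
#' @return data.frame `element_id`, `total`.
#' @export
element_summary <- function(hit_table) {
  tot <- hit_table$totals
  df <- data.frame(element_id = names(tot), total = as.integer(tot),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$total, df$element_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
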