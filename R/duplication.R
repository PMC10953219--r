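#' Call paralog pairs from a protein set
#'
#' All-vs-all global alignment; an unordered pair is kept iff its identity
#' (terminal gaps excluded, see [alignment_identity]) is at least
#' `min_identity` and its e-value proxy is at most `max_evalue`. Each pair
#' is reported once in lexicographic id order.
#'
#' @param proteins data.frame with `id`, `sequence`.
#' @param min_identity identity threshold (default 0.80).
#' @param max_evalue e-value threshold (default 1e-10).
#' @param n_comparisons database-size factor for the e-value proxy;
#'   defaults to the number of comparisons performed.
#' @param ... passed to [global_align].
#' @return data.frame `gene_a`, `gene_b`, `identity`, `score`, `evalue`.
#' @export
call_paralog_pairs <- function(proteins, min_identity = 0.80,
                               max_evalue = 1e-10, n_comparisons = NULL, ...) {
  n <- nrow(proteins)
  if (n < 2) stop("need at least 2 proteins", call. = FALSE)
  if (is.null(n_comparisons)) n_comparisons <- n * (n - 1) / 2
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- global_align(proteins$sequence[i], proteins$sequence[j], ...)
      ev <- evalue_proxy(al$score, nchar(proteins$sequence[i]),
                         nchar(proteins$sequence[j]), n_comparisons)
      if (al$identity >= min_identity && ev <= max_evalue) {
        ids <- sort(c(proteins$id[i], proteins$id[j]))
        rows[[length(rows) + 1]] <- data.frame(
          gene_a = ids[1], gene_b = ids[2],
          identity = al$identity, score = al$score, evalue = ev,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), score = numeric(0),
                      evalue = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Classify a duplicate pair as tandem or segmental
#'
#' Same chromosome with nearest-edge distance at most `tandem_cutoff_bp`
#' is tandem; same chromosome farther apart, or different chromosomes
#' (including one unknown, "0"), is segmental. The 5 Mb cutoff is the
#' single classification boundary.
#'
#' @param gene_a,gene_b `gene_model` objects.
#' @param tandem_cutoff_bp distance cutoff in bp (default 5e6).
#' @return `"tandem"` or `"segmental"`.
#' @export
classify_duplication <- function(gene_a, gene_b, tandem_cutoff_bp = 5e6) {
  if (gene_a$chromosome != gene_b$chromosome ||
      gene_a$chromosome == "0" || gene_b$chromosome == "0") {
    return("segmental")
  }
  gap <- max(gene_a$start, gene_b$start) - min(gene_a$end, gene_b$end)
  gap <- max(gap, 0)  # overllapping/adjacent genes have zero edge distance
  if (gap <= tandem_cutoff_bp) "tandem" else "segmental"
}

#' Full paralog-pair table with classification, Ka/Ks and dating
#'
#' Runs [call_paralog_pairs], classifies each pair against the gene
#' models, computes Nei-Gojobori Ka/Ks on the protein-threaded codon
#' alignment and dates divergence with `T = Ks/(2 lambda)`. Mirrors the
#' survey's paralog-table column order.
#'
#' @param proteins data.frame `id`, `sequence` (ids = gene ids).
#' @param cds data.frame `id`, `sequence`, same ids.
#' @param genes named list of `gene_model`.
#' @param cfg a [pipeline_config].
#' @return data.frame with one row per called pair: coordinates of both
#'   genes, `evalue`, `dup_class`, `ka_ks`, `ka`, `ks`, `t_years`, `t_mya`.
#' @export
paralog_pair_table <- function(proteins, cds, genes, cfg = pipeline_config()) {
  pairs <- call_paralog_pairs(
    proteins,
    min_identity = cfg$pair_min_identity,
    max_evalue = cfg$evalue_cutoff
  )
  if (nrow(pairs) == 0) return(pairs)
  cds_of <- setNames(cds$sequence, cds$id)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- genes[[pairs$gene_a[i]]]
    gb <- genes[[pairs$gene_b[i]]]
    kk <- kaks_pair(cds_of[[pairs$gene_a[i]]], cds_of[[pairs$gene_b[i]]])
    tt <- divergence_time(kk$Ks, cfg$lambda)
    data.frame(
      gene_1 = ga$gene_id, chr_1 = ga$chromosome,
      start_1 = ga$start, end_1 = ga$end,
      gene_2 = gb$gene_id, chr_2 = gb$chromosome,
      start_2 = gb$start, end_2 = gb$end,
      evalue = pairs$evalue[i], identity = pairs$identity[i],
      dup_class = classify_duplication(ga, gb, cfg$tandem_cutoff_bp),
      ka_ks = if (is.na(kk$omega)) NA_real_ else kk$omega,
      ka = kk$Ka, ks = kk$Ks,
      t_years = tt$t_years, t_mya = tt$t_mya,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Reciprocal best hits between two proteomes
#'
#' Pair `(a, b)` is kept iff `b` is `a`'s best-scoring hit in proteome B
#' and `a` is `b`'s best in A; score ties are broken lexicographically by
#' id and logged.
#'
#' @param proteome_a,proteome_b data.frames with `id`, `sequence`.
#' @param ... passed to [global_align].
#' @return data.frame `id_a`, `id_b`, `score`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, ...) {
  if (nrow(proteome_a) == 0 || nrow(proteome_b) == 0) {
    stop("both proteomes must be non-empty", call. = FALSE)
  }
  S <- matrix(NA_real_, nrow(proteome_a), nrow(proteome_b),
              dimnames = list(proteome_a$id, proteome_b$id))
  for (i in seq_len(nrow(proteome_a))) {
    for (j in seq_len(nrow(proteome_b))) {
      S[i, j] <- global_align(proteome_a$sequence[i],
                              proteome_b$sequence[j], ...)$score
    }
  }
  best_of <- function(v) {
    top <- which(v == max(v))
    if (length(top) > 1) {
      log_msg("INFO", "rbh", sprintf("score tie broken lexicographically among: %s",
                                     paste(names(v)[top], collapse = ",")))
      top <- top[order(names(v)[top])]
    }
    top[1]
  }
  rows <- list()
  for (i in seq_len(nrow(S))) {
    j <- best_of(S[i, ])
    if (best_of(S[, j]) == i) {
      rows[[length(rows) + 1]] <- data.frame(
        id_a = rownames(S)[i], id_b = colnames(S)[j], score = S[i, j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0)))
  }
  do.call(rbind, rows)
}
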