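#' @importFrom stats cutree dist hclust median p.adjust rnorm rpois
#'   runif setNames t.test uniroot
#' @importFrom utils read.delim write.table modifyList
NULL

AA_ALPHABET20 <- c(
  "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)
DNA_ALPHABET <- c("A", "C", "G", "T")

#' Validate a sequence against a declared alphabet
#'
#' Sequences are handled case-insensitively and stored uppercased. The
#' protein alphabet is the 20 standard residues plus `X`; the DNA alphabet
#' is `ACGT`.
#'
#' @param seq character scalar.
#' @param alphabet `"dna"` or `"protein"`.
#' @param id sequence id used in error messages.
#' @return the uppercased sequence, invisibly on success.
#' @keywords internal
check_alphabet <- function(seq, alphabet = c("dna", "protein"), id = "?") {
  alphabet <- match.arg(alphabet)
  seq <- toupper(seq)
  legal <- if (alphabet == "dna") DNA_ALPHABET else c(AA_ALPHABET20, "X")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% legal)
  if (length(bad) > 0) {
    stop(sprintf(
      "record '%s': illegal %s character '%s' at position %d",
      id, alphabet, chars[bad[1]], bad[1]
    ), call. = FALSE)
  }
  invisible(seq)
}

#' Read a FASTA file into a sequence table
#'
#' Wrapped sequence lines are concatenated, record order is preserved and
#' sequences are uppercased. Each record id (first whitespace-delimited
#' token of the header) must be unique within the file.
#'
#' @param path FASTA file.
#' @param alphabet `"dna"` or `"protein"`; every residue is checked.
#' @return a `data.frame` with columns `id`, `description`, `sequence` and
#'   attribute `alphabet`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 demo", "ACGT", ">g2", "GGCC"), tf)
#' read_fasta(tf, "dna")
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (length(lines) == 0 || !hdr[1]) {
    stop("not a FASTA file (no '>' header first): ", path, call. = FALSE)
  }
  grp <- cumsum(hdr)
  ids <- character(0); desc <- character(0); seqs <- character(0)
  for (g in unique(grp)) {
    block <- lines[grp == g]
    header <- sub("^>", "", block[1])
    tok <- strsplit(header, "\\s+")[[1]]
    id <- tok[1]
    if (!nzchar(id)) stop("empty FASTA id in ", path, call. = FALSE)
    s <- toupper(paste0(block[-1], collapse = ""))
    if (!nzchar(s)) stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
    check_alphabet(s, alphabet, id)
    ids <- c(ids, id)
    desc <- c(desc, if (length(tok) > 1) paste(tok[-1], collapse = " ") else "")
    seqs <- c(seqs, s)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id: ", dup[1], call. = FALSE)
  }
  out <- data.frame(id = ids, description = desc, sequence = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write a sequence table to FASTA
#'
#' @param seqs data.frame with `id`, `sequence` and optional `description`.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    d <- if (!is.null(seqs$description) && nzchar(seqs$description[i])) {
      paste0(" ", seqs$description[i])
    } else ""
    writeLines(paste0(">", seqs$id[i], d), con)
    s <- seqs$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Construct and validate a gene model
#'
#' Coordinates are 0-based, end-exclusive, so `length = end - start`
#' (the convention under which the transcribed survey table is internally
#' consistent). Chromosome `"0"` is a legal label meaning "unassigned".
#' Exons must be non-overlapping, sorted and contained in `[start, end)`.
#'
#' @param gene_id,chromosome,start,end,strand,cds_id,protein_id scalar fields.
#' @param exons two-column matrix (start, end) of exon sub-intervals; defaults
#'   to the single interval `[start, end)`.
#' @return a list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, start, end, strand = "+",
                       exons = NULL, cds_id = NA_character_,
                       protein_id = NA_character_) {
  stopifnot(is.character(gene_id), nzchar(gene_id))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || start < 0) stop("start must be a non-negative integer", call. = FALSE)
  if (is.na(end) || end <= start) {
    stop(sprintf("gene '%s': end (%s) must exceed start (%s)", gene_id, end, start),
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (is.null(exons)) exons <- matrix(c(start, end), ncol = 2)
  exons <- matrix(as.numeric(exons), ncol = 2)
  if (any(exons[, 2] <= exons[, 1])) {
    stop(sprintf("gene '%s': degenerate exon interval", gene_id), call. = FALSE)
  }
  o <- order(exons[, 1])
  if (!identical(o, seq_len(nrow(exons)))) {
    stop(sprintf("gene '%s': exons not sorted", gene_id), call. = FALSE)
  }
  if (any(exons[, 1] < start) || any(exons[, 2] > end)) {
    stop(sprintf("gene '%s': exon outside gene interval", gene_id), call. = FALSE)
  }
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop(sprintf("gene '%s': overlapping exons", gene_id), call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, chromosome = as.character(chromosome),
         start = start, end = end, strand = strand, exons = exons,
         cds_id = cds_id, protein_id = protein_id),
    class = "gene_model"
  )
}

#' Length of a gene model
#'
#' Always derived, never stored: `end - start`.
#' @param gene a `gene_model`.
#' @export
gene_length <- function(gene) gene$end - gene$start

#' Read a tab-separated gene table
#'
#' Expected header: `gene_id, chromosome, start, end, strand, exons,
#' cds_id, protein_id`, with `exons` a semicolon-joined list of
#' `start-end` pairs (may be empty, meaning a single-exon gene spanning
#' the whole interval). All gene-model invariants are enforced.
#'
#' @param path TSV file.
#' @return list of `gene_model` objects, named by `gene_id`.
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, colClasses = "character")
  need <- c("gene_id", "chromosome", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  genes <- lapply(seq_len(nrow(df)), function(i) {
    ex <- NULL
    if (!is.null(df$exons) && nzchar(df$exons[i])) {
      parts <- strsplit(strsplit(df$exons[i], ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
      ex <- do.call(rbind, lapply(parts, function(p) as.numeric(p)))
    }
    gene_model(
      gene_id = df$gene_id[i], chromosome = df$chromosome[i],
      start = as.numeric(df$start[i]), end = as.numeric(df$end[i]),
      strand = df$strand[i], exons = ex,
      cds_id = if (is.null(df$cds_id)) NA_character_ else df$cds_id[i],
      protein_id = if (is.null(df$protein_id)) NA_character_ else df$protein_id[i]
    )
  })
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  genes
}

#' Write gene models to the TSV gene-table format
#' @param genes list of `gene_model`.
#' @param path output TSV.
#' @export
write_gene_table <- function(genes, path) {
  df <- do.call(rbind, lapply(genes, function(g) {
    data.frame(
      gene_id = g$gene_id, chromosome = g$chromosome,
      start = format(g$start, scientific = FALSE),
      end = format(g$end, scientific = FALSE), strand = g$strand,
      exons = paste(sprintf("%s-%s",
                            format(g$exons[, 1], scientific = FALSE, trim = TRUE),
                            format(g$exons[, 2], scientific = FALSE, trim = TRUE)),
                    collapse = ";"),
      cds_id = g$cds_id, protein_id = g$protein_id,
      stringsAsFactors = FALSE
    )
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are written with 6 decimals; integer bootstrap supports,
#' when present in `tree$node.label`, appear as internal-node labels.
#'
#' @param tree an [ape::phylo] object with branch lengths; all tips named.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    stop("all leaves must be named", call. = FALSE)
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths", call. = FALSE)
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Pipeline configuration
#'
#' All thresholds of the survey in one record, with the study defaults:
#' redundancy identity cutoff 1.0, paralog-pair identity cutoff 0.80,
#' e-value cutoff 1e-10, tandem distance cutoff 5 Mb, promoter length
#' 2000 bp, clock rate lambda = 6.5e-9 substitutions/synonymous
#' site/year, 1000 bootstrap replicates.
#'
#' @param redundancy_identity,pair_min_identity,evalue_cutoff,tandem_cutoff_bp,upstream_length,lambda,bootstrap_reps,seed tunables.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(redundancy_identity = 1.0,
                            pair_min_identity = 0.80,
                            evalue_cutoff = 1e-10,
                            tandem_cutoff_bp = 5e6,
                            upstream_length = 2000L,
                            lambda = 6.5e-9,
                            bootstrap_reps = 1000L,
                            seed = 1L) {
  cfg <- list(
    redundancy_identity = redundancy_identity,
    pair_min_identity = pair_min_identity,
    evalue_cutoff = evalue_cutoff,
    tandem_cutoff_bp = tandem_cutoff_bp,
    upstream_length = upstream_length,
    lambda = lambda,
    bootstrap_reps = as.integer(bootstrap_reps),
    seed = as.integer(seed)
  )
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(num <= 0)) stop("every threshold must be strictly positive", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Fingerprint of a configuration (rolling hash over its serialized fields)
#'
#' Embedded in output file headers so runs are traceable to their settings.
#' @param cfg a `pipeline_config` (or any list of scalars).
#' @return hex string.
#' @export
config_digest <- function(cfg) {
  txt <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","), ""),
               sep = "=", collapse = ";")
  bytes <- utf8ToInt(txt)
  # polynomial rolling hash in double precision, modulus below 2^31
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a stage-output TSV with a config-digest comment header
#' @param df data.frame to write.
#' @param path output path.
#' @param cfg optional [pipeline_config] whose digest and seed are embedded
#'   in a leading comment line.
#' @export
write_stage_tsv <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) {
    writeLines(sprintf("# config_digest=%s seed=%s", config_digest(cfg),
                       cfg$seed), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_msg <- function(level, stage, msg) {
  message(sprintf("%s\t%s\t%s", level, stage, msg))
}
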