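#' Evolve a duplicated codon pair at a controlled dN/dS
#'
#' An ancestor of `n_codons` sense codons is drawn uniformly; each
#' descendant then receives `Poisson(n_codons * expected_subs_per_codon)`
#' single-nucleotide proposals at uniform positions. Synonymous proposals
#' are always accepted, nonsynonymous ones with probability
#' `min(omega, 1)`, and proposals creating a stop codon are rejected, so
#' the realized dN/dS of the pair is governed by `omega`. Positions listed
#' in `frozen_codons` accept synonymous changes only (used to keep a
#' planted domain intact at the protein level).
#'
#' @param n_codons number of codons (>= 10).
#' @param omega target dN/dS (>= 0).
#' @param expected_subs_per_codon expected proposals per codon per lineage.
#' @param seed integer seed.
#' @param ancestor optional ancestor CDS (overrides the random draw).
#' @param frozen_codons integer codon indices evolving synonymously only.
#' @return list `cds_a`, `cds_b`, `ancestor`, `n_syn` / `n_nonsyn`
#'   (realized substitution counts summed over both lineages).
#' @export
simulate_codon_pair <- function(n_codons, omega, expected_subs_per_codon,
                                seed = 1L, ancestor = NULL,
                                frozen_codons = integer(0)) {
  if (n_codons < 10) stop("n_codons must be >= 10 (too short for estimation)", call. = FALSE)
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(ancestor)) {
    anc <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  } else {
    anc <- substring(toupper(ancestor), seq(1, nchar(ancestor), 3),
                     seq(3, nchar(ancestor), 3))
    stopifnot(length(anc) == n_codons, all(anc %in% SENSE_CODONS))
  }
  evolve <- function(codons) {
    n_syn <- 0; n_nonsyn <- 0
    n_events <- rpois(1, n_codons * expected_subs_per_codon)
    for (e in seq_len(n_events)) {
      ci <- sample.int(n_codons, 1)
      pos <- sample.int(3, 1)
      cur <- codons[ci]
      base <- substr(cur, pos, pos)
      nb <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      mut <- cur
      substr(mut, pos, pos) <- nb
      if (translate_codon(mut) == "*") next
      syn <- translate_codon(mut) == translate_codon(cur)
      if (syn) {
        codons[ci] <- mut
        n_syn <- n_syn + 1
      } else if (!(ci %in% frozen_codons) && runif(1) < min(omega, 1)) {
        codons[ci] <- mut
        n_nonsyn <- n_nonsyn + 1
      }
    }
    list(codons = codons, n_syn = n_syn, n_nonsyn = n_nonsyn)
  }
  a <- evolve(anc)
  b <- evolve(anc)
  list(
    cds_a = paste(a$codons, collapse = ""),
    cds_b = paste(b$codons, collapse = ""),
    ancestor = paste(anc, collapse = ""),
    n_syn = a$n_syn + b$n_syn,
    n_nonsyn = a$n_nonsyn + b$n_nonsyn
  )
}

#' Random element-free DNA background
#'
#' Draws a uniform DNA string, then rejection-repairs it: while any
#' library element still matches (either strand) one base inside the
#' first match is redrawn. The result contains zero chance occurrences of
#' every element, so planted counts are exact ground truth.
#' @keywords internal
element_free_background <- function(len, elements, max_tries = 10000L) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (i in seq_len(max_tries)) {
    s <- paste(chars, collapse = "")
    subj <- Biostrings::DNAString(s)
    hit <- NULL
    for (j in seq_len(nrow(elements))) {
      pat <- toupper(elements$pattern[j])
      m <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
      if (length(m) > 0) {
        hit <- c(Biostrings::start(m)[1], Biostrings::end(m)[1])
        break
      }
      mrc <- Biostrings::matchPattern(
        pat, Biostrings::reverseComplement(subj), fixed = FALSE
      )
      if (length(mrc) > 0) {
        hit <- c(len - Biostrings::end(mrc)[1] + 1, len - Biostrings::start(mrc)[1] + 1)
        break
      }
    }
    if (is.null(hit)) return(s)
    pos <- sample(hit[1]:hit[2], 1)
    chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1)
  }
  stop("could not repair the background to be element-free; patterns too dense",
       call. = FALSE)
}

#' Plant exact element counts into an element-free promoter
#' @keywords internal
plant_elements <- function(len, elements, planted, max_tries = 200L) {
  stopifnot(length(planted) == nrow(elements))
  for (try in seq_len(max_tries)) {
    s <- element_free_background(len, elements)
    chars <- strsplit(s, "")[[1]]
    positions <- integer(0)
    ok <- TRUE
    for (i in seq_len(nrow(elements))) {
      pat <- elements$pattern[i]
      k <- nchar(pat)
      for (cp in seq_len(planted[i])) {
        # non-overlapping slot, away from already-used positions
        free <- setdiff(seq_len(len - k + 1),
                        unlist(lapply(positions, function(p) (p - k + 1):(p + k - 1))))
        if (length(free) == 0) { ok <- FALSE; break }
        p <- if (length(free) == 1) free else sample(free, 1)
        chars[p:(p + k - 1)] <- strsplit(pat, "")[[1]]
        positions <- c(positions, p)
      }
      if (!ok) break
    }
    if (!ok) next
    s2 <- paste(chars, collapse = "")
    # insertion may create chance matches across junctions; verify exactly
    if (all(scan_elements(s2, elements, both_strands = TRUE) == planted)) {
      return(s2)
    }
  }
  stop("could not plant the requested element counts exactly", call. = FALSE)
}

random_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Simulate a gene family with planted ground truth
#'
#' Builds a toy multi-chromosome layout containing tandem clusters
#' (members within the tandem cutoff on one chromosome) and segmental
#' pairs (farther apart or on different chromosomes), all descended from
#' one family founder CDS so every member protein has the same length and
#' carries the planted domain consensus (the domain region evolves
#' synonymously only). Decoy genes lack the domain. Each gene gets a
#' promoter-bearing contig: 2000 bp of element-free background with
#' exactly the planted element counts inserted, followed by the gene body.
#'
#' @param config list with fields (all defaulted):
#'   `n_chromosomes` (6), `chrom_length` (3e7), `n_tandem_clusters` (2),
#'   `tandem_cluster_size` (3), `n_segmental_pairs` (2), `n_codons` (300),
#'   `omega` (0.2), `subs_per_codon` (0.1), `domain` (a [domain_profile]),
#'   `n_decoys` (3), `elements` (default library), `planted_counts`
#'   (matrix genes x elements or NULL for random 0..3),
#'   `upstream_length` (2000), `tandem_cutoff_bp` (5e6).
#' @param seed integer seed; identical seeds give identical output.
#' @return list `proteins`, `cds` (data.frames id/sequence), `genes`
#'   (named list of `gene_model` with chromosomal layout), `contigs`
#'   (named character: per-gene promoter-bearing contig), `contig_genes`
#'   (gene models positioned on their contig), `truth` (list with
#'   `pair_truth`, `element_truth`, `expression_truth` placeholder,
#'   `seed`).
#' @export
simulate_family <- function(config = list(), seed = 1L) {
  cfg <- modifyList(list(
    n_chromosomes = 6L, chrom_length = 3e7,
    n_tandem_clusters = 2L, tandem_cluster_size = 3L,
    n_segmental_pairs = 2L, n_codons = 300L,
    omega = 0.2, subs_per_codon = 0.1,
    domain = domain_profile("DEXDC", "LDEADRMLDMGF", 10L),
    n_decoys = 3L, elements = default_element_library(),
    planted_counts = NULL, upstream_length = 2000L,
    tandem_cutoff_bp = 5e6
  ), config)
  set.seed(as.integer(seed))
  n_cod <- cfg$n_codons
  dom_aa <- cfg$domain$consensus
  if (grepl("X", dom_aa)) stop("planted domain consensus must be concrete residues", call. = FALSE)
  # founder CDS: random codons with the domain's residues back-translated
  dom_len <- nchar(dom_aa)
  if (n_cod < dom_len + 20) stop("n_codons too small for the planted domain", call. = FALSE)
  dom_start <- sample.int(n_cod - dom_len - 10, 1) + 5
  codons <- sample(SENSE_CODONS, n_cod, replace = TRUE)
  aa2codon <- split(SENSE_CODONS, translate_codon(SENSE_CODONS))
  for (i in seq_len(dom_len)) {
    aa <- substr(dom_aa, i, i)
    cands <- aa2codon[[aa]]
    codons[dom_start + i - 1] <- if (length(cands) == 1) cands else sample(cands, 1)
  }
  founder <- paste(codons, collapse = "")
  frozen <- dom_start:(dom_start + dom_len - 1)

  n_tand_genes <- cfg$n_tandem_clusters * cfg$tandem_cluster_size
  n_seg_genes <- 2L * cfg$n_segmental_pairs
  n_family <- n_tand_genes + n_seg_genes
  gene_ids <- sprintf("FAM-%03d", seq_len(n_family))

  # --- sequences: evolve every member from the founder ---
  member_cds <- character(n_family)
  for (i in seq_len(n_family)) {
    sp <- simulate_codon_pair(
      n_cod, cfg$omega, cfg$subs_per_codon,
      seed = sample.int(1e6, 1), ancestor = founder, frozen_codons = frozen
    )
    member_cds[i] <- sp$cds_a
  }

  # --- chromosomal layout ---
  glen <- 3L * n_cod
  genes <- list()
  pair_rows <- list()
  idx <- 1L
  place <- function(id, chrom, start) {
    gene_model(id, as.character(chrom), start, start + glen, "+",
               cds_id = paste0(id, "_cds"), protein_id = paste0(id, "_p"))
  }
  for (cl in seq_len(cfg$n_tandem_clusters)) {
    chrom <- ((cl - 1L) %% cfg$n_chromosomes) + 1L
    base <- sample.int(cfg$chrom_length / 2, 1)
    members <- character(cfg$tandem_cluster_size)
    for (m in seq_len(cfg$tandem_cluster_size)) {
      id <- gene_ids[idx]; idx <- idx + 1L
      gap <- sample.int(min(cfg$tandem_cutoff_bp / (cfg$tandem_cluster_size + 1), 1e6), 1)
      start <- base + (m - 1L) * (glen + gap)
      genes[[id]] <- place(id, chrom, start)
      members[m] <- id
    }
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        pair_rows[[length(pair_rows) + 1]] <- data.frame(
          gene_a = members[i], gene_b = members[j],
          true_class = "tandem", true_omega = cfg$omega,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  for (sp in seq_len(cfg$n_segmental_pairs)) {
    id1 <- gene_ids[idx]; idx <- idx + 1L
    id2 <- gene_ids[idx]; idx <- idx + 1L
    c1 <- sample.int(cfg$n_chromosomes, 1)
    if (sp %% 2L == 0L) {
      # same chromosome, far apart (> cutoff)
      s1 <- sample.int(1e6, 1)
      s2 <- s1 + cfg$tandem_cutoff_bp + glen + sample.int(1e6, 1)
      if (s2 + glen > cfg$chrom_length) {
        stop("segmental layout does not fit the chromosome length", call. = FALSE)
      }
      genes[[id1]] <- place(id1, c1, s1)
      genes[[id2]] <- place(id2, c1, s2)
    } else {
      c2 <- (c1 %% cfg$n_chromosomes) + 1L
      genes[[id1]] <- place(id1, c1, sample.int(cfg$chrom_length - glen, 1))
      genes[[id2]] <- place(id2, c2, sample.int(cfg$chrom_length - glen, 1))
    }
    pair_rows[[length(pair_rows) + 1]] <- data.frame(
      gene_a = id1, gene_b = id2,
      true_class = "segmental", true_omega = cfg$omega,
      stringsAsFactors = FALSE
    )
  }
  pair_truth <- do.call(rbind, pair_rows)

  # --- decoys: random proteins rejection-checked to lack the domain ---
  decoy_ids <- if (cfg$n_decoys > 0) sprintf("DEC-%03d", seq_len(cfg$n_decoys)) else character(0)
  decoy_cds <- character(cfg$n_decoys)
  for (i in seq_len(cfg$n_decoys)) {
    repeat {
      cand <- random_cds(n_cod)
      if (nrow(scan_domains(translate_cds(cand), list(cfg$domain))) == 0) {
        decoy_cds[i] <- cand
        break
      }
    }
  }

  all_ids <- c(gene_ids, decoy_ids)
  all_cds <- c(member_cds, decoy_cds)
  proteins <- data.frame(id = all_ids,
                         sequence = vapply(all_cds, translate_cds, "", USE.NAMES = FALSE),
                         stringsAsFactors = FALSE)
  cds <- data.frame(id = all_ids, sequence = all_cds, stringsAsFactors = FALSE)
  for (i in seq_along(decoy_ids)) {
    genes[[decoy_ids[i]]] <- place(decoy_ids[i],
                                   sample.int(cfg$n_chromosomes, 1),
                                   sample.int(cfg$chrom_length - glen, 1))
  }

  # --- promoter-bearing contigs with exact planted counts ---
  up <- cfg$upstream_length
  n_el <- nrow(cfg$elements)
  if (is.null(cfg$planted_counts)) {
    planted <- matrix(sample(0:3, length(all_ids) * n_el, replace = TRUE),
                      nrow = length(all_ids),
                      dimnames = list(all_ids, cfg$elements$element_id))
  } else {
    planted <- cfg$planted_counts
  }
  contigs <- character(0)
  contig_genes <- list()
  for (id in all_ids) {
    prom <- plant_elements(up, cfg$elements, planted[id, ])
    body <- cds$sequence[cds$id == id]
    contigs[[id]] <- paste0(prom, body)
    contig_genes[[id]] <- gene_model(id, genes[[id]]$chromosome,
                                     up, up + nchar(body), "+",
                                     cds_id = paste0(id, "_cds"),
                                     protein_id = paste0(id, "_p"))
  }

  truth <- list(pair_truth = pair_truth,
                element_truth = planted,
                seed = as.integer(seed))
  list(proteins = proteins, cds = cds, genes = genes,
       contigs = contigs, contig_genes = contig_genes,
       domain = cfg$domain, config = cfg, truth = truth)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' The reference gene's Ct is constant in expectation across conditions;
#' each target's treatment Ct is `Ct_control - log2(true_fc)` plus
#' Gaussian noise per replicate, so the comparative Ct analysis recovers
#' `true_fc` exactly at zero noise.
#'
#' @param design data.frame with `condition` and logical `is_control`
#'   (exactly one control).
#' @param true_fc named list/matrix: per gene, a named vector of true fold
#'   changes per non-control condition (control is 1 by construction);
#'   or a single named vector applied to one gene `"target"`.
#' @param ref_gene reference gene id (default `"Actin-7"`).
#' @param noise_sd Gaussian Ct noise (>= 0).
#' @param n_reps replicates per condition.
#' @param seed integer seed.
#' @param base_ct mean target Ct in the control; reference Ct is fixed at 15.
#' @return data.frame `gene`, `condition`, `is_control`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(design, true_fc, ref_gene = "Actin-7",
                              noise_sd = 0, n_reps = 3L, seed = 1L,
                              base_ct = 22) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (sum(design$is_control) != 1) {
    stop("design must flag exactly one control condition", call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (!is.list(true_fc)) true_fc <- list(target = true_fc)
  control <- design$condition[design$is_control]
  rows <- list()
  emit <- function(gene, cond, mu) {
    data.frame(gene = gene, condition = cond,
               is_control = cond == control,
               replicate = seq_len(n_reps),
               ct = mu + rnorm(n_reps, 0, noise_sd),
               stringsAsFactors = FALSE)
  }
  for (cond in design$condition) {
    rows[[length(rows) + 1]] <- emit(ref_gene, cond, 15)
  }
  for (g in names(true_fc)) {
    for (cond in design$condition) {
      fc <- if (cond == control) 1 else {
        v <- true_fc[[g]]
        if (!cond %in% names(v)) {
          stop(sprintf("true_fc for gene '%s' lacks condition '%s'", g, cond),
               call. = FALSE)
        }
        v[[cond]]
      }
      rows[[length(rows) + 1]] <- emit(g, cond, base_ct - log2(fc))
    }
  }
  do.call(rbind, rows)
}
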