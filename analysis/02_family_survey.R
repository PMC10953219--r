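#!/usr/bin/env Rscript
# Stage 2 — family identification and characterization: redundancy
# reduction, DEXDc/HELICc-style consensus-domain scan, protein length /
# molecular weight / isoelectric point, chromosome distribution and
# intron counts. Also recomputes the characterization summary of the
# published 133-gene table shipped as a fixture.

suppressMessages(library(rhsurvey))

seed <- if (length(commandArgs(TRUE)) >= 1) as.integer(commandArgs(TRUE)[1]) else 1L
indir <- "results/synthetic"
outdir <- "results/survey"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config(seed = seed)

proteins <- read_fasta(file.path(indir, "proteins.fa"), "protein")
genes <- read_gene_table(file.path(indir, "genes.tsv"))

red <- reduce_redundancy(proteins, cfg$redundancy_identity)
message(sprintf("redundancy reduction: %d -> %d representatives",
                nrow(proteins), nrow(red$kept)))

# the same domain consensus the generator plants (kept in code so the
# survey is reproducible without reading the truth files)
profile <- domain_profile("DEXDC", "LDEADRMLDMGF", 10L)
members <- red$kept[vapply(red$kept$sequence, function(s) {
  nrow(scan_domains(s, list(profile))) > 0
}, NA), , drop = FALSE]
message(sprintf("domain scan: %d of %d representatives carry %s",
                nrow(members), nrow(red$kept), profile$name))

props <- protein_properties(members)
write_stage_tsv(props, file.path(outdir, "protein_properties.tsv"), cfg)

dist <- chromosome_distribution(genes[members$id])
write_stage_tsv(dist$counts, file.path(outdir, "chromosome_distribution.tsv"), cfg)
introns <- data.frame(
  gene_id = members$id,
  introns = vapply(genes[members$id], intron_count, 0L)
)
write_stage_tsv(introns, file.path(outdir, "intron_counts.tsv"), cfg)

# published-table recomputation
pub <- rh_gene_table()
pubdist <- chromosome_distribution(pub$chromosome)
summary <- data.frame(
  stat = c("genes", "protein_len_min", "protein_len_max", "mw_min_kda",
           "mw_max_kda", "pi_min", "pi_max", "top_chromosome",
           "top_chromosome_pct", "unassigned"),
  value = c(nrow(pub), min(pub$protein_length), max(pub$protein_length),
            min(pub$mw_kda), max(pub$mw_kda), min(pub$pi), max(pub$pi),
            pubdist$counts$chromosome[1], pubdist$counts$percent[1],
            pubdist$unassigned)
)
write_stage_tsv(summary, file.path(outdir, "published_table_summary.tsv"), cfg)
message(sprintf(
  "published table: %d genes, %d-%d aa, top chromosome %s (%d%%)",
  nrow(pub), min(pub$protein_length), max(pub$protein_length),
  pubdist$counts$chromosome[1], pubdist$counts$percent[1]
))
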