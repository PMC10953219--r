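#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study system: a toy gene family with two
# tandem clusters, two segmental pairs and three non-family decoys, all
# with machine-readable planted truth. Everything downstream runs on
# these files.

suppressMessages(library(rhsurvey))

seed <- if (length(commandArgs(TRUE)) >= 1) as.integer(commandArgs(TRUE)[1]) else 1L
outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- pipeline_config(seed = seed)
fam <- simulate_family(list(), seed = seed)

write_fasta(fam$proteins, file.path(outdir, "proteins.fa"))
write_fasta(fam$cds, file.path(outdir, "cds.fa"))
write_gene_table(fam$genes, file.path(outdir, "genes.tsv"))
write_fasta(data.frame(id = names(fam$contigs),
                       sequence = unname(unlist(fam$contigs))),
            file.path(outdir, "contigs.fa"))
write_gene_table(fam$contig_genes, file.path(outdir, "contig_genes.tsv"))
write_stage_tsv(fam$truth$pair_truth, file.path(outdir, "truth_pairs.tsv"), cfg)
write.table(data.frame(gene = rownames(fam$truth$element_truth),
                       fam$truth$element_truth, check.names = FALSE),
            file.path(outdir, "truth_elements.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf(
  "simulated %d family members + %d decoys; %d true pairs (%d tandem, %d segmental); config %s",
  sum(grepl("^FAM", fam$proteins$id)), sum(grepl("^DEC", fam$proteins$id)),
  nrow(fam$truth$pair_truth),
  sum(fam$truth$pair_truth$true_class == "tandem"),
  sum(fam$truth$pair_truth$true_class == "segmental"),
  config_digest(cfg)
))
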