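#' Transcribed survey tables shipped with the package
#'
#' Plain-text transcriptions of the printed rapeseed RNA-helicase survey
#' tables: the 133-gene characterization table and the tandem and
#' segmental paralog-pair tables (with Ka, Ks, Ka/Ks and the printed
#' divergence-time column). Run-together printed cells were segmented
#' using the tables' own arithmetic (gene length = end - start; Ka/Ks
#' consistent with Ka and Ks; divergence column proportional to Ks).
#'
#' @return data.frame of the requested table.
#' @name survey_fixtures
NULL

fixture_path <- function(name) {
  system.file("extdata", name, package = "rhsurvey", mustWork = TRUE)
}

#' @rdname survey_fixtures
#' @export
rh_gene_table <- function() {
  df <- read.delim(fixture_path("rapeseed_rh_genes.tsv"),
                   colClasses = c(chromosome = "character"))
  df
}

#' @rdname survey_fixtures
#' @export
rh_tandem_pairs <- function() {
  read.delim(fixture_path("rapeseed_rh_tandem_pairs.tsv"),
             colClasses = c(chr_1 = "character", chr_2 = "character",
                            evalue = "character", ks = "character"))
}

#' @rdname survey_fixtures
#' @export
rh_segmental_pairs <- function() {
  read.delim(fixture_path("rapeseed_rh_segmental_pairs.tsv"),
             colClasses = c(chr_1 = "character", chr_2 = "character",
                            evalue = "character", ks = "character"))
}
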