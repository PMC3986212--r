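#' @title Bundled reference pummelo datasets
#'
#' @description
#' Small plain-text datasets from the published 25-SNP pummelo
#' identification panel and its companion 12-segment sequencing survey,
#' bundled for validation and worked examples: the per-SNP summary
#' statistics of the panel, the haplotype-pair profiles of the 24
#' sequenced accessions, and the published per-segment diversity
#' summaries.
#' @name reference_data
NULL

extdata <- function(file) {
  system.file("extdata", file, package = "snpbarcode", mustWork = TRUE)
}

#' The 25-SNP pummelo panel summary
#'
#' Per-SNP published statistics: reference-anchored SNP name, GenBank
#' accession of the source EST/segment (opaque string), observed and
#' expected heterozygosity, PIC and fixation coefficient, plus the
#' membership of the three published significant-LD groups (column
#' `ld_group`; NA = unlinked). Values are rounded to two decimals as
#' published.
#'
#' @return data.frame with 25 rows
#' @export
pummelo_panel <- function() {
  utils::read.csv(extdata("pummelo_panel_snps.csv"),
                  stringsAsFactors = FALSE)
}

#' Haplotype-pair profiles of the 24 sequenced pummelo accessions
#'
#' Twelve gene segments, each accession carrying an unordered pair of
#' per-segment haplotype ids ("-" = sequence unavailable). Groups:
#' WENDAN, SHATIANYOU and PUMMELO are the 20 true-to-type pummelos used
#' for the published diversity summaries; the four HYBRID accessions
#' carry mandarin haplotypes and were excluded from them.
#'
#' @return a [genotype_matrix()] whose loci are segments
#' @export
pummelo_segment_table <- function() {
  read_haplotype_table(extdata("pummelo_segment_haplotypes.csv"))
}

#' True-to-type accession ids of the sequenced collection
#'
#' @return character vector of 20 accession ids (non-HYBRID groups)
#' @export
pummelo_true_to_type <- function() {
  tab <- pummelo_segment_table()
  tab$accessions$id[tab$accessions$group != "HYBRID"]
}

#' Published per-segment diversity summaries
#'
#' Reference ranges, available sequence counts, segment lengths, SNP and
#' haplotype counts, haplotype diversity (Hd, with the n/(n-1)
#' correction) and nucleotide diversity (pi) for the 12 segments over the
#' 20 true-to-type pummelos, as published (2-dp / 4-dp rounding).
#'
#' @return data.frame with 12 rows
#' @export
pummelo_segment_summary <- function() {
  utils::read.csv(extdata("pummelo_segment_summary.csv"),
                  stringsAsFactors = FALSE)
}
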