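#!/usr/bin/env Rscript
# Stage 3 -- gene segments as genetic barcodes.
#
# Analyses the bundled haplotype-pair table of the 24 sequenced
# accessions: duplicate matching treating each segment as one
# multi-allelic locus, the haplotype census and diversity of the 20
# true-to-type pummelos against the published summaries, and the
# segment-set identity statistics with LD-linked segments merged. Also
# demonstrates SNP calling + EM phasing on simulated alignments.

library(snpbarcode)
dir.create("results", showWarnings = FALSE)

tab <- pummelo_segment_table()
rep_ <- segment_match(tab)
multi <- rep_$clusters[lengths(rep_$clusters) > 1]
cat(sprintf("24 accessions x 12 segments -> %d distinct genotypes\n",
            rep_$n_distinct))
cat(sprintf("only shared profile: {%s}\n",
            paste(multi[[1]], collapse = ", ")))

cen <- haplotype_census(tab, pummelo_true_to_type())
counts <- attr(cen, "counts")
cen$hd <- vapply(counts, function(ct) {
  round_half_up(haplotype_diversity(as.numeric(ct)), 2)
}, numeric(1))
pub <- pummelo_segment_summary()
cen$hd_published <- pub$hd[match(cen$segment, pub$segment)]
write.table(cen, "results/segment_census.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("haplotypes per segment: %s (mean %.1f)\n",
            paste(cen$n_haplotypes, collapse = ","),
            round_half_up(mean(cen$n_haplotypes), 1)))
cat(sprintf("Hd agrees with the published 2-dp value at %d/12 segments (known table inconsistencies at the rest)\n",
            sum(cen$hd == cen$hd_published)))

st <- segment_pi_stats(subset_matrix(tab, pummelo_true_to_type()),
                       n_perm = 199, seed = 20140414)
cat(sprintf("segment-set identity: %d effective loci, PI %.2g, PIsibs %.2g\n",
            st$n_effective, st$pi_total, st$pi_sibs_total))
cat(sprintf("segment capacity (pairwise, 95%%): %d genotypes\n",
            as.integer(discrimination_capacity(st$pi_total))))

# phasing demonstration on synthetic alignments
sim <- simulate_segments(segment_model(seed = 20140414), n_accessions = 24)
phased <- list()
for (seg in names(sim$alignments)) {
  v <- call_segment_snps(sim$alignments[[seg]])
  if (nrow(v$sites) > 0 && nrow(v$sites) <= 12) {
    phased[[seg]] <- phase_segment(v)
  }
}
conf <- vapply(phased, function(p) mean(p$pairs$posterior >= 0.95),
               numeric(1))
cat(sprintf("EM phasing on %d simulated segments: %.0f%% of accessions confidently phased (posterior >= 0.95)\n",
            length(phased), 100 * mean(conf)))
cat("wrote results/segment_census.tsv\n")
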