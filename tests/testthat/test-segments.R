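mk_aln <- function(seqs, id = "SEG") {
  names(seqs) <- names(seqs) %||%
    paste0(rep(sprintf("acc%d", seq_len(length(seqs) / 2)), each = 2),
           "__", rep(1:2, length(seqs) / 2))
  segment_alignment(id, seqs)
}

test_that("clone-support rule rejects singleton variants", {
  base <- strrep("A", 20)
  seqs <- rep(base, 6)
  poke <- function(s, pos, ch) {
    substr(s, pos, pos) <- ch
    s
  }
  seqs[1] <- poke(seqs[1], 5, "G")                 # singleton at 5
  seqs[1:3] <- vapply(seqs[1:3], poke, "", 10, "G") # A x3 / G x3 at 10
  seqs[1:2] <- vapply(seqs[1:2], poke, "", 15, "T") # A x4 / T x2 at 15
  v <- call_segment_snps(mk_aln(seqs))
  expect_equal(v$sites$pos, c(10, 15))
  expect_error(call_segment_snps(mk_aln(rep(base, 3))),
               class = "snpbarcode_validation")
})

test_that("planted SNPs are called exactly despite singleton errors", {
  set.seed(900)
  sim <- simulate_segments(segment_model(n_segments = 1, seed = 900),
                           n_accessions = 12)
  aln <- sim$alignments[[1]]
  truth_sites <- sim$pools[[1]]$sites
  # inject three singleton errors at non-SNP positions
  err_pos <- sample(setdiff(seq_len(aln$length), truth_sites), 3)
  for (k in 1:3) {
    s <- aln$sequences[k]
    old <- substr(s, err_pos[k], err_pos[k])
    substr(s, err_pos[k], err_pos[k]) <- setdiff(c("A", "C", "G", "T"),
                                                 old)[1]
    aln$sequences[k] <- s
  }
  v <- call_segment_snps(aln)
  # every called site is a planted site seen with >= 2 copies per allele
  expect_true(all(v$sites$pos %in% truth_sites))
  expect_false(any(err_pos %in% v$sites$pos))
})

test_that("haplotype census reproduces the published table rows", {
  tab <- pummelo_segment_table()
  cen <- haplotype_census(tab, pummelo_true_to_type())
  expect_equal(cen$n_haplotypes, c(4, 4, 3, 4, 5, 2, 4, 9, 2, 6, 8, 5))
  expect_equal(round_half_up(mean(cen$n_haplotypes), 1), 4.7)
  expect_equal(cen$n_sequences,
               c(40, 40, 40, 40, 40, 40, 40, 40, 38, 40, 38, 36))
  # single accession (h1, h1) -> 1 haplotype over 2 sequences
  solo <- haplotype_census(make_gm(c("1/1"), ids = "x"))
  expect_equal(solo$n_haplotypes, 1)
  expect_equal(solo$n_sequences, 2)
})

test_that("haplotype diversity uses the n/(n-1) correction", {
  expect_equal(round_half_up(haplotype_diversity(c(34, 4)), 2), 0.19)
  expect_equal(haplotype_diversity(c(1, 1)), 1)
  expect_equal(haplotype_diversity(c(5)), 0)
  expect_error(haplotype_diversity(c(1)), class = "snpbarcode_undefined")
})

test_that("published per-segment Hd values reproduce from the haplotype pairs", {
  tab <- pummelo_segment_table()
  cen <- haplotype_census(tab, pummelo_true_to_type())
  counts <- attr(cen, "counts")
  hd <- vapply(counts, function(ct) {
    round_half_up(haplotype_diversity(as.numeric(ct)), 2)
  }, numeric(1))
  published <- pummelo_segment_summary()
  consistent <- c("Cs1g23450", "Cs2g19680", "Cs2g31250", "Cs4g15590",
                  "Cs7g31800")
  expect_equal(unname(hd[consistent]),
               published$hd[match(consistent, published$segment)])
})

test_that("nucleotide diversity equals the all-pairs oracle", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 97), "C", "C", "C"), collapse = "")
  expect_equal(nucleotide_diversity(mk_aln(c(a, b))), 0.03)
  expect_equal(nucleotide_diversity(mk_aln(c(a, a))), 0)
  expect_equal(segregating_sites(mk_aln(c(a, a))), 0)
  set.seed(5)
  seqs <- vapply(1:4, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1))
  aln <- mk_aln(seqs)
  chars <- strsplit(seqs, "")
  pairs <- combn(4, 2)
  ora <- mean(vapply(seq_len(ncol(pairs)), function(k) {
    mean(chars[[pairs[1, k]]] != chars[[pairs[2, k]]])
  }, numeric(1)))
  expect_equal(nucleotide_diversity(aln), ora, tolerance = 1e-12)
  # invariance under reordering; pi = 0 <=> S = 0
  expect_equal(nucleotide_diversity(mk_aln(rev(seqs))),
               nucleotide_diversity(aln))
  expect_true((nucleotide_diversity(aln) == 0) ==
                (segregating_sites(aln) == 0))
})

test_that("phasing resolves a double heterozygote from homozygote context", {
  geno <- rbind(a = c("A/A", "C/C"), b = c("G/G", "T/T"),
                c = c("A/G", "C/T"))
  colnames(geno) <- c("s1", "s2")
  ph <- phase_segment(genotype_matrix(geno))
  # double het phased to the two observed haplotypes A|C and G|T
  haps <- ph$haplotypes[c(ph$pairs$hap1[3], ph$pairs$hap2[3])]
  expect_setequal(unname(haps), c("A|C", "G|T"))
  expect_gt(ph$pairs$posterior[3], 0.5)
  # single-site heterozygote: phase trivially known with posterior 1
  geno1 <- rbind(a = "A/G")
  colnames(geno1) <- "s1"
  ph1 <- phase_segment(genotype_matrix(geno1))
  expect_equal(ph1$pairs$posterior, 1)
})

test_that("phasing recovers planted haplotypes on synthetic segments", {
  sim <- simulate_segments(segment_model(n_segments = 6, seed = 321),
                           n_accessions = 40)
  total <- 0; correct <- 0
  for (seg in names(sim$alignments)) {
    v <- call_segment_snps(sim$alignments[[seg]])
    if (nrow(v$sites) == 0) next
    ph <- phase_segment(v)
    conf <- ph$pairs[ph$pairs$posterior >= 0.95, ]
    if (nrow(conf) == 0) next
    # truth haplotype allele tuples restricted to the called sites
    pool <- sim$pools[[seg]]$haplotypes
    pool_tuples <- vapply(pool, function(s) {
      paste(strsplit(s, "")[[1]][v$sites$pos], collapse = "|")
    }, character(1))
    for (i in seq_len(nrow(conf))) {
      acc <- conf$accession[i]
      truth_ids <- strsplit(sim$table$geno[acc, seg], "/", fixed = TRUE)[[1]]
      truth_tuples <- sort(unname(pool_tuples[truth_ids]))
      inferred <- sort(unname(ph$haplotypes[c(conf$hap1[i], conf$hap2[i])]))
      total <- total + 1
      if (identical(truth_tuples, inferred)) correct <- correct + 1
    }
  }
  expect_gt(total, 100)
  expect_gte(correct / total, 0.90)
})

test_that("segment matching reproduces the published duplicate structure", {
  tab <- pummelo_segment_table()
  t0 <- Sys.time()
  rep_ <- segment_match(tab)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 1)
  expect_equal(rep_$n_distinct, 23)
  multi <- rep_$clusters[lengths(rep_$clusters) > 1]
  expect_equal(length(multi), 1)
  expect_setequal(multi[[1]], c("Hejiangyou", "Lingnanshatianyou"))
  # all-unique tables keep every row distinct
  uniq <- random_gm(15, 8, seed = 1)
  expect_equal(segment_match(uniq, min_shared_loci = 6)$n_distinct,
               length(brute_match_clusters(uniq, 0, 6)))
})

test_that("segment PI statistics multiply over effective loci", {
  # one segment, two equifrequent haplotypes -> PI = 0.375
  cells <- c(rep("1/1", 5), rep("1/2", 10), rep("2/2", 5))
  tab <- make_gm(cells)
  st <- segment_pi_stats(tab, n_perm = 0)
  expect_equal(st$pi_total, pi_random(c(0.5, 0.5)))
  # adding a monomorphic segment leaves PI unchanged
  tab2 <- make_gm(cells, rep("1/1", 20))
  st2 <- segment_pi_stats(tab2, n_perm = 0)
  expect_equal(st2$pi_total, st$pi_total)
  expect_equal(st2$n_effective, 2)
})

test_that("linked segments merge before the product rule", {
  set.seed(17)
  # segment B is a relabelling of segment A -> complete LD
  a <- sample(c("1/1", "1/2", "2/2"), 40, replace = TRUE)
  b <- chartr("12", "34", a)
  c_ <- sample(c("1/1", "1/2", "2/2"), 40, replace = TRUE)
  tab <- make_gm(a, b, c_)
  st <- segment_pi_stats(tab, n_perm = 199, seed = 4)
  expect_equal(st$n_effective, 2)
  expect_equal(length(st$super_loci), 1)
  # the merged locus is counted once: totals use joint haplotype freqs
  expect_equal(nrow(st$per_locus), 2)
})
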