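#' @title Synthetic pummelo-style collections and segment pools
#'
#' @description
#' Generators that emulate the data-generating structure of a structured,
#' partly clonal germplasm collection: a Balding-Nichols island model for
#' SNP allele frequencies (K subpopulations at a target Fst), clonal
#' groups (a cultivar plus its somatic mutants sharing one multilocus
#' genotype), unique sexually derived seedlings, missing data and
#' genotyping error; and, for sequence barcoding, per-segment haplotype
#' pools with Dirichlet frequency laws and a diverged mandarin pool for
#' planting hybrids. Every generator is reproducible from its seed.
#' @name synthetic_data
NULL

#' Population model for genotype simulation
#'
#' @param K number of subpopulations (default 4)
#' @param fst target differentiation in (0,1) (default 0.16)
#' @param n_loci number of bi-allelic SNPs (default 25)
#' @param maf_range ancestral minor-allele-frequency window, a subset of
#'   (0, 0.5] (default c(0.10, 0.50): only markers informative for
#'   identification)
#' @param admixture_alpha Dirichlet concentration for admixed ancestry;
#'   NULL (default) assigns each founder wholly to one deme
#' @param seed RNG seed
#' @return list of class `population_model`
#' @export
population_model <- function(K = 4, fst = 0.16, n_loci = 25,
                             maf_range = c(0.10, 0.50),
                             admixture_alpha = NULL, seed = NULL) {
  stopifnot(fst > 0, fst < 1, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], K >= 1, n_loci >= 1)
  structure(list(K = K, fst = fst, n_loci = n_loci, maf_range = maf_range,
                 admixture_alpha = admixture_alpha, seed = seed),
            class = "population_model")
}

#' Collection design for genotype simulation
#'
#' Defaults mirror the scale of a 260-accession collection: 99 cultivars
#' of which 12 are sampled as three clonal individuals and 30 as two
#' (somatic mutants genotypically identical to their source), 52 further
#' unique accessions, and 55 unique seedlings of sexual origin.
#'
#' @param clone_group_sizes accessions per cultivar clone group
#' @param n_unknown additional unique accessions (group "UNKNOWN")
#' @param n_seedlings unique seedlings (group "MYANMAR"-like)
#' @param missing_rate per-cell missing probability
#' @param genotyping_error_rate per-cell (replacement mode) or per-pair
#'   (swap mode) error probability
#' @param error_mode "replacement" replaces single genotypes with random
#'   Hardy-Weinberg draws; "swap" exchanges whole profiles between random
#'   accession pairs (the sample-loading error mode)
#' @return list of class `collection_design`
#' @export
collection_design <- function(clone_group_sizes = c(rep(3, 12), rep(2, 30),
                                                    rep(1, 57)),
                              n_unknown = 52, n_seedlings = 55,
                              missing_rate = 0.005,
                              genotyping_error_rate = 0,
                              error_mode = c("replacement", "swap")) {
  error_mode <- match.arg(error_mode)
  stopifnot(all(clone_group_sizes >= 1), missing_rate >= 0, missing_rate < 1,
            genotyping_error_rate >= 0, genotyping_error_rate < 1)
  structure(list(clone_group_sizes = clone_group_sizes,
                 n_unknown = n_unknown, n_seedlings = n_seedlings,
                 missing_rate = missing_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 error_mode = error_mode),
            class = "collection_design")
}

r_dirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate a structured, partly clonal SNP collection
#'
#' Ancestral allele frequencies are drawn uniformly inside `maf_range`
#' (minor-allele orientation randomized); subpopulation frequencies
#' follow the Balding-Nichols Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)
#' distribution, redrawn (rejection step) until the pooled minor allele
#' frequency stays inside `maf_range`. Founder genotypes are
#' Hardy-Weinberg draws within their deme (or under Dirichlet-admixed
#' ancestry); clone-group members copy their founder exactly. Genotyping
#' error and missingness are applied last, in that order.
#'
#' @param model a [population_model()]
#' @param design a [collection_design()]
#' @return list: `matrix` (a `genotype_matrix`), `truth` (population
#'   labels and frequencies, clone partition, founder genotypes)
#' @export
simulate_genotypes <- function(model = population_model(),
                               design = collection_design()) {
  n_founders <- length(design$clone_group_sizes) + design$n_unknown +
    design$n_seedlings
  n_acc <- sum(design$clone_group_sizes) + design$n_unknown +
    design$n_seedlings
  if (n_founders < 1) stop_validation("empty design")
  with_seed(model$seed, {
    nt <- c("A", "C", "G", "T")
    loci_alleles <- t(replicate(model$n_loci, sample(nt, 2)))
    loci <- locus_table(
      sprintf("snp%02d", seq_len(model$n_loci)),
      lapply(seq_len(model$n_loci), function(j) sort(loci_alleles[j, ])),
      name = format_snp_name(sprintf("chr%d", sample(1:9, model$n_loci,
                                                     replace = TRUE)),
                             sample.int(3e7, model$n_loci),
                             loci_alleles[, 1], loci_alleles[, 2]))
    p_anc <- stats::runif(model$n_loci, model$maf_range[1],
                          model$maf_range[2])
    flip <- stats::runif(model$n_loci) < 0.5
    p_anc[flip] <- 1 - p_anc[flip] # frequency of allele1, MAF in range
    a <- (1 - model$fst) / model$fst
    deme_freq <- matrix(NA_real_, model$K, model$n_loci)
    for (j in seq_len(model$n_loci)) {
      for (tries in seq_len(1000)) {
        f <- stats::rbeta(model$K, p_anc[j] * a, (1 - p_anc[j]) * a)
        pooled <- mean(f)
        if (min(pooled, 1 - pooled) >= model$maf_range[1] &&
            min(pooled, 1 - pooled) <= model$maf_range[2]) break
      }
      deme_freq[, j] <- f
    }
    founder_deme <- rep_len(seq_len(model$K), n_founders)
    geno_strings <- function(a1, a2) { # index by 3 - dose(allele1)
      lo <- min(a1, a2); hi <- max(a1, a2)
      c(paste0(a1, "/", a1), paste0(lo, "/", hi), paste0(a2, "/", a2))
    }
    if (is.null(model$admixture_alpha)) {
      f <- deme_freq[founder_deme, , drop = FALSE]
      dose <- matrix(stats::rbinom(length(f), 2, f), n_founders,
                     model$n_loci)
    } else {
      dose <- matrix(NA_integer_, n_founders, model$n_loci)
      for (i in seq_len(n_founders)) {
        w <- r_dirichlet(rep(model$admixture_alpha, model$K))
        src <- matrix(sample(model$K, 2 * model$n_loci, replace = TRUE,
                             prob = w), 2)
        pj <- rbind(deme_freq[cbind(src[1, ], seq_len(model$n_loci))],
                    deme_freq[cbind(src[2, ], seq_len(model$n_loci))])
        dose[i, ] <- colSums(matrix(stats::runif(2 * model$n_loci), 2) < pj)
      }
    }
    founder_geno <- matrix(NA_character_, n_founders, model$n_loci)
    for (j in seq_len(model$n_loci)) {
      gs <- geno_strings(loci_alleles[j, 1], loci_alleles[j, 2])
      founder_geno[, j] <- gs[3 - dose[, j]]
    }
    # expand founders into accessions
    ids <- character(0); group <- character(0); founder_of <- integer(0)
    clone_partition <- list()
    fidx <- 0
    for (g in seq_along(design$clone_group_sizes)) {
      fidx <- fidx + 1
      members <- sprintf("CUL%03d%s", g,
                         letters[seq_len(design$clone_group_sizes[g])])
      ids <- c(ids, members)
      group <- c(group, rep("CUL", length(members)))
      founder_of <- c(founder_of, rep(fidx, length(members)))
      clone_partition[[g]] <- members
    }
    if (design$n_unknown > 0) {
      u <- sprintf("UNK%03d", seq_len(design$n_unknown))
      ids <- c(ids, u); group <- c(group, rep("UNKNOWN", length(u)))
      founder_of <- c(founder_of, fidx + seq_len(design$n_unknown))
      fidx <- fidx + design$n_unknown
    }
    if (design$n_seedlings > 0) {
      s <- sprintf("MYA%03d", seq_len(design$n_seedlings))
      ids <- c(ids, s); group <- c(group, rep("MYANMAR", length(s)))
      founder_of <- c(founder_of, fidx + seq_len(design$n_seedlings))
      fidx <- fidx + design$n_seedlings
    }
    geno <- founder_geno[founder_of, , drop = FALSE]
    # genotyping error
    er <- design$genotyping_error_rate
    if (er > 0) {
      if (design$error_mode == "replacement") {
        hit <- which(stats::runif(length(geno)) < er)
        for (h in hit) {
          j <- ((h - 1) %/% n_acc) + 1
          f <- mean(deme_freq[, j])
          dose <- stats::rbinom(1, 2, f)
          al <- c(rep(loci_alleles[j, 1], dose),
                  rep(loci_alleles[j, 2], 2 - dose))
          geno[h] <- paste(sort(al), collapse = "/")
        }
      } else {
        n_swaps <- stats::rbinom(1, n_acc, er)
        for (k in seq_len(n_swaps)) {
          pr <- sample(n_acc, 2)
          tmp <- geno[pr[1], ]; geno[pr[1], ] <- geno[pr[2], ]
          geno[pr[2], ] <- tmp
        }
      }
    }
    if (design$missing_rate > 0) {
      geno[stats::runif(length(geno)) < design$missing_rate] <- NA_character_
    }
    rownames(geno) <- ids
    gm <- genotype_matrix(geno, loci = loci,
                          accessions = data.frame(id = ids, group = group,
                                                  stringsAsFactors = FALSE))
    list(matrix = gm,
         truth = list(founder_deme = founder_deme,
                      deme_of = stats::setNames(
                        paste0("P", founder_deme[founder_of]), ids),
                      deme_freq = deme_freq, p_anc = p_anc,
                      clone_partition = clone_partition,
                      founder_geno = founder_geno))
  })
}

#' Segment model for sequence simulation
#'
#' Per-segment ranges follow the reference barcoding panel: lengths
#' 410-631 bp, 1-10 SNPs and 2-9 haplotypes per segment.
#'
#' @param n_segments number of segments (default 12)
#' @param length_range segment length window in bp
#' @param n_snps_range SNPs per segment
#' @param n_haplotypes_range haplotypes per segment (capped at 2^n_snps)
#' @param dirichlet_alpha symmetric Dirichlet concentration of the
#'   haplotype frequency law (default 1: uniform over the simplex)
#' @param divergence per-site divergence of the mandarin pool from the
#'   pummelo base sequence (default 0.02)
#' @param seed RNG seed
#' @return list of class `segment_model`
#' @export
segment_model <- function(n_segments = 12, length_range = c(410, 631),
                          n_snps_range = c(1, 10),
                          n_haplotypes_range = c(2, 9),
                          dirichlet_alpha = 1, divergence = 0.02,
                          seed = NULL) {
  structure(list(n_segments = n_segments, length_range = length_range,
                 n_snps_range = n_snps_range,
                 n_haplotypes_range = n_haplotypes_range,
                 dirichlet_alpha = dirichlet_alpha,
                 divergence = divergence, seed = seed),
            class = "segment_model")
}

# uniform draw from lo..hi that is safe when lo == hi (length-1 vectors
# would otherwise trigger sample()'s 1:x behaviour)
sample_range <- function(lo, hi) {
  if (lo == hi) return(lo)
  sample(lo:hi, 1)
}

mutate_base <- function(seq_chars, pos) {
  nt <- c("A", "C", "G", "T")
  for (p in pos) {
    seq_chars[p] <- sample(setdiff(nt, seq_chars[p]), 1)
  }
  seq_chars
}

#' Simulate aligned segment sequences for a diploid collection
#'
#' For each segment a haplotype pool is built by placing the segment's
#' SNP alleles on a random base sequence (every SNP site polymorphic in
#' the pool); pool frequencies follow a symmetric Dirichlet law. Each
#' accession draws two haplotypes; hybrids replace one copy with a
#' haplotype from a diverged mandarin pool at a random subset of
#' segments. Both the phased truth (haplotype table) and the alignments
#' (two sequences per accession) are returned, along with per-class
#' reference sequences for hybrid screening.
#'
#' @param model a [segment_model()]
#' @param n_accessions number of diploid accessions (default 24)
#' @param hybrid_fraction fraction of accessions planted as hybrids
#' @return list: `alignments` (list of `segment_alignment`), `table`
#'   (truth haplotype table), `hybrids` (logical named vector),
#'   `pools` (per segment: haplotype sequences, frequencies, mandarin
#'   haplotypes), `references` (data.frame usable with [flag_hybrids()])
#' @export
simulate_segments <- function(model = segment_model(), n_accessions = 24,
                              hybrid_fraction = 0) {
  with_seed(model$seed, {
    nt <- c("A", "C", "G", "T")
    acc <- sprintf("ACC%03d", seq_len(n_accessions))
    n_hyb <- round(hybrid_fraction * n_accessions)
    hybrids <- stats::setNames(rep(FALSE, n_accessions), acc)
    if (n_hyb > 0) hybrids[sample(n_accessions, n_hyb)] <- TRUE
    alignments <- list()
    pools <- list()
    refs <- list()
    tab_cols <- list()
    for (s in seq_len(model$n_segments)) {
      seg_id <- sprintf("SEG%02d", s)
      L <- sample_range(model$length_range[1], model$length_range[2])
      base <- sample(nt, L, replace = TRUE)
      n_snps <- sample_range(model$n_snps_range[1], model$n_snps_range[2])
      sites <- sort(sample.int(L, n_snps))
      k_max <- min(model$n_haplotypes_range[2], 2^n_snps)
      k_min <- min(model$n_haplotypes_range[1], k_max)
      k <- sample_range(k_min, k_max)
      # haplotype pool: distinct allele vectors; the all-reference and
      # all-alternate rows guarantee every SNP site is polymorphic
      alt <- vapply(sites, function(p) sample(setdiff(nt, base[p]), 1),
                    character(1))
      repeat {
        combos <- rbind(matrix(FALSE, 1, n_snps), matrix(TRUE, 1, n_snps),
                        matrix(stats::runif((k - 2) * n_snps) < 0.5,
                               max(0, k - 2), n_snps))
        combos <- unique(combos)
        if (nrow(combos) == k) break
      }
      hap_seqs <- apply(combos, 1, function(use_alt) {
        sc <- base
        sc[sites[use_alt]] <- alt[use_alt]
        paste(sc, collapse = "")
      })
      names(hap_seqs) <- as.character(seq_len(k))
      freqs <- r_dirichlet(rep(model$dirichlet_alpha, k))
      # diverged mandarin pool (two haplotypes)
      n_div <- max(1, round(model$divergence * L))
      mand_base <- mutate_base(base, sample.int(L, n_div))
      mand_seqs <- c(M1 = paste(mand_base, collapse = ""),
                     M2 = paste(mutate_base(mand_base,
                                            sample.int(L, max(1, n_snps))),
                                collapse = ""))
      draws <- matrix(sample(names(hap_seqs), 2 * n_accessions,
                             replace = TRUE, prob = freqs),
                      ncol = 2)
      hap_id <- matrix(draws, ncol = 2)
      seqs <- character(0)
      cells <- character(n_accessions)
      for (i in seq_len(n_accessions)) {
        pair_ids <- hap_id[i, ]
        pair_seq <- hap_seqs[pair_ids]
        if (hybrids[i] && stats::runif(1) < 0.6) {
          m <- sample(names(mand_seqs), 1)
          pair_ids[2] <- m
          pair_seq[2] <- mand_seqs[m]
        }
        cells[i] <- paste(sort_alleles(pair_ids), collapse = "/")
        seqs <- c(seqs, stats::setNames(pair_seq,
                                        paste0(acc[i], "__", 1:2)))
      }
      alignments[[seg_id]] <- segment_alignment(seg_id, seqs)
      pools[[seg_id]] <- list(haplotypes = hap_seqs, freqs = freqs,
                              mandarin = mand_seqs, sites = sites)
      refs[[seg_id]] <- data.frame(
        segment = seg_id,
        label = c("pummelo_ref", "mandarin_ref1", "mandarin_ref2"),
        class = c("pummelo", "mandarin", "mandarin"),
        sequence = c(paste(base, collapse = ""), mand_seqs[1], mand_seqs[2]),
        stringsAsFactors = FALSE)
      tab_cols[[seg_id]] <- cells
    }
    geno <- do.call(cbind, tab_cols)
    rownames(geno) <- acc
    table <- genotype_matrix(geno)
    list(alignments = alignments, table = table, hybrids = hybrids,
         pools = pools, references = do.call(rbind, refs))
  })
}
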