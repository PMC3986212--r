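#' @title Per-locus descriptive and selection statistics
#'
#' @description
#' Summaries used both to describe a marker panel and to select one:
#' allele frequencies, observed (Ho) and expected (He) heterozygosity,
#' Botstein's polymorphic information content (PIC), the fixation
#' coefficient f = (He - Ho)/He, an exact Hardy-Weinberg test, the
#' Weir-Cockerham Fst estimator, and a greedy MAF/PIC/LD-aware panel
#' selector. He is the plain Nei gene diversity 1 - sum(p^2) without a
#' small-sample correction; the n/(n-1) correction is applied only to
#' haplotype diversity of sequence segments (see [haplotype_diversity()]),
#' where the published reference values require it.
#' @name marker_stats
NULL

#' Allele frequencies at one locus
#'
#' Counts gene copies (two per typed individual) over non-missing
#' genotypes only.
#'
#' @param x a `genotype_matrix`
#' @param locus locus id or column index
#' @return named numeric vector of proportions summing to 1, with
#'   attribute `n_copies` (number of non-missing gene copies)
#' @export
allele_frequencies <- function(x, locus) {
  j <- if (is.character(locus)) match(locus, x$loci$locus_id) else locus
  if (is.na(j)) stop_validation(sprintf("unknown locus '%s'", locus))
  cells <- x$geno[, j]
  cells <- cells[!is.na(cells)]
  if (!length(cells)) {
    stop_undefined(sprintf("locus '%s' has no typed genotypes",
                           x$loci$locus_id[j]))
  }
  counts <- table(unlist(strsplit(cells, "/", fixed = TRUE)))
  counts <- counts[sort_alleles(names(counts))]
  p <- as.numeric(counts) / sum(counts)
  names(p) <- names(counts)
  attr(p, "n_copies") <- sum(counts)
  p
}

#' Expected heterozygosity (Nei gene diversity)
#'
#' He = 1 - sum(p_i^2), uncorrected.
#'
#' @param p allele frequency vector
#' @return He in [0, 1]
#' @export
expected_heterozygosity <- function(p) {
  check_freqs(p)
  1 - sum(p^2)
}

#' Polymorphic information content (Botstein)
#'
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2. For a bi-allelic locus
#' this reduces to He - 2 (p q)^2. PIC <= He for every frequency vector.
#'
#' @param p allele frequency vector
#' @return PIC in [0, 1]
#' @export
pic <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

#' Fixation coefficient
#'
#' f = (He - Ho)/He; negative values indicate heterozygote excess.
#'
#' @param ho observed heterozygosity
#' @param he expected heterozygosity (> 0)
#' @return f (may be negative)
#' @export
fixation_coefficient <- function(ho, he) {
  if (any(he <= 0)) stop_undefined("fixation coefficient undefined at He = 0")
  (he - ho) / he
}

check_freqs <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_validation("allele frequencies must be non-negative and sum to 1")
  }
  invisible(TRUE)
}

#' Exact Hardy-Weinberg test for a bi-allelic locus
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the summed probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Computed with
#' the standard probability recurrence over heterozygote counts of the
#' correct parity.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom/het/hom)
#' @return p-value; a monomorphic locus returns 1 with a warning
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_aa + n_ab
  nB <- 2 * n_bb + n_ab
  if (nA == 0 || nB == 0) {
    warning("monomorphic locus: HWE test undefined, returning p = 1")
    return(1)
  }
  rare <- min(nA, nB)
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized probabilities via the recurrence
  # P(h+2)/P(h) = (nAA(h) * nBB(h) * 4) / ((h+2)(h+1))  with
  # nAA(h) = (nA - h)/2, nBB(h) = (nB - h)/2
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    lp[k] <- lp[k - 1] +
      log(4 * ((nA - h) / 2) * ((nB - h) / 2)) - log((h + 2) * (h + 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_ab)
  if (!length(obs)) stop_validation("genotype counts inconsistent")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-9)]))
}

#' Per-locus summary statistics
#'
#' One row per locus: typed sample size, minor allele frequency, Ho, He,
#' PIC, fixation coefficient and (for bi-allelic loci) the exact HWE
#' p-value. Monomorphic loci get f = NA.
#'
#' @param x a `genotype_matrix`
#' @param hwe compute HWE p-values (bi-allelic loci only)?
#' @return data.frame
#' @export
locus_stats <- function(x, hwe = TRUE) {
  rows <- lapply(seq_len(ncol(x$geno)), function(j) {
    cells <- x$geno[, j]
    typed <- cells[!is.na(cells)]
    n <- length(typed)
    if (n == 0) {
      return(data.frame(locus_id = x$loci$locus_id[j], n = 0, maf = NA_real_,
                        ho = NA_real_, he = NA_real_, pic = NA_real_,
                        f = NA_real_, hwe_p = NA_real_))
    }
    p <- allele_frequencies(x, j)
    al <- vapply(strsplit(typed, "/", fixed = TRUE),
                 function(a) a[1] != a[2], logical(1))
    ho <- mean(al)
    he <- expected_heterozygosity(p)
    f <- if (he > 0) fixation_coefficient(ho, he) else NA_real_
    hp <- NA_real_
    if (hwe && length(p) == 2) {
      a1 <- names(p)[1]
      gt <- table(factor(typed, levels = c(paste0(a1, "/", a1),
                                           paste(sort_alleles(names(p)), collapse = "/"),
                                           paste0(names(p)[2], "/", names(p)[2]))))
      hp <- suppressWarnings(hwe_exact_test(gt[1], gt[2], gt[3]))
    }
    data.frame(locus_id = x$loci$locus_id[j], n = n,
               maf = if (length(p) > 1) min(p) else 0,
               ho = ho, he = he, pic = pic(p), f = f, hwe_p = hp)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-locus Weir-Cockerham Fst
#'
#' The theta estimator of Weir & Cockerham (1984), combined across loci and
#' alleles as a ratio of sums of the variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals).
#'
#' @param x a `genotype_matrix`
#' @param groups named character vector mapping accession id to group
#'   label, or NULL to use the matrix's accession `group` column
#' @return theta estimate (single number); attribute `components` holds
#'   the summed a, b, c
#' @export
wc_fst <- function(x, groups = NULL) {
  if (is.null(groups)) {
    groups <- stats::setNames(x$accessions$group, x$accessions$id)
  }
  g <- groups[x$accessions$id]
  keep <- !is.na(g)
  labels <- unique(g[keep])
  if (length(labels) < 2) stop_undefined("Fst needs at least two groups")
  A <- B <- C <- 0
  for (j in seq_len(ncol(x$geno))) {
    cells <- x$geno[, j]
    split_al <- strsplit(cells, "/", fixed = TRUE)
    alleles <- unique(unlist(split_al[!is.na(cells)]))
    if (length(alleles) < 2) next
    # per-group sample size, allele freq, het freq (per allele)
    for (al in alleles) {
      ni <- pi_ <- hi <- numeric(0)
      for (lab in labels) {
        rows <- which(keep & g == lab & !is.na(cells))
        if (length(rows) < 2) next
        pairs <- split_al[rows]
        dose <- vapply(pairs, function(a) sum(a == al), numeric(1))
        ni <- c(ni, length(rows))
        pi_ <- c(pi_, mean(dose) / 2)
        hi <- c(hi, mean(dose == 1))
      }
      r <- length(ni)
      if (r < 2) next
      nbar <- mean(ni)
      nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
      pbar <- sum(ni * pi_) / (r * nbar)
      s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      if (nbar <= 1 || nc <= 0) next
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                          (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
  }
  if (A + B + C == 0) stop_undefined("no polymorphic loci for Fst")
  theta <- A / (A + B + C)
  attr(theta, "components") <- c(a = A, b = B, c = C)
  theta
}

#' Select an identification panel by MAF, PIC and linkage
#'
#' Candidates with minor allele frequency at or below `maf_min` are
#' removed (the retention rule is strictly "MAF > maf_min"). Survivors are
#' ranked by PIC (descending, ties broken by locus id) and accepted
#' greedily, skipping any locus in significant LD (r2 > `r2_max` with
#' p < `alpha`) with an already accepted locus, unless the locus is listed
#' in `keep_linked`, in which case it is accepted and flagged as a
#' super-locus candidate.
#'
#' @param stats data.frame as from [locus_stats()] (needs `locus_id`,
#'   `maf`, `pic`)
#' @param r2,p square matrices of pairwise LD r2 and significance,
#'   dimnames = locus ids (NA entries are treated as "no evidence of LD")
#' @param maf_min MAF exclusion threshold (default 0.10)
#' @param r2_max LD threshold (default 0.10)
#' @param alpha LD significance level (default 0.05)
#' @param n_panel maximum panel size
#' @param keep_linked locus ids allowed into the panel despite LD
#' @return data.frame of accepted loci in acceptance order with a
#'   `super_locus_flag` column; empty (with a warning) if no candidates
#'   survive the MAF filter
#' @export
select_panel <- function(stats, r2 = NULL, p = NULL, maf_min = 0.10,
                         r2_max = 0.10, alpha = 0.05, n_panel = Inf,
                         keep_linked = character(0)) {
  cand <- stats[!is.na(stats$maf) & stats$maf > maf_min, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no candidates pass the MAF filter; returning empty panel")
    return(cand[, c("locus_id", "maf", "pic"), drop = FALSE])
  }
  cand <- cand[order(-cand$pic, cand$locus_id), , drop = FALSE]
  accepted <- character(0)
  flag <- logical(0)
  in_ld <- function(a, b) {
    if (is.null(r2) || is.null(p)) return(FALSE)
    v <- r2[a, b]; pv <- p[a, b]
    !is.na(v) && !is.na(pv) && v > r2_max && pv < alpha
  }
  for (id in cand$locus_id) {
    if (length(accepted) >= n_panel) break
    linked <- any(vapply(accepted, function(a) in_ld(id, a), logical(1)))
    if (!linked) {
      accepted <- c(accepted, id); flag <- c(flag, FALSE)
    } else if (id %in% keep_linked) {
      accepted <- c(accepted, id); flag <- c(flag, TRUE)
    }
  }
  out <- cand[match(accepted, cand$locus_id), , drop = FALSE]
  out$super_locus_flag <- flag
  rownames(out) <- NULL
  out
}
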