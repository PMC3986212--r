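#' @title Sequence-segment genetic barcodes
#'
#' @description
#' Analysis of short (roughly 400-650 bp) aligned nuclear gene segments
#' sequenced in a diploid collection: SNP calling under the cloned-amplicon
#' support rule, segregating sites, nucleotide diversity (pi), haplotype
#' census and Nei's unbiased haplotype diversity (Hd), EM phasing of
#' unphased segment genotypes, and segment-based duplicate matching where
#' each segment acts as one multi-allelic locus whose alleles are
#' haplotypes.
#' @name segment_analysis
NULL

# ---- alignment container ----------------------------------------------

#' Construct an aligned segment
#'
#' @param segment_id gene/segment identifier (e.g. "Cs1g16760")
#' @param sequences named character vector of equal-length aligned
#'   sequences; names are `"<accession>__<copy>"` (two copies per diploid
#'   accession) unless `accession`/`copy` are given
#' @param accession,copy optional explicit source annotation
#' @param location optional reference range string ("chr1:100-650")
#' @return object of class `segment_alignment`
#' @export
segment_alignment <- function(segment_id, sequences, accession = NULL,
                              copy = NULL, location = NA_character_) {
  sequences <- toupper(unlist(sequences))
  L <- unique(nchar(sequences))
  if (length(L) != 1) stop_validation("aligned sequences must share a length")
  if (any(grepl("[^ACGTN-]", sequences))) {
    stop_validation("alignment alphabet is {A,C,G,T,N,-}")
  }
  if (is.null(accession)) {
    parts <- strsplit(names(sequences), "__", fixed = TRUE)
    accession <- vapply(parts, `[`, character(1), 1)
    copy <- vapply(parts, function(p) p[2] %||% "1", character(1))
  }
  structure(list(segment_id = segment_id, sequences = sequences,
                 accession = accession, copy = copy,
                 length = L, location = location),
            class = "segment_alignment")
}

#' @export
print.segment_alignment <- function(x, ...) {
  cat(sprintf("<segment_alignment> %s: %d sequences x %d bp\n",
              x$segment_id, length(x$sequences), x$length))
  invisible(x)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$sequences, ""))
}

#' Read / write one aligned segment as FASTA
#'
#' Sequence ids follow the `"<accession>__<copy>"` convention.
#'
#' @param file path
#' @param segment_id defaults to the file name without extension
#' @return a [segment_alignment()]
#' @export
read_segment_fasta <- function(file, segment_id = NULL) {
  if (is.null(segment_id)) {
    segment_id <- sub("\\.(fa|fasta|fna)$", "", basename(file))
  }
  dna <- ape::read.FASTA(file)
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  segment_alignment(segment_id, stats::setNames(toupper(seqs), names(dna)))
}

#' @rdname read_segment_fasta
#' @param aln a `segment_alignment`
#' @export
write_segment_fasta <- function(aln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(aln$sequences)) {
    writeLines(c(paste0(">", names(aln$sequences)[i]), aln$sequences[i]), con)
  }
  invisible(file)
}

# ---- SNP calling -------------------------------------------------------

#' Call SNPs in an aligned segment under the clone-support rule
#'
#' A column is a putative SNP when at least two alleles are each carried
#' by `min_clone_support` or more sequences (singleton variants, the
#' signature of PCR/sequencing error in cloned amplicons, are rejected).
#' N and gap characters never support an allele. Per-accession unphased
#' genotypes are read off the two sequence copies; a copy carrying a
#' non-supported allele (or N/gap) at a retained site yields a missing
#' genotype there.
#'
#' @param aln a `segment_alignment` with >= 4 sequences
#' @param min_clone_support minimum sequences per allele (default 2)
#' @return object of class `segment_variants`: `sites` (data.frame of
#'   column positions and comma-joined alleles) and `genotypes` (accession
#'   x site matrix of "X/Y" strings)
#' @export
call_segment_snps <- function(aln, min_clone_support = 2) {
  if (length(aln$sequences) < 4) {
    stop_validation("SNP calling needs at least 4 sequences")
  }
  m <- aln_matrix(aln)
  keep_pos <- integer(0)
  keep_alleles <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    ok <- names(tab)[tab >= min_clone_support]
    if (length(ok) >= 2) {
      keep_pos <- c(keep_pos, j)
      keep_alleles[[length(keep_alleles) + 1]] <- sort(ok)
    }
  }
  accs <- unique(aln$accession)
  site_ids <- if (length(keep_pos)) paste0("s", keep_pos) else character(0)
  geno <- matrix(NA_character_, length(accs), length(keep_pos),
                 dimnames = list(accs, site_ids))
  for (a in accs) {
    rows <- which(aln$accession == a)
    if (length(rows) != 2) next # genotypes need exactly two copies
    for (k in seq_along(keep_pos)) {
      al <- m[rows, keep_pos[k]]
      if (all(al %in% keep_alleles[[k]])) {
        geno[a, k] <- paste(sort(al), collapse = "/")
      }
    }
  }
  structure(list(segment_id = aln$segment_id,
                 sites = data.frame(
                   pos = keep_pos,
                   alleles = vapply(keep_alleles, paste, character(1),
                                    collapse = ","),
                   stringsAsFactors = FALSE),
                 genotypes = geno),
            class = "segment_variants")
}

# ---- haplotype tables --------------------------------------------------

#' Read a haplotype-pair table from CSV
#'
#' Rows are accessions, columns segments; cells are unordered haplotype-id
#' pairs `"1/2"` with `"-"` for missing. Haplotype ids are per-segment
#' namespaces. An optional `group` column carries the collection grouping.
#' The result is an ordinary [genotype_matrix()] whose "loci" are segments
#' and whose "alleles" are haplotype ids, so all matching and identity
#' machinery applies unchanged.
#'
#' @param file path or connection
#' @return a `genotype_matrix`
#' @export
read_haplotype_table <- function(file) {
  read_genotype_csv(file)
}

#' Haplotype census per segment
#'
#' Counts haplotypes over the non-missing pairs of the chosen accessions;
#' the number of sequences is twice the number of typed accessions.
#'
#' @param x a haplotype table (`genotype_matrix`)
#' @param accessions accession ids to include (default all)
#' @return data.frame with one row per segment: `segment`, `n_sequences`,
#'   `n_haplotypes`; attribute `counts` holds the per-segment haplotype
#'   count tables
#' @export
haplotype_census <- function(x, accessions = NULL) {
  if (!is.null(accessions)) x <- subset_matrix(x, accessions = accessions)
  counts <- lapply(seq_len(ncol(x$geno)), function(j) {
    cells <- x$geno[, j]
    cells <- cells[!is.na(cells)]
    tab <- table(unlist(strsplit(cells, "/", fixed = TRUE)))
    tab[sort_alleles(names(tab))]
  })
  names(counts) <- x$loci$locus_id
  out <- data.frame(segment = x$loci$locus_id,
                    n_sequences = vapply(counts, sum, numeric(1)),
                    n_haplotypes = vapply(counts, length, numeric(1)),
                    row.names = NULL)
  attr(out, "counts") <- counts
  out
}

#' Nei's unbiased haplotype diversity
#'
#' Hd = n (1 - sum p_i^2) / (n - 1) with p_i = count_i / n. The n/(n-1)
#' small-sample correction is deliberate here (and absent from the SNP
#' [expected_heterozygosity()]): segment reference values are reported in
#' the corrected form.
#'
#' @param counts haplotype counts (vector) or a frequency vector if `n`
#'   is supplied
#' @param n number of sequences (default `sum(counts)`)
#' @return Hd in [0, 1]
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  if (n < 2) stop_undefined("haplotype diversity needs n >= 2 sequences")
  p <- counts / sum(counts)
  n * (1 - sum(p^2)) / (n - 1)
}

# ---- diversity from alignments ----------------------------------------

#' Segregating sites of an alignment
#'
#' Number of columns with two or more distinct A/C/G/T bases (N and gaps
#' ignored).
#'
#' @param aln a `segment_alignment`
#' @return integer count S
#' @export
segregating_sites <- function(aln) {
  m <- aln_matrix(aln)
  sum(apply(m, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
  }))
}

pair_diff <- function(a, b) {
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  c(diff = sum(a[valid] != b[valid]), valid = sum(valid))
}

#' Nucleotide diversity per site
#'
#' The unbiased estimator: the average over all sequence pairs of the
#' proportion of differing sites, with sites carrying N or a gap in
#' either sequence excluded pairwise. Equivalently
#' pi = n/(n-1) * sum_{i<j} 2 p_i p_j d_ij / L over haplotype frequencies.
#'
#' @param aln a `segment_alignment` with >= 2 sequences
#' @return pi (differences per site)
#' @export
nucleotide_diversity <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop_undefined("nucleotide diversity needs >= 2 sequences")
  combos <- utils::combn(n, 2)
  vals <- vapply(seq_len(ncol(combos)), function(k) {
    pd <- pair_diff(m[combos[1, k], ], m[combos[2, k], ])
    if (pd[["valid"]] == 0) return(NA_real_)
    pd[["diff"]] / pd[["valid"]]
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Per-segment diversity summary
#'
#' Table-style report over a set of alignments: available sequences,
#' segment length, segregating sites, haplotype count, Hd and pi.
#' Haplotypes here are the distinct sequences restricted to the called
#' SNP sites.
#'
#' @param alignments list of `segment_alignment`
#' @param min_clone_support passed to [call_segment_snps()]
#' @return data.frame, one row per segment
#' @export
segment_diversity_stats <- function(alignments, min_clone_support = 2) {
  rows <- lapply(alignments, function(aln) {
    v <- call_segment_snps(aln, min_clone_support)
    m <- aln_matrix(aln)
    if (nrow(v$sites)) {
      haps <- apply(m[, v$sites$pos, drop = FALSE], 1, paste, collapse = "")
      ok <- !grepl("[^ACGT]", haps)
      counts <- table(haps[ok])
      hd <- haplotype_diversity(as.numeric(counts))
      nh <- length(counts)
    } else {
      hd <- 0; nh <- 1
    }
    data.frame(segment = aln$segment_id,
               n_sequences = length(aln$sequences),
               length_bp = aln$length,
               n_snps = nrow(v$sites),
               n_haplotypes = nh,
               hd = hd,
               pi = nucleotide_diversity(aln))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- phasing -----------------------------------------------------------

#' Phase a segment's unphased genotypes by EM
#'
#' Haplotype frequencies over the called SNP sites are estimated with the
#' same EM as [em_haplotype_frequencies()] (haplotype space restricted to
#' haplotypes compatible with at least one fully typed accession), and
#' each accession is assigned its most probable haplotype pair with its
#' phase posterior. Haplotype ids are dense integers assigned by first
#' occurrence in accession input order. Requires <= 12 sites.
#'
#' @param variants a `segment_variants` (from [call_segment_snps()]) or a
#'   `genotype_matrix` of per-site genotypes
#' @param max_iter,tol EM control; non-convergence yields the best
#'   likelihood reached plus a warning
#' @return list: `pairs` (data.frame accession, hap1, hap2, posterior),
#'   `haplotypes` (named map id -> "A|C|..." allele tuple), `fit` (the
#'   `hap_freqs` object), `segment_id`
#' @export
phase_segment <- function(variants, max_iter = 1000, tol = 1e-8) {
  if (inherits(variants, "segment_variants")) {
    geno <- variants$genotypes
    loci <- locus_table(colnames(geno),
                        strsplit(variants$sites$alleles, ",", fixed = TRUE))
    gm <- genotype_matrix(geno, loci = loci)
    seg_id <- variants$segment_id
  } else {
    gm <- variants
    seg_id <- NA_character_
  }
  if (ncol(gm$geno) > 12) {
    stop_validation("phasing supports at most 12 sites per segment")
  }
  fit <- em_haplotype_frequencies(gm, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    warning(sprintf("phasing EM did not converge for segment %s; %s",
                    seg_id, "returning best likelihood reached"))
  }
  ids <- character(0)
  next_id <- 0
  take <- function(h) {
    if (!h %in% names(ids)) {
      next_id <<- next_id + 1
      ids[[h]] <<- as.character(next_id)
    }
    ids[[h]]
  }
  pairs <- fit$assignments
  h1 <- h2 <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) { # first-occurrence id assignment
    h1[i] <- take(pairs$hap1[i])
    h2[i] <- take(pairs$hap2[i])
  }
  pairs$hap1 <- h1
  pairs$hap2 <- h2
  hap_map <- stats::setNames(names(ids), unname(ids))
  list(pairs = pairs, haplotypes = hap_map, fit = fit, segment_id = seg_id)
}

#' Build a haplotype table from phased segments
#'
#' @param phased list of [phase_segment()] results
#' @param accessions accession ids defining row order (default: union in
#'   first-seen order)
#' @param posterior_min assignments below this phase posterior are set
#'   missing (default 0.95)
#' @return a `genotype_matrix` haplotype table
#' @export
haplotype_table_from_phased <- function(phased, accessions = NULL,
                                        posterior_min = 0.95) {
  if (is.null(accessions)) {
    accessions <- unique(unlist(lapply(phased, function(p) p$pairs$accession)))
  }
  cols <- lapply(phased, function(p) {
    cell <- rep(NA_character_, length(accessions))
    ok <- p$pairs$posterior >= posterior_min
    idx <- match(p$pairs$accession[ok], accessions)
    cell[idx] <- canonical_genotype(paste(p$pairs$hap1[ok], p$pairs$hap2[ok],
                                          sep = "/"))
    cell
  })
  geno <- do.call(cbind, cols)
  colnames(geno) <- vapply(phased, `[[`, character(1), "segment_id")
  rownames(geno) <- accessions
  genotype_matrix(geno)
}

# ---- segment-level identity -------------------------------------------

#' Match accessions on their segment haplotype profiles
#'
#' Each segment is one multi-allelic locus whose genotype is the unordered
#' haplotype pair; matching then delegates to [match_genotypes()].
#'
#' @param x a haplotype table (`genotype_matrix`)
#' @inheritParams match_genotypes
#' @return a `match_report`
#' @export
segment_match <- function(x, max_mismatch = 0, min_shared_loci = 6) {
  match_genotypes(x, max_mismatch = max_mismatch,
                  min_shared_loci = min_shared_loci)
}

#' Identity statistics of a segment barcode set
#'
#' Segments in significant LD are merged into super loci first (their
#' joint haplotype frequencies estimated by EM); PI and PIsibs are then
#' computed per effective locus from haplotype frequencies and multiplied.
#'
#' @param x a haplotype table (`genotype_matrix`)
#' @param r2_threshold,alpha,n_perm,seed,posterior_min see
#'   [build_super_loci()]
#' @return list: `per_locus` ([cumulative_pi()] table), `pi_total`,
#'   `pi_sibs_total`, `n_effective`, `super_loci`
#' @export
segment_pi_stats <- function(x, r2_threshold = 0.1, alpha = 0.05,
                             n_perm = 1000, seed = NULL,
                             posterior_min = 0.95) {
  sl <- build_super_loci(x, r2_threshold = r2_threshold, alpha = alpha,
                         n_perm = n_perm, seed = seed,
                         posterior_min = posterior_min)
  freqs <- effective_freq_list(sl$matrix, sl$super_loci)
  tab <- cumulative_pi(freqs)
  list(per_locus = tab,
       pi_total = tab$cum_pi[nrow(tab)],
       pi_sibs_total = tab$cum_pi_sibs[nrow(tab)],
       n_effective = sl$n_effective,
       super_loci = sl$super_loci)
}
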