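#' @title Multilocus genotype matching and identity statistics
#'
#' @description
#' Duplicate / synonym detection by multilocus genotype matching with
#' pairwise-complete handling of missing data, the minimum-difference
#' distribution between distinct genotypes, genotype-accumulation curves,
#' and the forensic identity statistics PI (two random individuals),
#' PIsibs (two full siblings) and PIpar-off (a parent-offspring pair),
#' both population-level and genotype-specific, with the discrimination
#' capacity derived from the cumulative PI.
#' @name identity
NULL

# pairwise mismatch / shared-loci counts between two genotype rows
row_mismatch <- function(a, b) {
  shared <- !is.na(a) & !is.na(b)
  c(mismatch = sum(a[shared] != b[shared]), shared = sum(shared))
}

#' Match multilocus genotypes and cluster identical accessions
#'
#' Two accessions carry the same multilocus genotype when they disagree at
#' no more than `max_mismatch` loci among their co-typed loci, provided
#' they are co-typed at `min_shared_loci` or more loci. Clusters are the
#' transitive closure of this relation; `n_distinct` counts clusters.
#' Accessions typed at fewer than `min_shared_loci` loci overall are
#' reported as unplaceable and excluded from `n_distinct`.
#'
#' @param x a `genotype_matrix`
#' @param max_mismatch mismatches tolerated while still calling a match
#'   (default 0)
#' @param min_shared_loci minimum co-typed loci for a comparison to count
#'   (default 6)
#' @return object of class `match_report`: `clusters` (list of accession
#'   id vectors), `n_distinct`, `unplaceable`, plus the pairwise
#'   `mismatch` and `shared` matrices
#' @export
match_genotypes <- function(x, max_mismatch = 0, min_shared_loci = 6) {
  n <- nrow(x$geno)
  ids <- x$accessions$id
  typed <- rowSums(!is.na(x$geno))
  placeable <- ids[typed >= min_shared_loci]
  unplaceable <- ids[typed < min_shared_loci]

  mm <- matrix(0L, n, n, dimnames = list(ids, ids))
  sh <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      a <- x$geno[i, ]
      for (j in (i + 1):n) {
        ms <- row_mismatch(a, x$geno[j, ])
        mm[i, j] <- mm[j, i] <- ms[["mismatch"]]
        sh[i, j] <- sh[j, i] <- ms[["shared"]]
      }
    }
  }
  edges <- list()
  if (length(placeable) > 1) {
    pc <- utils::combn(placeable, 2)
    for (k in seq_len(ncol(pc))) {
      i <- pc[1, k]; j <- pc[2, k]
      if (sh[i, j] >= min_shared_loci && mm[i, j] <= max_mismatch) {
        edges[[length(edges) + 1]] <- c(i, j)
      }
    }
  }
  comps <- union_find(sort(placeable), edges)
  # keep input order inside clusters, order clusters by first member
  comps <- lapply(comps, function(m) m[order(match(m, ids))])
  comps <- comps[order(vapply(comps, function(m) match(m[1], ids), numeric(1)))]
  structure(list(clusters = unname(comps), n_distinct = length(comps),
                 unplaceable = unplaceable, mismatch = mm, shared = sh,
                 max_mismatch = max_mismatch,
                 min_shared_loci = min_shared_loci),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<match_report> %d accessions -> %d distinct genotypes\n",
              sum(sizes) + length(x$unplaceable), x$n_distinct))
  multi <- x$clusters[sizes > 1]
  if (length(multi)) {
    cat("shared genotypes:\n")
    for (cl in multi) cat("  {", paste(cl, collapse = ", "), "}\n")
  }
  if (length(x$unplaceable)) {
    cat("unplaceable (too few typed loci):",
        paste(x$unplaceable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Minimum-difference distribution between distinct genotypes
#'
#' For each distinct genotype (one representative per cluster), the
#' minimum over all other distinct genotypes of the number of differing
#' co-typed loci. The summary mirrors the headline "every two genotypes
#' differ by at least k markers" claim of fingerprinting panels.
#'
#' @param report a `match_report`
#' @return list with `min_diff` (named vector per distinct genotype),
#'   `histogram` (table), `mean`, `min`; empty when fewer than two
#'   distinct genotypes exist
#' @export
min_diff_distribution <- function(report) {
  reps <- vapply(report$clusters, `[`, character(1), 1)
  if (length(reps) < 2) {
    return(list(min_diff = stats::setNames(numeric(0), character(0)),
                histogram = table(numeric(0)), mean = NA_real_,
                min = NA_real_))
  }
  md <- vapply(seq_along(reps), function(i) {
    min(report$mismatch[reps[i], reps[-i]])
  }, numeric(1))
  names(md) <- reps
  list(min_diff = md, histogram = table(md), mean = mean(md), min = min(md))
}

#' Genotype-accumulation curve
#'
#' Loci are ranked by PIC (descending; ties broken by locus id) and added
#' one by one; the k-th curve value is the number of distinct multilocus
#' genotypes resolved by the first k loci. The curve is non-decreasing.
#'
#' @param x a `genotype_matrix`
#' @param stats optional [locus_stats()] table (computed if missing)
#' @param min_shared_loci passed to [match_genotypes()]; the effective
#'   threshold at step k is `min(k, min_shared_loci)` so that small panels
#'   remain comparable (default 1)
#' @return data.frame with columns k, locus_id, n_distinct
#' @export
accumulation_curve <- function(x, stats = NULL, min_shared_loci = 1) {
  if (is.null(stats)) stats <- locus_stats(x, hwe = FALSE)
  ord <- order(-stats$pic, stats$locus_id)
  ids <- stats$locus_id[ord]
  nd <- vapply(seq_along(ids), function(k) {
    match_genotypes(subset_matrix(x, loci = ids[seq_len(k)]),
                    min_shared_loci = min(k, min_shared_loci))$n_distinct
  }, numeric(1))
  data.frame(k = seq_along(ids), locus_id = ids, n_distinct = nd)
}

# ---- probability-of-identity statistics --------------------------------

#' Probability of identity between two random individuals
#'
#' PI = 2 (sum p_i^2)^2 - sum p_i^4: the probability that two individuals
#' drawn at random from a Hardy-Weinberg population share the same
#' genotype at this locus.
#'
#' @param p allele frequency vector
#' @return PI in (0, 1]
#' @export
pi_random <- function(p) {
  check_freqs(p)
  2 * sum(p^2)^2 - sum(p^4)
}

#' Probability of identity between two full siblings
#'
#' PIsibs = 0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4,
#' the sibling match probability of Waits-style forensic analysis; the
#' conservative bound used when relatives may be present in the sample.
#'
#' @param p allele frequency vector
#' @return PIsibs in (0, 1]
#' @export
pi_sibs <- function(p) {
  check_freqs(p)
  s2 <- sum(p^2)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * sum(p^4)
}

#' Probability of identity between a parent and an offspring
#'
#' Population level this equals sum p_i^2 (the probability that the allele
#' transmitted by the other parent matches by chance). Always between PI
#' and PIsibs.
#'
#' @param p allele frequency vector
#' @return PIpar-off in (0, 1]
#' @export
pi_par_off <- function(p) {
  check_freqs(p)
  sum(p^2)
}

#' Genotype-specific identity probabilities
#'
#' For a given genotype g: PI_g is its Hardy-Weinberg frequency; PIsibs_g
#' is (1+p_i)^2/4 for a homozygote A_iA_i and (1+p_i+p_j+2 p_i p_j)/4 for
#' a heterozygote A_iA_j; PIpar-off_g is p_i for a homozygote and
#' (p_i+p_j)/2 for a heterozygote.
#'
#' @param genotype "X/Y" string or length-2 allele vector
#' @param p allele frequency vector (named)
#' @return named vector c(pi, pi_sibs, pi_par_off)
#' @export
genotype_pi <- function(genotype, p) {
  check_freqs(p)
  al <- if (length(genotype) == 1) genotype_alleles(canonical_genotype(genotype))
        else genotype
  if (!all(al %in% names(p))) stop_validation("genotype allele not in freqs")
  pi_ <- p[al]
  if (any(pi_ == 0)) stop_validation("genotype carries an allele with p = 0")
  if (al[1] == al[2]) {
    c(pi = unname(pi_[1]^2),
      pi_sibs = unname((1 + pi_[1])^2 / 4),
      pi_par_off = unname(pi_[1]))
  } else {
    c(pi = unname(2 * pi_[1] * pi_[2]),
      pi_sibs = unname((1 + pi_[1] + pi_[2] + 2 * pi_[1] * pi_[2]) / 4),
      pi_par_off = unname((pi_[1] + pi_[2]) / 2))
  }
}

#' Allele frequencies for every effective locus
#'
#' Singleton loci use sample allele frequencies; super loci use the EM
#' haplotype frequencies of their fit, so the product rule operates on
#' (approximately) independent markers.
#'
#' @param x a `genotype_matrix` (typically the recoded matrix from
#'   [build_super_loci()])
#' @param super_loci the `super_loci` element of [build_super_loci()]'s
#'   result (optional; matched by locus id)
#' @return named list of frequency vectors
#' @export
effective_freq_list <- function(x, super_loci = NULL) {
  out <- lapply(seq_len(ncol(x$geno)), function(j) {
    id <- x$loci$locus_id[j]
    if (!is.null(super_loci) && id %in% names(super_loci)) {
      sl <- super_loci[[id]]
      stats::setNames(sl$freqs, sl$labels)
    } else {
      allele_frequencies(x, j)
    }
  })
  stats::setNames(out, x$loci$locus_id)
}

#' Cumulative identity probabilities across effective loci
#'
#' Per-locus PI, PIsibs and PIpar-off with their cumulative products and
#' -log10 trajectories, assuming (enforced by super-locus recoding)
#' independence between effective loci.
#'
#' @param freq_list named list of allele frequency vectors, one per
#'   effective locus (see [effective_freq_list()])
#' @return data.frame with per-locus and cumulative columns; the last row
#'   holds the panel totals
#' @export
cumulative_pi <- function(freq_list) {
  pi_ <- vapply(freq_list, pi_random, numeric(1))
  ps <- vapply(freq_list, pi_sibs, numeric(1))
  pp <- vapply(freq_list, pi_par_off, numeric(1))
  data.frame(locus_id = names(freq_list),
             pi = pi_, pi_sibs = ps, pi_par_off = pp,
             cum_pi = cumprod(pi_), cum_pi_sibs = cumprod(ps),
             cum_pi_par_off = cumprod(pp),
             neglog10_pi = -log10(cumprod(pi_)),
             neglog10_pi_sibs = -log10(cumprod(ps)),
             row.names = NULL)
}

#' Discrimination capacity of a marker panel
#'
#' How many cultivars can be catalogued before false identities become
#' likely. In `pairwise` mode (default) the capacity is the largest n such
#' that no two of the n(n-1)/2 genotype pairs collide with probability at
#' least `confidence`: (1 - PI)^(n(n-1)/2) >= confidence. In `query` mode
#' it is the largest n with n * PI <= 1 - confidence (a single query
#' against a database of n genotypes).
#'
#' @param pi_total cumulative PI of the panel, in (0, 1)
#' @param confidence required probability of no false identity
#'   (default 0.95)
#' @param mode "pairwise" or "query"
#' @return integer capacity; attributes `mode` and `confidence` record the
#'   provenance of the number
#' @export
discrimination_capacity <- function(pi_total, confidence = 0.95,
                                    mode = c("pairwise", "query")) {
  mode <- match.arg(mode)
  if (pi_total <= 0 || pi_total >= 1) {
    stop_validation("pi_total must be in (0, 1)")
  }
  if (mode == "query") {
    if (pi_total >= 1 - confidence) {
      warning("PI too large for the requested confidence; capacity 0")
      n <- 0L
    } else {
      n <- floor((1 - confidence) / pi_total)
    }
  } else {
    m <- log(confidence) / log1p(-pi_total) # max number of pairs
    n <- floor((1 + sqrt(1 + 8 * m)) / 2)
    ok <- function(k) k * (k - 1) / 2 * log1p(-pi_total) >= log(confidence)
    while (n > 1 && !ok(n)) n <- n - 1
    while (ok(n + 1)) n <- n + 1
  }
  structure(as.integer(n), mode = mode, confidence = confidence)
}
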