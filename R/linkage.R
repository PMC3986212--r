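#' @title Haplotype-frequency EM, LD and super loci
#'
#' @description
#' Maximum-likelihood haplotype frequencies for sets of loci from unphased
#' diploid genotypes via EM, pairwise linkage disequilibrium (D and r2)
#' with permutation significance, and the construction of "super loci":
#' connected components of the significant-LD graph recoded as single
#' multi-allelic markers whose alleles are the EM haplotypes. Treating
#' linked markers this way keeps the product rule of the identity
#' statistics valid.
#' @name linkage
NULL

# ---- EM engine ---------------------------------------------------------

# Enumerate the unordered haplotype pairs compatible with one multilocus
# genotype (list of length-2 allele vectors). A genotype heterozygous at h
# loci has 2^(h-1) resolutions; the first heterozygous locus is pinned to
# break the hap1/hap2 symmetry.
compatible_pairs <- function(pairs) {
  k <- length(pairs)
  het <- which(vapply(pairs, function(a) a[1] != a[2], logical(1)))
  base1 <- vapply(pairs, `[`, character(1), 1)
  base2 <- vapply(pairs, `[`, character(1), 2)
  if (length(het) <= 1) {
    return(list(rbind(paste(base1, collapse = "|"),
                      paste(base2, collapse = "|"))))
  }
  free <- het[-1]
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(free)))
  lapply(seq_len(nrow(grid)), function(r) {
    h1 <- base1; h2 <- base2
    swap <- free[unlist(grid[r, ])]
    tmp <- h1[swap]; h1[swap] <- h2[swap]; h2[swap] <- tmp
    rbind(paste(h1, collapse = "|"), paste(h2, collapse = "|"))
  })
}

em_core <- function(pattern_pairs, pattern_counts, universe, init,
                    max_iter, tol) {
  f <- init
  n_copies <- 2 * sum(pattern_counts)
  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    newf <- stats::setNames(numeric(length(universe)), universe)
    ll <- 0
    for (g in seq_along(pattern_pairs)) {
      prs <- pattern_pairs[[g]]
      w <- vapply(prs, function(pq) {
        v <- f[pq[1]] * f[pq[2]]
        if (pq[1] != pq[2]) 2 * v else v
      }, numeric(1))
      tot <- sum(w)
      if (tot <= 0) { # degenerate; spread mass uniformly over resolutions
        w <- rep(1 / length(w), length(w)); tot <- 1e-300
      } else w <- w / tot
      ll <- ll + pattern_counts[g] * log(tot)
      for (i in seq_along(prs)) {
        pq <- prs[[i]]
        newf[pq[1]] <- newf[pq[1]] + pattern_counts[g] * w[i]
        newf[pq[2]] <- newf[pq[2]] + pattern_counts[g] * w[i]
      }
    }
    newf <- newf / n_copies
    if (ll < loglik - 1e-8) {
      stop("EM log-likelihood decreased; this is a bug")
    }
    delta <- max(abs(newf - f))
    f <- newf
    loglik <- ll
    if (delta < tol) {
      return(list(freqs = f, loglik = loglik, n_iter = it, converged = TRUE))
    }
  }
  list(freqs = f, loglik = loglik, n_iter = max_iter, converged = FALSE)
}

#' EM haplotype-frequency estimation over a set of loci
#'
#' Maximizes the multinomial likelihood of the unphased multilocus
#' genotypes under random union of gametes, over the haplotype space
#' compatible with at least one fully typed accession. Initialization is
#' a deterministic uniform distribution; convergence is declared when the
#' largest frequency change drops below `tol` (default 1e-8) or after
#' `max_iter` iterations. The log-likelihood is checked to be
#' non-decreasing at every iteration. For two loci, two phase-biased
#' restarts are also run so the symmetric double-heterozygote saddle point
#' cannot trap the estimate; exact likelihood ties between mirror
#' solutions are resolved toward the higher coupling-gamete frequency and
#' flagged in the `tie` field.
#'
#' @param x a `genotype_matrix`
#' @param loci 2..k locus ids (k <= 10 recommended); accessions not fully
#'   typed at these loci are excluded from the fit
#' @param max_iter,tol EM control
#' @return object of class `hap_freqs`: fields `member_loci`, `haplotypes`
#'   (allele tuples as "a|b|..." strings), `freqs`, `loglik`, `n_iter`,
#'   `converged`, `tie`, `n_used`, and `assignments` (data.frame with the
#'   most probable haplotype pair and its posterior per used accession)
#' @export
em_haplotype_frequencies <- function(x, loci = x$loci$locus_id,
                                     max_iter = 1000, tol = 1e-8) {
  li <- if (is.character(loci)) match(loci, x$loci$locus_id) else loci
  if (anyNA(li)) stop_validation("unknown locus id")
  sub <- x$geno[, li, drop = FALSE]
  full <- which(rowSums(is.na(sub)) == 0)
  if (length(full) == 0) {
    stop_undefined("no accession fully typed at the member loci")
  }
  allele_rows <- lapply(full, function(i) {
    lapply(sub[i, ], genotype_alleles)
  })
  keys <- vapply(full, function(i) paste(sub[i, ], collapse = " "),
                 character(1))
  uniq <- !duplicated(keys)
  pattern_counts <- as.numeric(table(keys)[keys[uniq]])
  pattern_pairs <- lapply(allele_rows[uniq], function(pr) {
    lapply(compatible_pairs(pr), function(m) c(m[1], m[2]))
  })
  universe <- sort(unique(unlist(pattern_pairs)))
  uni_init <- stats::setNames(rep(1 / length(universe), length(universe)),
                              universe)
  fits <- list(em_core(pattern_pairs, pattern_counts, universe, uni_init,
                       max_iter, tol))
  if (length(li) == 2) {
    als <- locus_allele_list(x$loci[li, , drop = FALSE])
    if (all(lengths(als) == 2)) {
      coupling <- c(paste(als[[1]][1], als[[2]][1], sep = "|"),
                    paste(als[[1]][2], als[[2]][2], sep = "|"))
      repulsion <- c(paste(als[[1]][1], als[[2]][2], sep = "|"),
                     paste(als[[1]][2], als[[2]][1], sep = "|"))
      for (bias in list(coupling, repulsion)) {
        ini <- uni_init
        hit <- universe %in% bias
        if (any(hit)) {
          ini[hit] <- ini[hit] + 0.10
          ini <- ini / sum(ini)
          fits <- c(fits, list(em_core(pattern_pairs, pattern_counts,
                                       universe, ini, max_iter, tol)))
        }
      }
    }
  }
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- which(lls > max(lls) - 1e-9)
  tie <- FALSE
  pick <- best[1]
  if (length(best) > 1) {
    # mirror-solution tie: prefer the higher coupling-gamete frequency
    same <- vapply(best[-1], function(b) {
      max(abs(fits[[b]]$freqs - fits[[pick]]$freqs)) < 1e-6
    }, logical(1))
    if (!all(same)) {
      tie <- TRUE
      coup <- vapply(best, function(b) {
        f <- fits[[b]]$freqs
        if (exists("coupling", inherits = FALSE) &&
            any(names(f) %in% coupling)) sum(f[names(f) %in% coupling]) else 0
      }, numeric(1))
      pick <- best[which.max(coup)]
    }
  }
  fit <- fits[[pick]]
  ord <- order(-fit$freqs, names(fit$freqs))
  freqs <- fit$freqs[ord]

  # most probable phase per accession at the converged frequencies
  pat_idx <- match(keys, keys[uniq])
  assigns <- do.call(rbind, lapply(seq_along(full), function(ii) {
    prs <- pattern_pairs[[pat_idx[ii]]]
    w <- vapply(prs, function(m) {
      v <- freqs[m[1]] * freqs[m[2]]
      if (m[1] != m[2]) 2 * v else v
    }, numeric(1))
    w <- w / sum(w)
    b <- which.max(w)
    data.frame(accession = x$accessions$id[full[ii]],
               hap1 = prs[[b]][1], hap2 = prs[[b]][2],
               posterior = w[b], stringsAsFactors = FALSE)
  }))
  structure(list(member_loci = x$loci$locus_id[li],
                 haplotypes = names(freqs),
                 freqs = unname(freqs) / sum(freqs),
                 loglik = fit$loglik, n_iter = fit$n_iter,
                 converged = fit$converged, tie = tie,
                 n_used = length(full), assignments = assigns),
            class = "hap_freqs")
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat(sprintf("<hap_freqs> loci {%s}: %d haplotypes, loglik %.4f (%d iter%s)\n",
              paste(x$member_loci, collapse = ","), length(x$haplotypes),
              x$loglik, x$n_iter, if (x$converged) "" else ", NOT converged"))
  print(stats::setNames(round(x$freqs, 4), x$haplotypes))
  invisible(x)
}

# ---- LD statistics -----------------------------------------------------

#' Pairwise LD from a two-locus haplotype-frequency fit
#'
#' For bi-allelic loci: D = p_AB - p_A p_B and
#' r2 = D^2 / (p_A(1-p_A) p_B(1-p_B)), where A and B are the first listed
#' alleles of the two loci. For multi-allelic loci the generalized
#' r2 = sum_ab D_ab^2 / ((1 - sum_a p_a^2)(1 - sum_b p_b^2)) is returned
#' with D = NA.
#'
#' @param fit a two-locus `hap_freqs`
#' @return named vector c(D, r2); errors if either locus is monomorphic
#'   in the fitted sample
#' @export
ld_r2 <- function(fit) {
  if (length(fit$member_loci) != 2) stop_validation("ld_r2 needs 2 loci")
  parts <- strsplit(fit$haplotypes, "|", fixed = TRUE)
  a1 <- vapply(parts, `[`, character(1), 1)
  a2 <- vapply(parts, `[`, character(1), 2)
  p1 <- tapply(fit$freqs, a1, sum)
  p2 <- tapply(fit$freqs, a2, sum)
  if (min(length(p1), length(p2)) < 2 ||
      any(c(p1, p2) > 1 - 1e-12)) {
    stop_undefined("monomorphic member locus: LD undefined")
  }
  if (length(p1) == 2 && length(p2) == 2) {
    A <- sort_alleles(names(p1))[1]
    B <- sort_alleles(names(p2))[1]
    pAB <- sum(fit$freqs[a1 == A & a2 == B])
    D <- pAB - p1[[A]] * p2[[B]]
    r2 <- D^2 / (p1[[A]] * (1 - p1[[A]]) * p2[[B]] * (1 - p2[[B]]))
    return(c(D = D, r2 = r2))
  }
  num <- 0
  for (u in names(p1)) for (v in names(p2)) {
    puv <- sum(fit$freqs[a1 == u & a2 == v])
    num <- num + (puv - p1[[u]] * p2[[v]])^2
  }
  r2 <- num / ((1 - sum(p1^2)) * (1 - sum(p2^2)))
  c(D = NA_real_, r2 = r2)
}

# allele1 dosage vector for one locus column (NA where missing); NULL when
# the locus is not bi-allelic
locus_dose <- function(x, j) {
  al <- locus_allele_list(x$loci[j, , drop = FALSE])[[1]]
  if (length(al) != 2) return(NULL)
  cells <- x$geno[, j]
  dose <- rep(NA_real_, length(cells))
  ok <- !is.na(cells)
  dose[ok] <- vapply(strsplit(cells[ok], "/", fixed = TRUE),
                     function(a) sum(a == al[1]), numeric(1))
  dose
}

# Fast EM + r2 for two bi-allelic dosage vectors. Only the double
# heterozygotes have ambiguous phase, so EM iterates a single coupling
# proportion over the 3x3 genotype-count table.
dose_r2 <- function(d1, d2, max_iter = 1000, tol = 1e-8) {
  ok <- !is.na(d1) & !is.na(d2)
  d1 <- d1[ok]; d2 <- d2[ok]
  if (length(d1) < 2) return(NA_real_)
  p1 <- mean(d1) / 2; p2 <- mean(d2) / 2
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)
  n <- table(factor(d1, levels = 2:0), factor(d2, levels = 2:0))
  ndd <- n["1", "1"]
  # phase-known gamete counts (AB, Ab, aB, ab), A = allele1 of locus 1
  base <- c(2 * n["2", "2"] + n["2", "1"] + n["1", "2"],
            2 * n["2", "0"] + n["2", "1"] + n["1", "0"],
            2 * n["0", "2"] + n["0", "1"] + n["1", "2"],
            2 * n["0", "0"] + n["0", "1"] + n["1", "0"])
  tot <- 2 * length(d1)
  f <- rep(0.25, 4)
  for (it in seq_len(max_iter)) {
    coup <- f[1] * f[4]
    rep_ <- f[2] * f[3]
    pi_c <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    newf <- (base + ndd * c(pi_c, 1 - pi_c, 1 - pi_c, pi_c)) / tot
    if (max(abs(newf - f)) < tol) { f <- newf; break }
    f <- newf
  }
  D <- f[1] - (f[1] + f[2]) * (f[1] + f[3])
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# allele-index representation of one locus column: n x 2 integer matrix
# (rows NA where missing), attribute k = allele count
locus_idx <- function(x, j) {
  al <- locus_allele_list(x$loci[j, , drop = FALSE])[[1]]
  cells <- x$geno[, j]
  out <- matrix(NA_integer_, length(cells), 2)
  ok <- !is.na(cells)
  parts <- strsplit(cells[ok], "/", fixed = TRUE)
  out[ok, 1] <- match(vapply(parts, `[`, character(1), 1), al)
  out[ok, 2] <- match(vapply(parts, `[`, character(1), 2), al)
  attr(out, "k") <- length(al)
  out
}

# Vectorized two-locus EM for arbitrary allele counts. For two loci each
# individual has at most two compatible unordered haplotype pairs, so the
# E-step is a single vectorized responsibility update.
idx_r2 <- function(A1, A2, max_iter = 1000, tol = 1e-8) {
  k1 <- attr(A1, "k"); k2 <- attr(A2, "k")
  ok <- !is.na(A1[, 1]) & !is.na(A2[, 1])
  A1 <- A1[ok, , drop = FALSE]; A2 <- A2[ok, , drop = FALSE]
  n <- nrow(A1)
  if (n < 2) return(NA_real_)
  flat <- function(a, c) (a - 1L) * k2 + c
  i11 <- flat(A1[, 1], A2[, 1]); i12 <- flat(A1[, 2], A2[, 2])
  i21 <- flat(A1[, 1], A2[, 2]); i22 <- flat(A1[, 2], A2[, 1])
  K <- k1 * k2
  f <- rep(1 / K, K)
  m1 <- ifelse(i11 == i12, 1, 2)
  m2 <- ifelse(i21 == i22, 1, 2)
  for (it in seq_len(max_iter)) {
    w1 <- f[i11] * f[i12] * m1
    w2 <- f[i21] * f[i22] * m2
    tot <- w1 + w2
    r <- ifelse(tot > 0, w1 / tot, 0.5)
    rs <- rowsum(c(r, r, 1 - r, 1 - r), c(i11, i12, i21, i22))
    newf <- numeric(K)
    newf[as.integer(rownames(rs))] <- rs / (2 * n)
    if (max(abs(newf - f)) < tol) { f <- newf; break }
    f <- newf
  }
  M <- matrix(f, k1, k2, byrow = TRUE)
  p1 <- rowSums(M); p2 <- colSums(M)
  if (max(p1) > 1 - 1e-12 || max(p2) > 1 - 1e-12) return(NA_real_)
  D <- M - outer(p1, p2)
  sum(D^2) / ((1 - sum(p1^2)) * (1 - sum(p2^2)))
}

pair_r2 <- function(x, pair, max_iter = 200, tol = 1e-6) {
  li <- if (is.character(pair)) match(pair, x$loci$locus_id) else pair
  d1 <- locus_dose(x, li[1])
  d2 <- locus_dose(x, li[2])
  r2 <- if (!is.null(d1) && !is.null(d2)) {
    dose_r2(d1, d2)
  } else {
    idx_r2(locus_idx(x, li[1]), locus_idx(x, li[2]))
  }
  if (is.na(r2)) stop_undefined("monomorphic member locus: LD undefined")
  r2
}

#' Permutation test of LD significance
#'
#' The observed statistic is r2 from an EM haplotype-frequency fit of the
#' two loci. Under the null, one locus's genotype column is permuted
#' across accessions and the statistic recomputed; the p-value is
#' (1 + #{permuted r2 >= observed}) / (n_perm + 1). Deterministic given
#' `seed`.
#'
#' @param x a `genotype_matrix`
#' @param pair two locus ids
#' @param n_perm number of permutations (default 1000)
#' @param seed RNG seed (the caller's RNG state is restored)
#' @return p-value with attribute `r2` (observed statistic)
#' @export
ld_significance <- function(x, pair, n_perm = 1000, seed = NULL) {
  li <- match(pair, x$loci$locus_id)
  if (anyNA(li)) stop_validation("unknown locus id")
  shared <- sum(!is.na(x$geno[, li[1]]) & !is.na(x$geno[, li[2]]))
  if (shared < 10) {
    stop_undefined("fewer than 10 accessions typed at both loci")
  }
  obs <- pair_r2(x, li)
  n <- nrow(x$geno)
  d1 <- locus_dose(x, li[1])
  d2 <- locus_dose(x, li[2])
  fast <- !is.null(d1) && !is.null(d2)
  if (!fast) {
    A1 <- locus_idx(x, li[1])
    A2 <- locus_idx(x, li[2])
  }
  exceed <- with_seed(seed, {
    cnt <- 0
    for (b in seq_len(n_perm)) {
      r2p <- if (fast) {
        dose_r2(d1, d2[sample.int(n)])
      } else {
        perm <- A2[sample.int(n), , drop = FALSE]
        attr(perm, "k") <- attr(A2, "k")
        idx_r2(A1, perm)
      }
      if (!is.na(r2p) && r2p >= obs - 1e-12) cnt <- cnt + 1
    }
    cnt
  })
  p <- (1 + exceed) / (n_perm + 1)
  attr(p, "r2") <- obs
  p
}

#' All-pairs LD table
#'
#' @param x a `genotype_matrix`
#' @param loci locus ids (default all)
#' @param n_perm permutations per pair for the significance test; 0 skips
#'   testing (p = NA)
#' @param seed RNG seed
#' @return data.frame with columns locus1, locus2, D, r2, p; pairs with a
#'   monomorphic member are flagged with NA statistics
#' @export
ld_pairs <- function(x, loci = x$loci$locus_id, n_perm = 1000, seed = NULL) {
  li <- match(loci, x$loci$locus_id)
  if (length(li) < 2) {
    return(data.frame(locus1 = character(0), locus2 = character(0),
                      D = numeric(0), r2 = numeric(0), p = numeric(0)))
  }
  combos <- utils::combn(seq_along(li), 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    i <- li[combos[1, k]]; j <- li[combos[2, k]]
    res <- tryCatch({
      fit <- em_haplotype_frequencies(x, c(i, j))
      st <- ld_r2(fit)
      p <- if (n_perm > 0) {
        as.numeric(ld_significance(x, x$loci$locus_id[c(i, j)],
                                   n_perm = n_perm,
                                   seed = if (is.null(seed)) NULL else seed + k))
      } else NA_real_
      c(st["D"], st["r2"], p = p)
    }, snpbarcode_undefined = function(e) c(D = NA_real_, r2 = NA_real_,
                                            p = NA_real_))
    data.frame(locus1 = x$loci$locus_id[i], locus2 = x$loci$locus_id[j],
               D = res[[1]], r2 = res[[2]], p = res[[3]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- super loci --------------------------------------------------------

union_find <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(a) {
    while (parent[[a]] != a) a <- parent[[a]]
    a
  }
  for (e in edges) {
    ra <- find(e[1]); rb <- find(e[2])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  comp <- vapply(ids, find, character(1))
  split(ids, comp)
}

#' Build super loci from significant LD and recode the matrix
#'
#' Loci joined by significant LD (r2 > `r2_threshold` and p < `alpha`) are
#' grouped by connected components; components of two or more loci become
#' super loci. Each super locus is recoded as one multi-allelic marker
#' whose alleles are the EM haplotypes (labelled H1, H2, ... by
#' descending frequency); an accession's recoded genotype is its most
#' probable haplotype pair, or missing when the phase posterior falls
#' below `posterior_min` (so no haplotype is fabricated). The effective
#' locus count is the number of singleton loci plus the number of super
#' loci.
#'
#' @param x a `genotype_matrix`
#' @param r2_threshold,alpha LD significance rule (defaults 0.1, 0.05)
#' @param n_perm,seed permutation-test control (see [ld_significance()])
#' @param posterior_min phase-posterior cutoff for recoding (default 0.95)
#' @param ld optional precomputed [ld_pairs()] table (skips recomputation)
#' @return list with `super_loci` (one entry per component: id, members,
#'   haplotypes, freqs, fit), `matrix` (the recoded `genotype_matrix`),
#'   `n_effective`, and `ld` (the pair table used)
#' @export
build_super_loci <- function(x, r2_threshold = 0.1, alpha = 0.05,
                             n_perm = 1000, seed = NULL,
                             posterior_min = 0.95, ld = NULL) {
  if (is.null(ld)) ld <- ld_pairs(x, n_perm = n_perm, seed = seed)
  sig <- ld[!is.na(ld$r2) & !is.na(ld$p) &
              ld$r2 > r2_threshold & ld$p < alpha, , drop = FALSE]
  ids <- sort(x$loci$locus_id)
  comps <- union_find(ids, lapply(seq_len(nrow(sig)), function(k) {
    c(sig$locus1[k], sig$locus2[k])
  }))
  comps <- comps[order(vapply(comps, min, character(1)))]
  multi <- comps[lengths(comps) >= 2]

  super <- list()
  cols <- list()
  loci_rows <- list()
  consumed <- character(0)
  sl_index <- 0
  first_member_pos <- vapply(multi, function(m) {
    min(match(m, x$loci$locus_id))
  }, numeric(1))
  for (j in seq_len(ncol(x$geno))) {
    id <- x$loci$locus_id[j]
    if (id %in% consumed) next
    hit <- which(first_member_pos == j)
    if (length(hit)) {
      sl_index <- sl_index + 1
      members <- sort(multi[[hit]])
      consumed <- c(consumed, members)
      fit <- em_haplotype_frequencies(x, members)
      labels <- stats::setNames(sprintf("H%d", seq_along(fit$haplotypes)),
                                fit$haplotypes)
      sl_id <- sprintf("SL%d", sl_index)
      cell <- rep(NA_character_, nrow(x$geno))
      ok <- fit$assignments$posterior >= posterior_min
      rows <- match(fit$assignments$accession[ok], x$accessions$id)
      cell[rows] <- canonical_genotype(paste(labels[fit$assignments$hap1[ok]],
                                             labels[fit$assignments$hap2[ok]],
                                             sep = "/"))
      cols[[sl_id]] <- cell
      loci_rows[[sl_id]] <- locus_table(sl_id,
                                        paste(labels, collapse = ","),
                                        name = paste(members, collapse = "+"))
      super[[sl_id]] <- list(id = sl_id, members = members,
                             haplotypes = fit$haplotypes,
                             labels = unname(labels), freqs = fit$freqs,
                             fit = fit)
    } else {
      cols[[id]] <- x$geno[, j]
      loci_rows[[id]] <- x$loci[j, , drop = FALSE]
    }
  }
  geno <- do.call(cbind, cols)
  rownames(geno) <- x$accessions$id
  loci <- do.call(rbind, loci_rows)
  recoded <- genotype_matrix(geno, loci = loci, accessions = x$accessions)
  list(super_loci = super, matrix = recoded,
       n_effective = ncol(geno), ld = ld)
}
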