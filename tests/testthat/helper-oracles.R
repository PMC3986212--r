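# Independent oracles used across the suite. Each deliberately takes a
# different computational path from the package implementation it checks.

# Build a genotype matrix from a character vector per locus.
make_gm <- function(..., ids = NULL, groups = NULL) {
  cols <- list(...)
  geno <- do.call(cbind, cols)
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("L%02d", seq_len(ncol(geno)))
  }
  rownames(geno) <- ids %||% sprintf("a%02d", seq_len(nrow(geno)))
  acc <- data.frame(id = rownames(geno), stringsAsFactors = FALSE)
  if (!is.null(groups)) acc$group <- groups
  genotype_matrix(geno, accessions = acc)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Random bi-allelic genotype matrix with missing cells.
random_gm <- function(n, L, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nt <- c("A", "C", "G", "T")
  cols <- lapply(seq_len(L), function(j) {
    al <- sort(sample(nt, 2))
    p <- runif(1, 0.1, 0.9)
    dose <- rbinom(n, 2, p)
    g <- vapply(dose, function(d) {
      paste(sort(c(rep(al[1], d), rep(al[2], 2 - d))), collapse = "/")
    }, character(1))
    g[runif(n) < missing_rate] <- NA_character_
    g
  })
  do.call(make_gm, cols)
}

canonical_matrix <- function(geno) {
  out <- geno
  out[] <- canonical_genotype(geno)
  out
}

r_dirichlet_test <- function(k, alpha = 1) {
  g <- rgamma(k, alpha)
  g / sum(g)
}

# --- HWE oracles --------------------------------------------------------

# Direct-formula conditional distribution of the heterozygote count.
oracle_hwe_direct <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_aa + n_ab
  nB <- 2 * n - nA
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  lp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (nB - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) - (lfactorial(2 * n) - lfactorial(nA) - lfactorial(nB))
  }, numeric(1))
  pr <- exp(lp)
  obs <- pr[hets == n_ab]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Exhaustive enumeration of allele-to-slot arrangements (2n <= 14):
# choose which of the 2n allele slots carry allele A; every arrangement is
# equally likely given the allele counts.
oracle_hwe_enum <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_aa + n_ab
  stopifnot(2 * n <= 14)
  slots <- combn(2 * n, nA)
  hets <- apply(slots, 2, function(pos) {
    isA <- rep(FALSE, 2 * n)
    isA[pos] <- TRUE
    ind <- matrix(isA, nrow = 2)
    sum(colSums(ind) == 1)
  })
  tab <- table(hets) / ncol(slots)
  obs <- tab[as.character(n_ab)]
  sum(tab[tab <= obs * (1 + 1e-9)])
}

# --- identity-statistic oracles (enumeration over genotype space) ------

hwe_genotypes <- function(p) {
  k <- length(p)
  gl <- list(); fr <- numeric(0)
  for (i in seq_len(k)) for (j in i:k) {
    gl[[length(gl) + 1]] <- c(i, j)
    fr <- c(fr, if (i == j) p[i]^2 else 2 * p[i] * p[j])
  }
  list(genotypes = gl, freqs = fr)
}

oracle_pi_enum <- function(p) {
  g <- hwe_genotypes(p)
  sum(g$freqs^2)
}

# offspring genotype distribution given two parental genotypes
offspring_dist <- function(g1, g2, k) {
  d <- matrix(0, k, k)
  for (a in g1) for (b in g2) {
    i <- min(a, b); j <- max(a, b)
    d[i, j] <- d[i, j] + 0.25
  }
  d
}

oracle_pisibs_enum <- function(p) {
  k <- length(p)
  g <- hwe_genotypes(p)
  total <- 0
  for (u in seq_along(g$genotypes)) for (v in seq_along(g$genotypes)) {
    d <- offspring_dist(g$genotypes[[u]], g$genotypes[[v]], k)
    total <- total + g$freqs[u] * g$freqs[v] * sum(d^2)
  }
  total
}

oracle_piparoff_enum <- function(p) {
  g <- hwe_genotypes(p)
  total <- 0
  for (u in seq_along(g$genotypes)) {
    gt <- g$genotypes[[u]]
    # transmitted allele uniform over the pair; partner allele from p
    pr <- 0
    for (t in gt) {
      need <- setdiff(gt, t)
      if (length(need) == 0) pr <- pr + 0.5 * p[t]       # homozygote
      else pr <- pr + 0.5 * p[need]
    }
    total <- total + g$freqs[u] * pr
  }
  total
}

# --- two-locus EM oracle: 1-D grid search over the coupling frequency --

oracle_em_grid <- function(gm, step = 1e-5) {
  stopifnot(ncol(gm$geno) == 2)
  cells <- gm$geno[stats::complete.cases(gm$geno), , drop = FALSE]
  al1 <- sort(unique(unlist(strsplit(cells[, 1], "/"))))
  al2 <- sort(unique(unlist(strsplit(cells[, 2], "/"))))
  stopifnot(length(al1) == 2, length(al2) == 2)
  dose1 <- vapply(strsplit(cells[, 1], "/"), function(a) sum(a == al1[1]),
                  numeric(1))
  dose2 <- vapply(strsplit(cells[, 2], "/"), function(a) sum(a == al2[1]),
                  numeric(1))
  pA <- mean(dose1) / 2; pB <- mean(dose2) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  cnt <- table(factor(dose1, levels = 2:0), factor(dose2, levels = 2:0))
  ll <- vapply(grid, function(x) {
    AB <- x; Ab <- pA - x; aB <- pB - x; ab <- 1 - pA - pB + x
    if (min(AB, Ab, aB, ab) < -1e-12) return(-Inf)
    pr <- rbind(c(AB^2, 2 * AB * Ab, Ab^2),
                c(2 * AB * aB, 2 * (AB * ab + Ab * aB), 2 * Ab * ab),
                c(aB^2, 2 * aB * ab, ab^2))
    if (any(pr[cnt > 0] <= 0)) return(-Inf)
    sum(cnt[cnt > 0] * log(pr[cnt > 0]))
  }, numeric(1))
  best <- which.max(ll)
  list(pAB = grid[best], loglik = ll[best], pA = pA, pB = pB)
}

# --- brute-force matching ----------------------------------------------

brute_match_clusters <- function(gm, max_mismatch = 0, min_shared = 6) {
  n <- nrow(gm$geno)
  ids <- gm$accessions$id
  typed <- rowSums(!is.na(gm$geno))
  keep <- which(typed >= min_shared)
  adj <- diag(length(keep)) == 1
  for (x in seq_along(keep)) for (y in seq_along(keep)) {
    if (x >= y) next
    a <- gm$geno[keep[x], ]; b <- gm$geno[keep[y], ]
    sh <- !is.na(a) & !is.na(b)
    if (sum(sh) >= min_shared && sum(a[sh] != b[sh]) <= max_mismatch) {
      adj[x, y] <- adj[y, x] <- TRUE
    }
  }
  # transitive closure by repeated multiplication
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, length(keep))
  cl <- 0
  for (x in seq_along(keep)) {
    if (is.na(comp[x])) {
      cl <- cl + 1
      comp[which(adj[x, ])] <- cl
    }
  }
  split(ids[keep], comp)
}

# --- Tajima-Nei second path (pair-count based) -------------------------

oracle_tn <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]; b <- strsplit(toupper(b), "")[[1]]
  nt <- c("A", "C", "G", "T")
  keep <- a %in% nt & b %in% nt
  a <- a[keep]; b <- b[keep]
  counts <- table(factor(c(a, b), levels = nt))
  bq <- 1 - sum((counts / sum(counts))^2)
  mism <- sum(a != b)
  p <- mism / length(a)
  if (p == 0) 0 else -bq * log(1 - p / bq)
}
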