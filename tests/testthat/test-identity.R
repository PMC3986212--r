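test_that("matching clusters identical rows and respects missing data", {
  gm <- make_gm(c("A/A", "A/A", "A/G"), c("C/C", "C/C", "C/C"),
                c("T/T", "T/T", "T/T"), c("G/G", "G/G", "G/G"),
                c("A/A", "A/A", "A/A"), c("C/T", "T/C", "C/C"))
  rep_ <- match_genotypes(gm, min_shared_loci = 6)
  expect_equal(rep_$n_distinct, 2)
  expect_equal(rep_$clusters[[1]], c("a01", "a02"))
  # all rows identical -> one cluster
  same <- make_gm(rep("A/G", 5), rep("C/C", 5), rep("T/T", 5),
                  rep("A/A", 5), rep("G/G", 5), rep("C/T", 5))
  expect_equal(match_genotypes(same)$n_distinct, 1)
})

test_that("accessions typed below the shared-locus floor are unplaceable", {
  geno <- rbind(a = c("A/A", "C/C", "T/T", NA, NA, NA),
                b = c("A/A", "C/C", "T/T", "G/G", "A/A", "C/C"),
                c = c("A/A", "C/C", "T/T", "G/G", "A/A", "C/C"))
  colnames(geno) <- sprintf("L%02d", 1:6)
  rep_ <- match_genotypes(genotype_matrix(geno), min_shared_loci = 6)
  expect_identical(rep_$unplaceable, "a")
  expect_equal(rep_$n_distinct, 1)
})

test_that("matching equals brute force on random matrices with missing cells", {
  for (s in 1:8) {
    gm <- random_gm(30, 8, missing_rate = runif(1, 0.1, 0.3), seed = 300 + s)
    rep_ <- match_genotypes(gm, min_shared_loci = 4)
    ora <- brute_match_clusters(gm, max_mismatch = 0, min_shared = 4)
    expect_equal(rep_$n_distinct, length(ora))
    canon <- function(cl) {
      sort(vapply(cl, function(m) paste(sort(m), collapse = "+"),
                  character(1)))
    }
    expect_identical(unname(canon(rep_$clusters)), unname(canon(ora)))
  }
})

test_that("minimum-difference distribution follows hand enumeration", {
  # three genotypes with pairwise differences d12=2, d13=5, d23=6
  gm <- make_gm(c("A/A", "A/G", "A/A"), c("A/A", "A/A", "A/G"),
                c("C/C", "C/C", "C/T"), c("T/T", "T/T", "G/T"),
                c("G/G", "G/G", "C/G"), c("A/A", "A/G", "G/G"),
                c("C/C", "C/C", "C/C"))
  rep_ <- match_genotypes(gm, min_shared_loci = 6)
  expect_equal(rep_$n_distinct, 3)
  expect_equal(rep_$mismatch["a01", "a02"], 2L, ignore_attr = TRUE)
  expect_equal(rep_$mismatch["a01", "a03"], 5L, ignore_attr = TRUE)
  expect_equal(rep_$mismatch["a02", "a03"], 6L, ignore_attr = TRUE)
  md <- min_diff_distribution(rep_)
  expect_equal(unname(md$min_diff), c(2, 2, 5))
  expect_equal(md$min, 2)
  # two genotypes differing at 3 loci
  gm2 <- make_gm(c("A/A", "A/G"), c("C/C", "C/T"), c("T/T", "G/G"),
                 c("G/G", "G/G"), c("A/A", "A/A"), c("C/C", "C/C"))
  md2 <- min_diff_distribution(match_genotypes(gm2))
  expect_equal(unname(md2$min_diff), c(3, 3))
  expect_equal(md2$mean, 3)
  # single genotype -> empty histogram
  one <- min_diff_distribution(
    match_genotypes(subset_matrix(gm2, accessions = "a01"),
                    min_shared_loci = 6))
  expect_equal(length(one$min_diff), 0)
})

test_that("accumulation curve is monotone and consistent with full matching", {
  gm <- random_gm(100, 12, missing_rate = 0, seed = 12)
  st <- locus_stats(gm, hwe = FALSE)
  curve <- accumulation_curve(gm, st)
  expect_true(all(diff(curve$n_distinct) >= 0))
  expect_equal(curve$n_distinct[nrow(curve)],
               match_genotypes(gm, min_shared_loci = 1)$n_distinct)
  # PIC ordering with ties broken by locus id
  expect_identical(curve$locus_id,
                   st$locus_id[order(-st$pic, st$locus_id)])
  # monomorphic loci only -> constant curve at 1
  mono <- make_gm(rep("A/A", 4), rep("C/C", 4))
  expect_equal(accumulation_curve(mono)$n_distinct, c(1, 1))
})

test_that("PI formulas equal the genotype-enumeration oracles to 1e-12", {
  expect_equal(pi_random(1), 1)
  expect_equal(pi_random(c(0.5, 0.5)), 0.375)
  expect_equal(pi_sibs(1), 1)
  expect_equal(pi_sibs(c(0.5, 0.5)), 0.59375)
  grid <- seq(0.05, 0.95, by = 0.05)
  for (p1 in grid) { # all bi-allelic vectors on a 0.05 grid
    p <- c(p1, 1 - p1)
    expect_equal(pi_random(p), oracle_pi_enum(p), tolerance = 1e-12)
    expect_equal(pi_sibs(p), oracle_pisibs_enum(p), tolerance = 1e-12)
    expect_equal(pi_par_off(p), oracle_piparoff_enum(p), tolerance = 1e-12)
  }
  set.seed(66)
  for (i in 1:50) { # random vectors with up to 4 alleles
    p <- r_dirichlet_test(sample(2:4, 1))
    expect_equal(pi_random(p), oracle_pi_enum(p), tolerance = 1e-12)
    expect_equal(pi_sibs(p), oracle_pisibs_enum(p), tolerance = 1e-12)
    expect_equal(pi_par_off(p), oracle_piparoff_enum(p), tolerance = 1e-12)
  }
})

test_that("PI <= PIpar-off <= PIsibs for random frequency vectors", {
  set.seed(13)
  for (i in 1:1000) {
    p <- r_dirichlet_test(sample(2:6, 1))
    a <- pi_random(p); b <- pi_par_off(p); c_ <- pi_sibs(p)
    expect_lte(a, b + 1e-12)
    expect_lte(b, c_ + 1e-12)
    expect_gt(a, 0); expect_lte(c_, 1)
  }
})

test_that("genotype-specific identity probabilities follow the forensic forms", {
  p <- c(A = 0.5, B = 0.5)
  het <- genotype_pi("A/B", p)
  expect_equal(unname(het["pi_par_off"]), 0.5)
  expect_equal(unname(het["pi"]), 0.5)
  p1 <- c(A = 1)
  expect_equal(unname(genotype_pi("A/A", p1)), c(1, 1, 1))
  expect_error(genotype_pi("A/C", c(A = 0.5, B = 0.5)),
               class = "snpbarcode_validation")
  # population PIpar-off equals the HWE-weighted genotype-specific values
  set.seed(21)
  for (i in 1:20) {
    p <- r_dirichlet_test(3)
    names(p) <- c("A", "B", "C")
    gl <- hwe_genotypes(p)
    agg <- sum(vapply(seq_along(gl$genotypes), function(u) {
      g <- names(p)[gl$genotypes[[u]]]
      gl$freqs[u] * genotype_pi(paste(g, collapse = "/"), p)["pi_par_off"]
    }, numeric(1)))
    expect_equal(agg, pi_par_off(p), tolerance = 1e-12)
    expect_equal(pi_par_off(p), sum(p^2), tolerance = 1e-12)
  }
})

test_that("cumulative PI multiplies independent effective loci", {
  fl <- list(L1 = c(0.5, 0.5), L2 = c(0.5, 0.5))
  tab <- cumulative_pi(fl)
  expect_equal(tab$cum_pi[2], 0.140625)
  expect_equal(tab$neglog10_pi[2], -log10(0.140625))
  # brute-force product over a 21-locus synthetic panel
  set.seed(44)
  fl2 <- lapply(1:21, function(i) r_dirichlet_test(sample(2:4, 1)))
  names(fl2) <- sprintf("E%02d", 1:21)
  tab2 <- cumulative_pi(fl2)
  expect_equal(tab2$cum_pi[21], prod(vapply(fl2, pi_random, numeric(1))),
               tolerance = 1e-12)
})

test_that("discrimination capacity solves both criteria", {
  expect_equal(as.integer(discrimination_capacity(0.05, mode = "query")), 1)
  cap <- discrimination_capacity(5.28e-8, mode = "pairwise")
  expect_identical(attr(cap, "mode"), "pairwise")
  # verify the defining inequality at n and n+1
  n <- as.integer(cap)
  expect_gte((n * (n - 1) / 2) * log1p(-5.28e-8), log(0.95))
  expect_lt(((n + 1) * n / 2) * log1p(-5.28e-8), log(0.95))
  expect_equal(n, 1394L)
  # monotone in PI
  set.seed(3)
  pis <- sort(runif(20, 1e-9, 0.5))
  caps <- vapply(pis, function(x) {
    as.integer(discrimination_capacity(x))
  }, integer(1))
  expect_true(all(diff(caps) <= 0))
  expect_warning(z <- discrimination_capacity(0.2, mode = "query"),
                 "capacity 0")
  expect_equal(as.integer(z), 0L)
})

test_that("planted clone groups are recovered exactly without error or missingness", {
  sim <- simulate_genotypes(
    population_model(seed = 555),
    collection_design(clone_group_sizes = c(3, 2, 2, 1, 1),
                      n_unknown = 5, n_seedlings = 8, missing_rate = 0,
                      genotyping_error_rate = 0))
  rep_ <- match_genotypes(sim$matrix, min_shared_loci = 6)
  planted <- sim$truth$clone_partition
  for (grp in planted[lengths(planted) > 1]) {
    hit <- Filter(function(cl) any(grp %in% cl), rep_$clusters)
    expect_equal(length(hit), 1)
    expect_true(all(grp %in% hit[[1]]))
  }
})
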