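#' @title Pipeline orchestration and report bundles
#'
#' @description
#' A single entry point that chains the analysis stages - per-locus
#' statistics, LD and super loci, identity analysis (matching,
#' minimum-difference histogram, accumulation curve, cumulative PI and
#' discrimination capacity), optional segment barcoding - and writes a
#' reproducible report bundle (TSV/JSON files plus a run log recording
#' the thresholds actually applied). Rerunning with the same
#' configuration and seed regenerates the bundle byte for byte.
#' @name cli_reporting
NULL

#' Assemble a pipeline configuration
#'
#' @param genotype_csv path to a genotype CSV ([read_genotype_csv()]), or
#'   NULL when only a haplotype table is analysed
#' @param haplotype_csv optional path to a haplotype-pair table
#'   ([read_haplotype_table()])
#' @param out_dir output directory for the report bundle
#' @param seed RNG seed used by all stochastic stages
#' @param maf_min,r2_threshold,alpha,confidence,min_shared_loci,posterior_min
#'   analysis thresholds (defaults 0.10, 0.10, 0.05, 0.95, 6, 0.95)
#' @param n_perm permutations for LD significance (default 1000)
#' @return list of class `run_config`
#' @export
run_config <- function(genotype_csv = NULL, haplotype_csv = NULL,
                       out_dir = tempfile("snpbarcode_run"), seed = 1,
                       maf_min = 0.10, r2_threshold = 0.10, alpha = 0.05,
                       confidence = 0.95, min_shared_loci = 6,
                       posterior_min = 0.95, n_perm = 1000) {
  stopifnot(maf_min >= 0, maf_min < 0.5, r2_threshold >= 0,
            r2_threshold <= 1, alpha > 0, alpha < 1, confidence > 0,
            confidence < 1, min_shared_loci >= 1, posterior_min >= 0,
            posterior_min <= 1, n_perm >= 0)
  structure(list(genotype_csv = genotype_csv, haplotype_csv = haplotype_csv,
                 out_dir = out_dir, seed = seed, maf_min = maf_min,
                 r2_threshold = r2_threshold, alpha = alpha,
                 confidence = confidence,
                 min_shared_loci = min_shared_loci,
                 posterior_min = posterior_min, n_perm = n_perm),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full identification pipeline
#'
#' Stages, in order: per-locus statistics (with raw and
#' Bonferroni-adjusted HWE p-values); LD scan and super-locus recoding;
#' identity analysis on the effective loci (duplicate matching,
#' minimum-difference distribution, genotype-accumulation curve,
#' cumulative PI / PIsibs / PIpar-off with their -log10 trajectories,
#' discrimination capacity in both modes, and the barcode fingerprint
#' database); optionally the same matching machinery on a segment
#' haplotype table. Any stage failure aborts with a stage-named error;
#' files written before the failure are retained.
#'
#' @param config a [run_config()]
#' @param matrix,haplotypes optionally pass the data objects directly
#'   instead of reading them from the configured paths
#' @return (invisibly) a list with all stage results
#' @export
run_full_pipeline <- function(config, matrix = NULL, haplotypes = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(config = config)
  log_lines <- c("snpbarcode run log",
                 sprintf("package_version: %s",
                         as.character(utils::packageVersion("snpbarcode"))),
                 sprintf("seed: %s", config$seed),
                 sprintf("config_hash: %s", {
                   # hash the analysis-relevant settings only (not out_dir)
                   h <- config[setdiff(names(config), "out_dir")]
                   fnv1a(paste(deparse(h[order(names(h))]), collapse = ""))
                 }),
                 sprintf("thresholds: maf_min=%g r2_threshold=%g alpha=%g confidence=%g min_shared_loci=%d posterior_min=%g n_perm=%d",
                         config$maf_min, config$r2_threshold, config$alpha,
                         config$confidence, config$min_shared_loci,
                         config$posterior_min, config$n_perm))

  gm <- matrix
  if (is.null(gm) && !is.null(config$genotype_csv)) {
    gm <- stage("read", read_genotype_csv(config$genotype_csv))
  }
  ht <- haplotypes
  if (is.null(ht) && !is.null(config$haplotype_csv)) {
    ht <- stage("read", read_haplotype_table(config$haplotype_csv))
  }
  if (is.null(gm) && !is.null(ht)) gm <- ht
  if (is.null(gm)) stop("pipeline needs a genotype matrix or haplotype table")

  out$stats <- stage("stats", {
    st <- locus_stats(gm)
    st$hwe_p_bonferroni <- pmin(1, st$hwe_p * sum(!is.na(st$hwe_p)))
    write_tsv(cbind(st[1], lapply(st[-1], function(v) {
      ifelse(is.na(v), NA, round_half_up(v, 4))
    })), file.path(config$out_dir, "locus_stats.tsv"))
    st
  })

  out$ld <- stage("ld", {
    sl <- build_super_loci(gm, r2_threshold = config$r2_threshold,
                           alpha = config$alpha, n_perm = config$n_perm,
                           seed = config$seed,
                           posterior_min = config$posterior_min)
    write_tsv(sl$ld, file.path(config$out_dir, "ld_pairs.tsv"))
    jsonlite::write_json(
      lapply(sl$super_loci, function(s) {
        s[c("id", "members", "haplotypes", "labels", "freqs")]
      }),
      file.path(config$out_dir, "super_loci.json"), auto_unbox = TRUE,
      digits = NA)
    sl
  })
  eff <- out$ld$matrix

  out$identity <- stage("identity", {
    rep_ <- match_genotypes(eff, min_shared_loci = config$min_shared_loci)
    md <- min_diff_distribution(rep_)
    acc <- accumulation_curve(eff)
    freqs <- effective_freq_list(eff, out$ld$super_loci)
    cpi <- cumulative_pi(freqs)
    pi_total <- cpi$cum_pi[nrow(cpi)]
    cap_pair <- discrimination_capacity(pi_total, config$confidence,
                                        "pairwise")
    cap_query <- discrimination_capacity(pi_total, config$confidence,
                                         "query")
    clusters_df <- data.frame(
      accession = unlist(rep_$clusters),
      genotype = rep(sprintf("G%03d", seq_along(rep_$clusters)),
                     lengths(rep_$clusters)))
    write_tsv(clusters_df, file.path(config$out_dir, "match_clusters.tsv"))
    write_tsv(data.frame(min_diff = as.integer(names(md$histogram)),
                         n_genotypes = as.integer(md$histogram)),
              file.path(config$out_dir, "min_diff_histogram.tsv"))
    write_tsv(acc, file.path(config$out_dir, "accumulation_curve.tsv"))
    write_tsv(cpi, file.path(config$out_dir, "cumulative_pi.tsv"))
    fp <- data.frame(accession = eff$accessions$id,
                     barcode = export_barcode(eff))
    write_tsv(fp, file.path(config$out_dir, "fingerprints.tsv"))
    jsonlite::write_json(
      list(n_accessions = nrow(eff$geno), n_distinct = rep_$n_distinct,
           n_effective_loci = out$ld$n_effective,
           min_diff_mean = md$mean, min_diff_min = md$min,
           pi_total = pi_total,
           pi_sibs_total = cpi$cum_pi_sibs[nrow(cpi)],
           pi_par_off_total = cpi$cum_pi_par_off[nrow(cpi)],
           capacity_pairwise = as.integer(cap_pair),
           capacity_query = as.integer(cap_query),
           confidence = config$confidence),
      file.path(config$out_dir, "identity_summary.json"),
      auto_unbox = TRUE, digits = NA)
    list(report = rep_, min_diff = md, accumulation = acc,
         cumulative = cpi, capacity_pairwise = cap_pair,
         capacity_query = cap_query)
  })

  if (!is.null(ht) && !identical(ht, gm)) {
    out$segments <- stage("segments", {
      census <- haplotype_census(ht)
      counts <- attr(census, "counts")
      census$hd <- vapply(counts, function(ct) {
        if (sum(ct) >= 2) haplotype_diversity(as.numeric(ct)) else NA_real_
      }, numeric(1))
      write_tsv(census, file.path(config$out_dir, "segment_census.tsv"))
      census
    })
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(out)
}

#' Export genotypes in STRUCTURE format
#'
#' Writes the two-row-per-individual numeric format consumed by the
#' STRUCTURE clustering program (alleles coded as integers per locus,
#' missing as -9), so population assignment can be run externally;
#' Bayesian MCMC clustering itself is out of scope here.
#'
#' @param x a `genotype_matrix`
#' @param file path
#' @export
write_structure <- function(x, file) {
  alleles <- locus_allele_list(x$loci)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(x$loci$locus_id, collapse = "\t"), con)
  for (i in seq_len(nrow(x$geno))) {
    two <- vapply(seq_len(ncol(x$geno)), function(j) {
      g <- x$geno[i, j]
      if (is.na(g)) return(c(-9L, -9L))
      match(genotype_alleles(g), alleles[[j]])
    }, integer(2))
    for (r in 1:2) {
      writeLines(paste(c(x$accessions$id[i], two[r, ]), collapse = "\t"),
                 con)
    }
  }
  invisible(file)
}
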