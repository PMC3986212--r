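#' @title Genotype matrices for cultivar identification
#'
#' @description
#' The central container of the package is the `genotype_matrix`: a
#' rectangular table of unordered diploid allele pairs (accessions in rows,
#' loci in columns) with an explicit missing-data sentinel. Loci may be
#' bi-allelic nucleotide SNPs, multi-allelic "super loci" built from linked
#' SNPs, or sequenced gene segments whose alleles are haplotype identifiers.
#' Heterozygotes are stored order-free ("A/G" and "G/A" are the same
#' genotype) by canonicalizing the allele pair at construction time.
#' @name genotype_data
NULL

# ---- allele / genotype primitives -------------------------------------

sort_alleles <- function(a) {
  suppressWarnings(num <- as.numeric(a))
  if (!anyNA(num)) a[order(num)] else sort(a, method = "radix")
}

#' Canonicalize a diploid genotype string
#'
#' @param g character vector of "X/Y" genotype strings (NA allowed)
#' @return canonical strings with alleles in sorted order
#' @export
canonical_genotype <- function(g) {
  out <- g
  idx <- which(!is.na(g))
  if (length(idx)) {
    parts <- strsplit(g[idx], "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      stop_validation(sprintf("malformed genotype '%s' (expected 'X/Y')",
                              g[idx][bad][1]))
    }
    out[idx] <- vapply(parts, function(p) paste(sort_alleles(p), collapse = "/"),
                       character(1))
  }
  out
}

genotype_alleles <- function(g) {
  if (is.na(g)) return(character(0))
  strsplit(g, "/", fixed = TRUE)[[1]]
}

#' Parse and format reference-anchored SNP names
#'
#' SNP names anchor a marker to the reference assembly as
#' `<chromosome>_<position><allele1>/<allele2>`, e.g. `chr1_7539019A/G`
#' for an A/G polymorphism at reference bp 7,539,019 (1-based) on
#' pseudo-chromosome 1. `chrUn` marks loci on unplaced scaffolds.
#'
#' @param name character vector of SNP names
#' @return `parse_snp_name`: data.frame with columns `chrom`, `pos`,
#'   `allele1`, `allele2`; `format_snp_name`: character vector of names.
#' @export
parse_snp_name <- function(name) {
  m <- regmatches(name, regexec("^(.+)_([0-9]+)([ACGT])/([ACGT])$", name))
  bad <- lengths(m) != 5L
  if (any(bad)) {
    stop_validation(sprintf("cannot parse SNP name '%s'", name[bad][1]))
  }
  df <- data.frame(
    chrom = vapply(m, `[`, character(1), 2),
    pos = as.integer(vapply(m, `[`, character(1), 3)),
    allele1 = vapply(m, `[`, character(1), 4),
    allele2 = vapply(m, `[`, character(1), 5),
    stringsAsFactors = FALSE
  )
  if (any(df$pos < 1L)) stop_validation("SNP position must be >= 1")
  if (any(df$allele1 == df$allele2)) {
    stop_validation("SNP alleles must be distinct")
  }
  df
}

#' @rdname parse_snp_name
#' @param chrom,pos,allele1,allele2 locus fields
#' @export
format_snp_name <- function(chrom, pos, allele1, allele2) {
  sprintf("%s_%d%s/%s", chrom, as.integer(pos), allele1, allele2)
}

# ---- locus metadata ----------------------------------------------------

#' Build a locus metadata table
#'
#' @param locus_id short unique labels
#' @param alleles list of character vectors (or comma-joined strings) of
#'   valid alleles per locus
#' @param name optional reference-anchored SNP names
#' @param chrom,pos optional reference coordinates (1-based)
#' @return data.frame with one row per locus
#' @export
locus_table <- function(locus_id, alleles, name = NA_character_,
                        chrom = NA_character_, pos = NA_integer_) {
  if (anyDuplicated(locus_id)) stop_validation("locus ids must be unique")
  if (is.list(alleles)) {
    alleles <- vapply(alleles, function(a) paste(a, collapse = ","),
                      character(1))
  }
  data.frame(locus_id = as.character(locus_id), name = name,
             chrom = chrom, pos = as.integer(pos),
             alleles = alleles, stringsAsFactors = FALSE)
}

locus_allele_list <- function(loci) {
  out <- strsplit(loci$alleles, ",", fixed = TRUE)
  names(out) <- loci$locus_id
  out
}

# ---- the genotype matrix container ------------------------------------

#' Construct a genotype matrix
#'
#' @param geno character matrix of "X/Y" genotype strings (NA = missing),
#'   accessions in rows, loci in columns
#' @param loci locus metadata as from [locus_table()]; if NULL, alleles are
#'   inferred from the observed genotypes (and coordinates from column
#'   names that parse as SNP names)
#' @param accessions data.frame with at least column `id`; optional `name`
#'   and `group`. Defaults to the row names of `geno`.
#' @return object of class `genotype_matrix`
#' @export
genotype_matrix <- function(geno, loci = NULL, accessions = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "character"
  geno[geno %in% c("-", "", "./.", "-/-", "--")] <- NA_character_
  geno[] <- canonical_genotype(geno)

  if (is.null(accessions)) {
    ids <- rownames(geno) %||% sprintf("acc%03d", seq_len(nrow(geno)))
    accessions <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  accessions$id <- as.character(accessions$id)
  if (anyDuplicated(accessions$id)) {
    stop_validation("accession ids must be unique")
  }
  if (nrow(accessions) != nrow(geno)) {
    stop_validation("accession table and genotype matrix disagree in size")
  }
  if (is.null(accessions$group)) accessions$group <- NA_character_

  if (is.null(loci)) {
    ids <- colnames(geno) %||% sprintf("L%02d", seq_len(ncol(geno)))
    obs <- apply(geno, 2, function(col) {
      al <- unique(unlist(strsplit(col[!is.na(col)], "/", fixed = TRUE)))
      paste(sort_alleles(al), collapse = ",")
    })
    parsed <- tryCatch(parse_snp_name(ids), error = function(e) NULL)
    if (!is.null(parsed)) {
      loci <- locus_table(ids, obs, name = ids, chrom = parsed$chrom,
                          pos = parsed$pos)
    } else {
      loci <- locus_table(ids, obs)
    }
  }
  if (nrow(loci) != ncol(geno)) {
    stop_validation("locus table and genotype matrix disagree in size")
  }
  rownames(geno) <- accessions$id
  colnames(geno) <- loci$locus_id

  validate_alleles(geno, loci)
  structure(list(geno = geno, loci = loci, accessions = accessions),
            class = "genotype_matrix")
}

validate_alleles <- function(geno, loci) {
  allowed <- locus_allele_list(loci)
  for (j in seq_len(ncol(geno))) {
    ok <- allowed[[j]]
    if (length(ok) == 0 || (length(ok) == 1 && ok == "")) next
    cells <- geno[, j]
    idx <- which(!is.na(cells))
    if (!length(idx)) next
    al <- strsplit(cells[idx], "/", fixed = TRUE)
    bad <- vapply(al, function(a) !all(a %in% ok), logical(1))
    if (any(bad)) {
      i <- idx[which(bad)[1]]
      stop_validation(sprintf(
        "allele not valid for locus '%s' in accession '%s': got '%s', allowed {%s}",
        loci$locus_id[j], rownames(geno)[i], cells[i], loci$alleles[j]))
    }
  }
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d accessions x %d loci (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by accessions and/or loci
#'
#' @param x a `genotype_matrix`
#' @param accessions,loci id vectors (or logical/integer indices)
#' @return a `genotype_matrix`
#' @export
subset_matrix <- function(x, accessions = NULL, loci = NULL) {
  ai <- if (is.null(accessions)) seq_len(nrow(x$geno)) else {
    if (is.character(accessions)) match(accessions, x$accessions$id)
    else accessions
  }
  li <- if (is.null(loci)) seq_len(ncol(x$geno)) else {
    if (is.character(loci)) match(loci, x$loci$locus_id) else loci
  }
  if (anyNA(ai)) stop_validation("unknown accession id in subset")
  if (is.numeric(li) && anyNA(li)) stop_validation("unknown locus id in subset")
  genotype_matrix(x$geno[ai, li, drop = FALSE],
                  loci = x$loci[li, , drop = FALSE],
                  accessions = x$accessions[ai, , drop = FALSE])
}

# ---- CSV dialect -------------------------------------------------------

#' Read a genotype table from CSV
#'
#' The dialect is a plain comma-separated UTF-8 table: first column the
#' accession id, an optional `group` column, then one column per locus with
#' cells `"X/Y"` and `"-"` for missing. Column headers that parse as
#' reference-anchored SNP names supply the locus metadata; otherwise
#' alleles are taken from `loci` or inferred from the data.
#'
#' @param file path or connection
#' @param loci optional locus metadata; cells are validated against it
#' @param group_col name of the optional group column
#' @return a [genotype_matrix()]
#' @export
read_genotype_csv <- function(file, loci = NULL, group_col = "group") {
  if (is.character(file) && file.exists(file)) {
    nf <- utils::count.fields(file, sep = ",", quote = "\"")
    if (length(unique(nf)) > 1) {
      stop_validation("ragged CSV: rows have differing field counts")
    }
  }
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop_validation("genotype CSV needs id + locus columns")
  ids <- df[[1]]
  df <- df[, -1, drop = FALSE]
  group <- NULL
  if (group_col %in% names(df)) {
    group <- df[[group_col]]
    df <- df[, setdiff(names(df), group_col), drop = FALSE]
  }
  geno <- as.matrix(df)
  rownames(geno) <- ids
  acc <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(group)) acc$group <- group
  genotype_matrix(geno, loci = loci, accessions = acc)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_csv()]: `read_genotype_csv(write_genotype_csv(x))`
#' reproduces `x` cell for cell.
#'
#' @param x a `genotype_matrix`
#' @param file path
#' @export
write_genotype_csv <- function(x, file) {
  out <- x$geno
  out[is.na(out)] <- "-"
  df <- data.frame(id = x$accessions$id, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(is.na(x$accessions$group))) df$group <- x$accessions$group
  df <- cbind(df, as.data.frame(out, stringsAsFactors = FALSE,
                                check.names = FALSE))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# ---- genetic barcodes --------------------------------------------------

#' Export per-accession genetic barcode strings
#'
#' Collapses each multilocus genotype into a canonical string: homozygotes
#' as `"AA"`, heterozygotes with alleles in sorted order (`"AG"`), missing
#' as `"--"`, loci joined by `"|"`. Two accessions share a barcode string
#' exactly when they share a multilocus genotype over the chosen loci, so
#' the strings can serve as keys of a fingerprint database.
#'
#' @param x a `genotype_matrix`
#' @param loci locus ids defining the barcode order (default: all loci in
#'   matrix order)
#' @return named character vector, one barcode per accession
#' @export
export_barcode <- function(x, loci = x$loci$locus_id) {
  li <- match(loci, x$loci$locus_id)
  if (anyNA(li)) stop_validation("barcode loci must be a subset of matrix loci")
  sub <- x$geno[, li, drop = FALSE]
  codes <- apply(sub, c(1, 2), function(g) {
    if (is.na(g)) "--" else paste(genotype_alleles(g), collapse = "")
  })
  out <- apply(codes, 1, paste, collapse = "|")
  names(out) <- x$accessions$id
  out
}

# ---- VCF export / import ----------------------------------------------

#' Write a genotype matrix as VCF 4.2
#'
#' One record per locus with unphased diploid GT fields (`0/0`, `0/1`, ...,
#' `./.` for missing). Loci must carry chromosome and position metadata.
#' The first listed allele of each locus is emitted as REF.
#'
#' @param x a `genotype_matrix`
#' @param file path
#' @export
write_vcf <- function(x, file) {
  if (anyNA(x$loci$chrom) || anyNA(x$loci$pos)) {
    stop_validation("VCF export needs chromosome/position for every locus")
  }
  alleles <- locus_allele_list(x$loci)
  contigs <- unique(x$loci$chrom)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=snpbarcode",
           sprintf("##contig=<ID=%s>", contigs),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$accessions$id), collapse = "\t"))
  rows <- vapply(seq_len(ncol(x$geno)), function(j) {
    al <- alleles[[j]]
    gt <- vapply(x$geno[, j], function(g) {
      if (is.na(g)) return("./.")
      paste(sort(match(genotype_alleles(g), al)) - 1L, collapse = "/")
    }, character(1))
    alt <- if (length(al) > 1) paste(al[-1], collapse = ",") else "."
    paste(c(x$loci$chrom[j], x$loci$pos[j], x$loci$locus_id[j], al[1],
            alt, ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' Read a VCF file into a genotype matrix
#'
#' Uses the vcfR parser; only the GT field is consumed.
#'
#' @param file path to an (uncompressed or gzipped) VCF
#' @return a [genotype_matrix()]
#' @export
read_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- lapply(seq_len(nrow(fix)), function(j) {
    alt <- fix[j, "ALT"]
    if (is.na(alt) || alt == ".") return(fix[j, "REF"])
    c(fix[j, "REF"], strsplit(alt, ",", fixed = TRUE)[[1]])
  })
  geno <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) {
    al <- alleles[[j]]
    codes <- gt[j, ]
    ok <- !is.na(codes) & codes != "./." & codes != ".|."
    idx <- strsplit(gsub("|", "/", codes[ok], fixed = TRUE), "/", fixed = TRUE)
    geno[which(ok), j] <- vapply(idx, function(i) {
      paste(sort_alleles(al[as.integer(i) + 1L]), collapse = "/")
    }, character(1))
  }
  rownames(geno) <- colnames(gt)
  colnames(geno) <- fix[, "ID"]
  loci <- locus_table(fix[, "ID"],
                      vapply(alleles, paste, character(1), collapse = ","),
                      chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
  genotype_matrix(geno, loci = loci)
}
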