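#' @title Tajima-Nei distances, NJ trees and hybrid screening
#'
#' @description
#' Equal-input (Tajima-Nei) nucleotide distances between aligned
#' sequences, neighbour-joining trees over segment haplotypes together
#' with reference genomes, and a nearest-reference rule that flags
#' accessions carrying haplotypes closer to mandarin (or outgroup)
#' references than to pummelo references - the computational counterpart
#' of reading interspecific hybrids off a tree.
#' @name phylo
NULL

#' Tajima-Nei (equal-input) distance between two aligned sequences
#'
#' d = -b ln(1 - p/b), where p is the proportion of mismatching sites and
#' b = 1 - sum q_i^2 over the base frequencies q_i pooled across both
#' sequences. Sites with N or a gap in either sequence are excluded. At
#' uniform base composition b = 0.75 and the formula reduces to
#' Jukes-Cantor.
#'
#' @param a,b equal-length aligned sequences (strings or character
#'   vectors)
#' @return distance (substitutions per site)
#' @export
tajima_nei_distance <- function(a, b) {
  if (length(a) == 1) a <- strsplit(toupper(a), "")[[1]]
  if (length(b) == 1) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) stop_validation("sequences must be aligned")
  nt <- c("A", "C", "G", "T")
  valid <- a %in% nt & b %in% nt
  if (!any(valid)) stop_undefined("no jointly valid sites")
  a <- a[valid]; b <- b[valid]
  p <- mean(a != b)
  if (p == 0) return(0)
  q <- table(factor(c(a, b), levels = nt)) / (2 * length(a))
  bb <- 1 - sum(q^2)
  if (p >= bb) {
    stop_undefined(sprintf(
      "distance saturated (p = %.3f >= b = %.3f)", p, bb))
  }
  -bb * log(1 - p / bb)
}

#' Tajima-Nei distance matrix
#'
#' @param seqs named character vector of aligned sequences
#' @return symmetric matrix with zero diagonal
#' @export
tn_distance_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  chars <- strsplit(toupper(seqs), "")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- tajima_nei_distance(chars[[i]], chars[[j]])
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration (via ape) on a distance matrix; negative
#' branch lengths, an artefact of non-additive distances, are clamped to
#' zero and flagged in the `clamped` attribute.
#'
#' @param dm symmetric distance matrix (or `dist`) with >= 3 labels
#' @return an unrooted `phylo` tree
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop_validation("NJ needs at least 3 labels")
  if (max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0)) {
    stop_validation("distance matrix must be symmetric with zero diagonal")
  }
  tree <- ape::nj(stats::as.dist(dm))
  neg <- tree$edge.length < 0
  if (any(neg)) tree$edge.length[neg] <- 0
  attr(tree, "clamped") <- sum(neg)
  tree
}

#' Flag putative interspecific hybrids by nearest reference
#'
#' Every haplotype of every segment is assigned the class (e.g. pummelo /
#' mandarin / outgroup) of its nearest reference sequence under the
#' Tajima-Nei distance; an exact distance tie yields class "ambiguous",
#' which is never counted as evidence. An accession is flagged as a
#' hybrid when at least one of its haplotype copies in at least one
#' segment is classified non-pummelo.
#'
#' @param table haplotype table (`genotype_matrix`, segments as loci)
#' @param hap_sequences named list per segment: named character vector
#'   mapping haplotype id to its sequence
#' @param references data.frame with columns `segment`, `label`, `class`,
#'   `sequence`; at least one `native_class` reference per segment
#' @param native_class the non-hybrid class (default "pummelo")
#' @return data.frame per accession: `accession`, `n_foreign` (foreign
#'   haplotype copies summed over segments), `hybrid` flag; attribute
#'   `haplotype_classes` holds the per-segment classification table
#' @export
flag_hybrids <- function(table, hap_sequences, references,
                         native_class = "pummelo") {
  segs <- table$loci$locus_id
  class_tabs <- list()
  for (s in segs) {
    refs <- references[references$segment == s, , drop = FALSE]
    if (!any(refs$class == native_class)) {
      stop_validation(sprintf("no '%s' reference for segment %s",
                              native_class, s))
    }
    haps <- hap_sequences[[s]]
    cls <- vapply(names(haps), function(h) {
      d <- vapply(seq_len(nrow(refs)), function(r) {
        # a saturated distance carries no signal: rank it last
        tryCatch(tajima_nei_distance(haps[[h]], refs$sequence[r]),
                 snpbarcode_undefined = function(e) Inf)
      }, numeric(1))
      if (all(!is.finite(d))) return("ambiguous")
      best <- which(d <= min(d) + 1e-12)
      if (length(unique(refs$class[best])) > 1) "ambiguous"
      else refs$class[best[1]]
    }, character(1))
    class_tabs[[s]] <- data.frame(segment = s, haplotype = names(haps),
                                  class = unname(cls),
                                  stringsAsFactors = FALSE)
  }
  class_map <- do.call(rbind, class_tabs)
  n_foreign <- vapply(table$accessions$id, function(a) {
    tot <- 0
    for (s in segs) {
      g <- table$geno[a, s]
      if (is.na(g)) next
      al <- genotype_alleles(g)
      cl <- class_map$class[match(paste(s, al), paste(class_map$segment,
                                                      class_map$haplotype))]
      tot <- tot + sum(!is.na(cl) & cl != native_class & cl != "ambiguous")
    }
    tot
  }, numeric(1))
  out <- data.frame(accession = table$accessions$id,
                    n_foreign = unname(n_foreign),
                    hybrid = unname(n_foreign) > 0,
                    stringsAsFactors = FALSE)
  attr(out, "haplotype_classes") <- class_map
  out
}
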