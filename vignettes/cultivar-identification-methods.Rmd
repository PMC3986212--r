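---
title: "Methods: SNP panels and sequence segments as genetic barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP panels and sequence segments as genetic barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpbarcode)
```

# The problem

Tree-crop cultivars — here pummelo (*Citrus maxima*), a mono-embryonic
citrus propagated both sexually and clonally — are routinely
mis-identified from morphology alone. A small panel of DNA markers turns
identification into a database lookup: genotype the candidate at a fixed
set of loci, collapse the multilocus genotype into a canonical barcode
string, and compare against a reference fingerprint collection. This
package implements the statistics that make such a panel trustworthy:
how informative each marker is, how independent the markers are, how
often two distinct cultivars would collide by chance, and how many
cultivars a panel can therefore support. A second, sequence-based route
treats each of a dozen short nuclear gene segments (roughly 410–630 bp)
as one multi-allelic locus whose alleles are haplotypes, which packs far
more discriminating power per locus than a single bi-allelic SNP.

# Per-locus statistics

For allele frequencies $p_i$ counted over non-missing gene copies:

* expected heterozygosity $H_e = 1 - \sum_i p_i^2$ (Nei's gene
  diversity, uncorrected);
* polymorphic information content
  $PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ (Botstein), which
  for a bi-allelic locus reduces to $H_e - 2(pq)^2$ and always satisfies
  $PIC \le H_e$;
* fixation coefficient $f = (H_e - H_o)/H_e$;
* an exact conditional Hardy–Weinberg test (the probability, given the
  allele counts, of all heterozygote counts no more probable than the
  observed one). The exact test was chosen over the chi-square
  approximation because the collection subgroups analysed this way are
  small (tens of genotypes); the reference study does not name its test.
* Weir–Cockerham $\theta$ for $F_{st}$, combined over loci and alleles
  as a ratio of sums.

A deliberate asymmetry: SNP-level $H_e$ is *uncorrected*, while
haplotype diversity of sequence segments uses Nei's unbiased form
$H_d = \frac{n}{n-1}(1 - \sum_i p_i^2)$. The published per-segment
diversity table reproduces only under the corrected form, and the
published SNP panel table only under the uncorrected one, so the package
keeps both conventions and names them separately
(`expected_heterozygosity()` vs `haplotype_diversity()`).

Reported tables round half-up to two decimals (`round_half_up()`); exact
values are retained internally.

# Panel selection

`select_panel()` implements the published screening rule: candidates
must have minor allele frequency strictly above 0.10 (a MAF of exactly
0.10 is excluded); survivors are ranked by PIC descending (ties broken
by locus id, so selection is deterministic) and accepted greedily unless
in significant LD with an already accepted marker, except for markers
explicitly kept as super-locus material.

# Linkage, EM and super loci

Haplotype frequencies over 2..k loci are estimated from unphased diploid
genotypes by EM over the multinomial likelihood under random union of
gametes. Numerical choices:

* deterministic uniform initialization over the haplotype space
  compatible with at least one fully typed accession;
* convergence when the largest frequency change falls below $10^{-8}$,
  capped at 1,000 iterations (non-convergence returns the best
  likelihood reached, with a warning in the phasing wrapper);
* the log-likelihood is asserted non-decreasing at every iteration;
* for two loci the symmetric double-heterozygote configuration is a
  saddle point of the uniform start, so two phase-biased restarts are
  also run; exact mirror-solution ties are resolved toward the higher
  coupling-gamete frequency and flagged (`tie = TRUE`).

Pairwise LD is $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$ with
$D = p_{AB} - p_A p_B$ for bi-allelic loci, and the generalized
$\sum_{ab} D_{ab}^2 / ((1-\sum_a p_a^2)(1-\sum_b p_b^2))$ for
multi-allelic ones. Significance is a permutation test (one genotype
column shuffled across accessions, the EM-based $r^2$ recomputed; the
reference study names no test), with the p-value
$(1 + \#\{r^2_{perm} \ge r^2_{obs}\})/(n_{perm}+1)$; it is seeded and
reproducible. Markers joined by significant LD ($r^2 > 0.1$ and
$p < 0.05$) form the connected components of an LD graph; components of
two or more markers become *super loci*, recoded as single multi-allelic
markers whose alleles are the EM haplotypes. An accession's recoded
genotype is its most probable haplotype pair, or missing when the phase
posterior is below 0.95 — a missing cell never fabricates a haplotype.
The effective locus count (singletons + super loci) is what the product
rule below multiplies over.

Running the same scan on the bundled 12-segment haplotype table merges
more segment pairs than the published analysis did (which merged one
pair). The permutation test is correctly calibrated under the null (the
test suite checks uniformity of its p-values), so these extra edges
reflect genuine association among the 20 related true-to-type cultivars
— several are members of the same cultivar families — under the
generalized multi-allelic statistic. Merging more aggressively is
conservative for identification: it can only weaken the claimed
discriminating power, never inflate it.

# Identity statistics

With $s_2 = \sum_i p_i^2$ and $s_4 = \sum_i p_i^4$, the per-locus match
probabilities under Hardy–Weinberg are

* two random individuals: $PI = 2 s_2^2 - s_4$;
* parent–offspring: $PI_{par\text{-}off} = s_2$;
* full siblings:
  $PI_{sibs} = \tfrac14 + \tfrac12 s_2 + \tfrac12 s_2^2 - \tfrac14 s_4$,

with $PI \le PI_{par\text{-}off} \le PI_{sibs}$ always. Genotype-specific
forms follow the forensic standard: for the observed genotype $g$,
$PI_g$ is its HWE frequency, $PI_{sibs,g}$ is $(1+p_i)^2/4$ for a
homozygote and $(1+p_i+p_j+2p_ip_j)/4$ for a heterozygote, and
$PI_{par\text{-}off,g}$ is $p_i$ resp. $(p_i+p_j)/2$. The reference
study states no equations; all five forms are verified in the test suite
against independent enumeration over genotype and transmission space.
Panel-level values multiply across *effective* loci (super loci counted
once, using their EM haplotype frequencies), which is why super-locus
recoding is a precondition of the product rule.

Duplicate detection declares two accessions identical when they disagree
at zero co-typed loci (configurable) and share at least
`min_shared_loci = 6` typed loci; clusters are transitive closures.
The default 6 keeps accessions with a couple of failed segments
placeable while refusing matches based on nearly empty profiles.
Accessions typed at fewer loci than the floor are reported unplaceable
and excluded from the distinct-genotype count.

## Discrimination capacity

The published capacity formula is described only in words ("the chance
for the non-existence of any false identical genotypes ... is larger
than 95%"); its display equation is not recoverable from the source
text. Both defensible readings are implemented and every capacity number
carries its mode:

* **pairwise** (default): largest $n$ with
  $(1-PI)^{n(n-1)/2} \ge 0.95$ — no collision among all pairs;
* **query**: largest $n$ with $n \cdot PI \le 0.05$ — one candidate
  checked against a database of $n$.

The pairwise reading reproduces the published "at least 1000 cultivars"
claim from the published panel PI of $5.28\times10^{-8}$ (it gives
1394); the query reading gives a far larger number. Neither reading
reproduces the published "40 to 150 siblings" range from the published
$PI_{sibs}$ values, so that range is documented but not asserted
anywhere.

# Sequence segments

SNPs in aligned cloned amplicons are called under the clone-support
rule: a column is a variant only if at least two alleles are each
carried by two or more sequences — singletons are the signature of
PCR/sequencing error in cloned material. Diversity statistics are
$S$ (segregating sites), $\pi$ (mean pairwise difference per site,
unbiased, N/gap sites excluded pairwise) and $H_d$ as above. Phasing of
unphased segment genotypes reuses the EM engine (capped at 12 sites,
i.e. 2048 phase resolutions per double-heterozygous accession);
haplotype ids are dense integers assigned by first occurrence in input
order, forming a per-segment namespace exactly as in the bundled
haplotype-pair table.

# Trees and hybrid screening

Tajima–Nei (equal-input) distances,
$d = -b \ln(1 - p/b)$ with $b = 1 - \sum_i q_i^2$ over pooled base
frequencies, feed neighbour-joining trees (via ape's NJ; negative branch
lengths are clamped to zero and flagged). The reference method names no
model parameters, and the trees here serve classification rather than
dating, so the simple equal-input variant suffices. Hybrid screening
replaces the visual tree reading of the original workflow with an
explicit rule: each haplotype takes the class of its nearest reference
sequence (pummelo / mandarin / outgroup); exact distance ties — and
saturated, hence uninformative, distances — classify as "ambiguous" and
never count as evidence; an accession is flagged as a hybrid when any
haplotype copy at any segment is non-pummelo. Nearest-reference was
chosen over a monophyly test because clade membership is brittle on
segments this short.

# The synthetic collection

`simulate_genotypes()` emulates the structure the study reports rather
than re-inferring it: four subpopulations at $F_{st} = 0.16$ under the
Balding–Nichols model (subpopulation frequencies
$\mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ around ancestral
frequencies drawn uniformly with MAF in $(0.10, 0.50]$, with a rejection
step keeping the pooled MAF inside the window); 260 accessions as 99
cultivars (12 sampled as three clonal individuals, 30 as two — somatic
mutants are genotypically identical to their founder at panel loci), 52
further unique accessions and 55 unique seedlings; missing data
(default 0.5%) and genotyping error applied last. Two error modes
exist because the study's observed errors were whole-profile sample
swaps: per-cell replacement (default) and profile swapping.

`simulate_segments()` builds per-segment haplotype pools by placing
1–10 SNPs on a random base sequence with 2–9 haplotypes per segment
(the published per-segment ranges), frequencies from a symmetric
Dirichlet (α = 1), plus a mandarin pool diverged by 2% per site for
planting hybrids. Both generators are byte-reproducible from their
seeds.

What the generators do *not* emulate: real linkage blocks along
chromosomes (LD appears only where planted), ascertainment bias of the
marker discovery process, genotyping chemistry artefacts (melting-curve
behaviour, primer-template mismatches), indels, and recombination
within segments. Tests passing on synthetic data therefore validate the
estimators and the pipeline logic, not the field behaviour of any
particular marker set.

# Problem sizes used in the checks

The test suite and the analysis scripts run at deliberately moderate
scale: the bundled 24 × 12 haplotype table and 25-SNP panel statistics
exactly as published; synthetic collections of 260 × 25 for
pipeline-level checks; 160 individuals × 200 loci (a handful of seeds)
for $F_{st}$ recovery; 40 accessions × 6 segments for phasing recovery;
100 random 5–10 taxon trees for NJ; 200 replicates for permutation-test
calibration. These sizes give stable checks with comfortable margins
while keeping a full run in minutes.

# Known limitations

* The product rule assumes effective loci are independent *and*
  Hardy–Weinberg holds within the group analysed; in structured
  collections PI is therefore optimistic, which is why per-group
  analyses (and the published per-population spread of two orders of
  magnitude) matter.
* The exact HWE test is bi-allelic; multi-allelic loci fall back to no
  test rather than a chi-square of doubtful validity at these sample
  sizes.
* Phasing and super-locus recoding refuse low-posterior assignments
  instead of imputing them; downstream counts treat those cells as
  missing.
* HWE and LD p-values are reported raw, as in the reference analysis; a
  Bonferroni column is emitted alongside for transparency, and neither
  drives any hard-coded decision.
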