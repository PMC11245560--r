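---
title: "Detecting diploid fungal hybrids and dissecting transgressive expression"
author: "hybridtriad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diploid fungal hybrids and dissecting transgressive expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Parasexual hybridization between closely related haploid fungal lineages can
produce intraspecific diploid hybrids: one nucleus carrying a haplotype from
each parent. Such hybrids are recognisable from sequencing data alone through
a set of convergent signatures, and once recognised, the natural next
question is whether hybridity confers a fitness advantage (heterosis) — and
which genes drive it. `hybridtriad` implements that whole inference chain as
reusable, tested components:

1. **Ploidy diagnostics.** A diploid with heterozygous loci shows a bimodal
   canonical k-mer spectrum — a heterozygous peak at half the coverage of the
   homozygous peak — and an alternative-allele frequency profile concentrated
   at 0.5, where haploids concentrate at 1.0.
2. **Population structure.** Filtered SNPs, heterozygosity in 100-kb
   windows, IUPAC-encoded genotype matrices, p-distances, and a
   neighbor-joining tree.
3. **Parentage and subgenomes.** Heterozygous SNPs classified against all
   candidate parent pairs; the true pair explains (nearly) every site, with
   the shortfall measuring novel post-hybridization alleles. Hybrid
   chromosomes are assigned to subgenomes by k-mer containment against the
   parents, and haplotypes compared in 500-bp identity windows.
4. **Triad expression.** TMM/CPM/FPKM normalisation, homoeolog expression
   bias (>2-fold dominance), classification of each gene's hybrid expression
   into additive and nonadditive categories (ELD, TUR, TDR, UC),
   allele-specific read rules, and a cis/trans partition of regulatory
   divergence.
5. **Enrichment.** One-sided hypergeometric over-representation with
   Benjamini–Hochberg correction over a gene-to-term map.

Because the original sequencing data are not required, a synthetic-data
module generates every input with known ground truth; every stage is
exercisable end to end on a laptop in seconds to minutes.

## The synthetic-data generator

The generator is first-class, tested code. It emulates:

* **Diverged haploid lineages.** An ancestral genome is drawn uniformly over
  A/C/G/T; lineages accumulate substitutions along a hierarchy fitted to the
  requested pairwise-divergence matrix (average linkage over half-divergences,
  branch rate = height span). Clade-structured matrices — small within-group,
  large between-group divergence — are therefore reproduced in expectation;
  a warning is issued for matrices far from ultrametric, which a tree-free
  per-pair model cannot represent either. Substitution-only divergence keeps
  variant truth exact; indels enter only as explicit gap operations in
  alignment blocks for the identity-window code.
* **Dysploidy.** Fusion concatenates two chromosomes, fission splits one at
  a stated breakpoint; sequences are kept in ancestral coordinates with a
  karyotype map, so site-level truth survives rearrangement.
* **A diploid hybrid**: one haplotype copied from each parent, each
  optionally perturbed by novel substitutions; every heterozygous site is
  truth-labelled parental or novel.
* **Reads**: uniform sampling so the total per-base coverage over the
  diploid equals the requested depth (half per haplotype), constant high
  quality — no downstream stage consumes base quality, and the VCF QUAL
  filter is exercised through simulated site QUAL values instead.
* **Genotype tables**: heterozygous diploid sites split their depth
  Binomial(depth, 0.5) between alleles; haploid sites put every read on the
  single allele.
* **Triad counts**: negative-binomial replicate counts around planted
  category means, homoeolog splits with a planted >2-fold bias fraction, and
  read-level allele-informative observations with a conflict rate.

### Planted expression geometry

With effect size $e$ (log2 units; default 2) and a per-gene baseline drawn
log-normally around `baseline_mean` (default 300, a typical well-expressed
fungal gene at these library sizes):

| category | parents | hybrid |
|----------|---------|--------|
| Additive | equal or $e$ apart | arithmetic mid-parent |
| ELD_P1 / ELD_P2 | $2e$ apart | equal to that parent, planted as the **lower** one |
| TUR | equal (NDE subtype) or $e$ apart (DE) | max-parent × $2^e$ |
| TDR | equal or $e$ apart | min-parent × $2^{-e}$ |
| UC | $3e$ apart | between the parents, $2^{-0.5}$ below baseline |

Two of these choices deserve justification. First, expression-level
dominance toward the *higher* parent is not planted: with a two-fold gate,
the hybrid/mid-parent ratio for upward dominance is $2r/(1+r) < 2$ for any
parental ratio $r$, so upward ELD can never clear the gate and is formally
indistinguishable from additivity under the decision table below — a real
limitation of two-fold-gated triad classification, not of this
implementation. Second, UC ("unclassified") genes are planted so that the
hybrid differs detectably from both parents *and* from the mid-parent while
remaining between the parents; that requires a wide parental gap because the
arithmetic mid-parent is dominated by the higher parent.

The generator's defaults are the conditions under which the package's
recovery claims are tested: 3 replicates, NB dispersion 0.05, effect 2,
70% additive genes (the approximate share reported for hybrid triads),
10% homoeolog-biased genes at 4-fold, 5% conflicting allele-informative
reads, 100 informative reads per gene, and per-sample library-size factors
uniform on [0.8, 1.25] so that TMM has real work to do.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: mapping bias and repeat-driven multi-mapping
(approximated only by the single-copy-interval restriction and the optional
unique-k-mer mask), GC and coverage waviness, indel-containing variants,
shared polymorphism between parent lineages (each site is fixed per
lineage), RNA-seq count overdispersion beyond a single NB dispersion, and
correlated replicate structure.

## Ploidy diagnostics

`count_kmers()` counts canonical k-mers (lexicographic minimum of a k-mer
and its reverse complement; k odd so canonical form is unambiguous, default
17) exactly, in C++. `detect_peaks()` smooths the multiplicity histogram
with a centered moving average (edge-replicated padding, window 3), excludes
the error region below the first local minimum, and reports local maxima
with prominence at least 10% of the retained global maximum — positions from
the smoothed series, heights from the raw one. `call_ploidy()` labels a
spectrum diploid-like iff exactly two peaks sit at a position ratio of
2 ± 20%.

One numerical subtlety: a read of length $L$ contributes $L - k + 1$ k-mers,
so a sample sequenced at depth $D$ has its homozygous k-mer multiplicity
peak at $D\,(L-k+1)/L$ — about $0.89\,D$ for 150-bp reads and $k = 17$ —
not at $D$. Peak tables therefore carry both the raw multiplicity position
and a `coverage` column converted by $L/(L-k+1)$ when the read length is
known; in coverage units a 100× diploid shows its heterozygous peak at ≈50×
and its homozygous peak at ≈100×, which is how such spectra are
conventionally annotated.

The allele-frequency profile bins alternative-allele fractions at width 0.02
with bin *centers* on 0, 0.02, …, 1, so that the haploid signature (fraction
exactly 1) and the diploid signature (fractions near 0.5) fall on bin
centers rather than edges. At depth 50 the fractions are quantised to
multiples of 0.02, making the 0.48/0.50/0.52 bins nearly equiprobable
singleton bins; the diploid modal bin is therefore asserted within
[0.48, 0.52] rather than exactly 0.50.

## Variant filtering and population structure

`filter_variants()` mirrors a two-stage filter: per-sample genotypes are
masked where site QUAL < 20 or sample depth falls outside [10, 400]; sites
are then dropped for minor-allele frequency < 0.02 (computed over the
remaining called alleles, honouring the sequential order), missingness
above 50%, or more than one ALT allele. The operation is idempotent.

Heterozygosity is reported in non-overlapping 100-kb windows, 0-based
half-open internally (VCF positions converted at the boundary). The
denominator is ambiguous in the field — "proportion of heterozygous SNPs"
reads most naturally per SNP, and that is the default, but a per-bp mode is
retained; windows with no called SNPs report a missing value, not zero.

Heterozygous genotypes are encoded as IUPAC degenerate bases (G/T → K),
missing as N. p-distances compare literal symbols (K vs G is a mismatch),
matching what distance tools do when fed IUPAC matrices; an overlap-aware
mode is deliberately out of scope. Neighbor joining is implemented
in-package so its two documented determinism rules hold: ties in the
Q-criterion break on the lexicographically smallest active-node pair, and
negative branch lengths clamp to zero with a count. On additive matrices it
reproduces the generating tree's path lengths to 1e-9 (ape's independent
implementation is the cross-check in the tests, never the implementation).

## Parentage, subgenomes, identity windows

For each hybrid heterozygous site and each candidate pair (p, q):
*pair-explained* iff the unordered hybrid allele pair equals the unordered
(allele_p, allele_q) pair with distinct alleles; *novel-allele* iff a hybrid
allele occurs in no candidate; *shared* iff all candidates agree and that
allele is among the hybrid's; *conflicting* otherwise. This partition is one
consistent reading of diagnostic-class taxonomies whose fine binning varies
between studies, and it is labelled as such. Pairs are ranked by explained
fraction; a best pair under 0.9 raises a missing/extinct-parent flag.

Subgenome support is the fraction of a chromosome's canonical 31-mers
contained anywhere in each parent genome — deterministic and
aligner-free — with an ambiguity margin of 0.05 and an optional
unique-k-mer mask as a crude repeat guard; a BED-like per-chromosome
coverage table can be ingested instead to stay faithful to
alignment-coverage workflows.

Identity windows are query-anchored, 500 bp, non-overlapping: aligned
columns = matches + mismatches + indel columns (insertion columns occupy
query positions; deletion columns attach to the window of the preceding
query position), identity = matches / aligned columns, and windows under
50% aligned coverage report a missing identity. Whether published 500-bp
identity windows count gap columns is generally unstated; counting them as
aligned-but-non-matching is this package's documented convention. PAF input
must carry an extended (`=`/`X`) CIGAR; ambiguous `M` runs are rejected.

## Triad expression

TMM factors follow the standard trimmed-mean-of-M-values estimator: genes
expressed in both sample and reference; M-values trimmed 30% two-sided and
A-values 5% two-sided (average ranks on ties); precision-weighted mean of
surviving M-values; factors rescaled to geometric mean 1. The reference
defaults to the sample whose upper quartile of count rates is closest to
the mean upper quartile. The precision weights depend on absolute library
sizes, so rescaling one sample's counts moves its factor slightly
(~0.5%); with `precision_weights = FALSE` the plain trimmed mean is exactly
scale-invariant. CPM = count / (library size × factor) × 1e6 and
FPKM = CPM × 1000 / CDS length.

`de_test()` is a vectorised Welch t-test on log2(CPM + 1), reporting raw
and BH-adjusted p-values and a conservative flag (BH < α and |log2FC| ≥ 1).
Degenerate zero-variance genes get p = 1 (equal means) or p = 0 flagged
(unequal). Under complete-null NB simulations at n = 3 the raw type-I error
sits slightly *below* nominal (log-scale t-tests on NB counts are mildly
conservative), which the error-control tests assert as a one-sided bound.

The triad decision table, per gene, in order: TUR iff the hybrid is
significantly above both parents; TDR iff below both; Additive iff the
hybrid-vs-mid-parent contrast is non-significant (mid-parent computed per
replicate index, (P1_i + P2_i)/2 on the CPM scale); ELD toward the parent
the hybrid matches while differing from the other; UC otherwise. TUR splits
into NDE-TUR/DE-TUR by the parent-vs-parent contrast. Contrasts are gated
at |log2FC| ≥ 1 and, by default, on the raw t-test p-value at α = 0.05 —
the threshold rule conventional for triad classification, where the
fold-change gate already controls practical relevance; `p_adjust = "BH"` is
available and makes every call strictly more conservative. The same
convention applies to homoeolog dominance (>2-fold plus t-test at 0.05,
global bias tested by a t-test of per-pair log-ratios against zero, with an
FPKM ≥ 1 floor on both homoeologs).

Allele-specific rules: a read is informative with ≥ 2 distinguishing sites
(the count is a parameter, since "at least two SNP(s)" is sometimes read as
one), assigned iff all its alleles match one parent; a gene passes with
≥ 20 assigned reads and < 10% conflicting. The cis/trans partition sets
cis = log2 allelic ratio (Haldane-corrected; exact binomial test against
0.5), P = parental log2 ratio (Welch test), trans = P − cis so the identity
cis + trans = P holds to machine precision; trans significance comes from a
Fisher test of hybrid allele counts against parental pseudo-counts scaled
to the same total. Categories: conserved (neither cis nor trans
significant), cis-only, trans-only, compensatory (cis and trans significant,
P not), cis+trans (same sign), cis×trans (opposite sign, |cis| < |trans|),
ambiguous (remainder); all families BH-adjusted across genes. The exact
decision table is a documented instantiation — published cis/trans
taxonomies differ in their remainder handling.

## Enrichment

One-sided hypergeometric tail p = P(X ≥ k) per term, BH step-up across all
tested terms, fold enrichment (k/n)/(K/N). The universe defaults to all
annotated genes and should be set to all *expressed* genes when the
selection derives from expression analysis; published analyses rarely state
their universe, so it is explicit here.

## Recovery benchmarks and problem sizes

The test suite regenerates everything from seeds; the sizes are the
package's chosen benchmark conditions:

* parental-pair identification and subgenome assignment: 20 seeded hybrids,
  four candidate lineages (clades at 0.5%/2% divergence), 100-kb
  chromosomes, novel rate 0.001 (= 0.05 × parental divergence); both are
  expected correct in 20/20.
* triad classification: 2,000 genes at the default mixture (70% additive),
  effect 2, n = 3, dispersion 0.05; per-category confusion-matrix diagonal
  ≥ 0.9. The benchmark runs at the paper-like mixture rather than balanced
  classes because a balanced mixture violates TMM's mostly-non-DE
  assumption and attenuates the planted fold-changes.
* cis/trans recovery: 900 genes, 100 assigned reads per gene, ≥ 0.85 per
  class.
* error control: 2,000-gene complete nulls for the t-test; 200 seeded null
  annotation maps for enrichment; all-additive null for the TUR
  false-positive rate (bounded by α² since two contrasts must fire).
* k-mer signatures: a 1-Mb diploid at 100× (and the same genome's haploid
  parent at 50×), error-free 150-bp reads.

## Known limitations

* Per-gene Welch t-tests at n = 3 are noticeably less powerful than
  moderated (shared-dispersion) engines; planted effects below ~2-fold
  log2 under BH gating will be under-called. The package exposes both
  gating modes and documents the default.
* Upward expression-level dominance is indistinguishable from additivity
  under a two-fold mid-parent gate (see above).
* The k-mer subgenome assignment assumes parents diverged enough that
  chromosome-scale containment separates them (≥ ~10× the novel-mutation
  rate); it does not model introgression mosaics within a chromosome.
* The identity-window gap convention and the diagnostic-SNP class partition
  are documented choices among several defensible ones; both are labelled
  in outputs.
* p-distances are computed on variant sites only (population-scale SNP
  matrices), so absolute branch lengths are in per-SNP units, not per-bp.
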