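---
title: "Methods: calling derepressed Polycomb targets from RNA-seq and ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling derepressed Polycomb targets from RNA-seq and ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derepressr)
```

## The question the pipeline answers

When a repressive chromatin writer such as the PRC2 methyltransferase Ezh2
is inactivated in a cell population, which genes respond because they were
*directly* repressed — carrying H3K27me3 at their promoter — rather than as
downstream consequences? The pipeline answers this by intersecting two
independent measurements on the same gene universe: differential expression
between control and knockout RNA-seq libraries, and H3K27me3 tag density at
each transcription start site (TSS) from ChIP-seq of control-genotype cells.
A gene called both *upregulated* and *high-marked* is a derepressed
direct-target call.

## Expression: the diffrat score

Expression is quantified as FPKM,
$\mathrm{FPKM}_{gs} = c_{gs} / \big((L_g/10^3)(N_s/10^6)\big)$, with $c_{gs}$
the fragment count, $L_g$ the length of the union of the gene's exon
intervals and $N_s$ the library's mapped fragments. Per-condition means
$a$ (mutant) and $b$ (control) are then compared by the ranking score

$$\mathrm{diffrat}(a, b) = |a - b| \times \log_2\frac{a + 1}{b + 1},$$

the absolute difference times the (pseudocounted) log ratio. The score
blends magnitude and fold change: it vanishes iff $a = b$, is antisymmetric,
and its sign carries direction. Binding $a$ to the mutant condition makes
positive scores mean derepression; nothing in the score itself forces this
convention, so it is stated here once and used everywhere.

### Permutation significance

The score has no known null distribution, so significance is empirical:
condition labels are reassigned across samples, the score recomputed, and
the observed score referred to the permutation distribution of $|$diffrat$|$
(two-sided). All $\binom{n}{n_\text{mut}}$ distinct assignments are
enumerated whenever there are at most `n_permutations` of them (3 v 3 gives
20); otherwise `n_permutations` assignments are sampled under the stated
seed and the add-one estimator $(1 + \#\{|d^*| \ge |d|\})/(1 + B)$ is used.
Ties count as exceedances (conservative). Genes constant across all samples
get $p = 1$ by convention; genes with all-zero counts are retained rather
than filtered. Benjamini–Hochberg adjustment is applied across genes and
calls are made at adjusted $P \le 0.01$.

Two null references are available, and the difference matters:

* **`per_gene`** compares each gene only to its own permuted scores. This is
  exact and is verified in the test suite against brute-force enumeration,
  but its resolution is capped at $2/\binom{2r}{r}$ for $r$ replicates per
  condition — $p \ge 0.1$ at 3 v 3, since the identity assignment and its
  mirror always tie the observed score. No genome-wide threshold of
  adjusted $P \le 0.01$ is then attainable. It is the right tool for
  checking calibration and for designs with many replicates.
* **`pooled`** (the default for genome-scale calling) borrows resolution
  across genes, as moderated permutation methods in the SAM tradition do.
  Each gene's $|$diffrat$|$ is standardised and referred to the pooled
  standardised null over all genes × mixed assignments, giving a resolution
  floor of order $1/(G \times E)$ — fine enough for adjusted calls at 0.01
  from three replicates, which is how a genome-wide ranking with few
  per-embryo libraries can produce calls at that threshold at all.

The pooled construction has three deliberate ingredients. First, the null
pool uses only *mixed* assignments: the identity assignment and its mirror
reproduce $\pm$ the observed score exactly, so including them would let
every truly responding gene inject its own signal into the shared null and
inflate everyone's p-values. Second, the standardising scale for each gene
is the **larger** of its own mixed-assignment spread and a binned-median
trend of spread against mean expression (bins of roughly 100 genes,
interpolated on the log scale): the per-gene component deflates genes with
real signal, while the trend floor stops genes whose spread happens to be
underestimated — diffrat noise grows with expression, so a single global
constant either drowns low-expressed genes or under-corrects high-expressed
ones. Third, pooled null values are standardised **leave-one-out**: the
observed score is standardised by a spread estimated without it, so each
null value must be too, otherwise observed scores are systematically
out-of-sample relative to the pool and the test is anticonservative. The
test suite checks the resulting calibration on a 2000-gene global-null
fixture (fraction of genes at adjusted $P \le 0.01$ must stay within 0.02)
and target recovery on the default fixture.

## Chromatin: TSS tag density on a 0–10 scale

For each gene the pipeline counts ChIP tag positions $p$ with
$\mathrm{TSS} - w \le p < \mathrm{TSS} + w$, $w = 2000$ bp — "within 2 kb"
read as a symmetric ±2 kb window, half-open on the right in BED's 0-based
convention. The TSS is strand-aware (gene start on `+`, gene end on `-`);
tag strand is ignored, as a histone mark has no strand. If an annotation
supplies several TSSs per gene, the maximum window count would be taken;
the built-in generator emits one canonical TSS per gene.

Raw counts $x$ are placed on a bounded log scale,
$\mathrm{scaled} = \min\!\big(10,\; 10 \cdot \log(x+1)/\log(q+1)\big)$,
where $q$ is the 0.95 empirical quantile of the raw counts — "the smallest
value that captured 95% of the data" — computed on raw (not log) counts.
The anchor count maps to exactly 10, larger counts are clipped (a "0 to 10
point scale" is bounded), and the base of the logarithm cancels in the
ratio. Genes scale to 0 when the anchor itself is 0. Genes with scaled
value ≤ 2 are classed **low**, above 2 **high**; the boundary value 2.0 is
low. Note the arithmetic consequence tested by the suite: a background
window count $x_b$ stays below the boundary only while
$x_b + 1 \le (q+1)^{1/5}$, so a meaningful high/low split requires marked
windows to out-count background by a large factor.

## Integration and the association analyses

DE status × mark class yields six categories that partition the gene
universe; `marked_up` genes are the derepressed direct-target calls and
`marked_down` their repressed counterparts. Two companion analyses probe
the mark itself: a two-sided Wilcoxon rank-sum comparison of per-gene mean
FPKM between high- and low-marked genes within each condition (marked genes
are expected lower — they are repressed), and a two-sided Fisher's exact
test on the 2×2 table of mark class against DE status (is the mark
predictive of responding at all?). "Differentially expressed" in the
association test means status ≠ `ns` at the caller's alpha. The rank-sum
test is a choice — any two-sample location test would serve — made for its
distribution-freeness on heavy-tailed expression values.

## Rescue genetics

`mendelian_expected_fraction()` computes offspring genotype probabilities as
the product over independently assorting loci of uniform gamete segregation;
a Cre transgene is modelled as a hemizygous dominant locus (`cre/0` × `0/0`
transmits to half the offspring). For the rescue cross of
`Ezh2 fl/+; Cre cre/0; Mmp9 -/+` sires with `Ezh2 fl/fl; Mmp9 -/-` dams,
the triple genotype `Ezh2 fl/fl; cre+; Mmp9 -/-` is expected in
$\tfrac12 \cdot \tfrac12 \cdot \tfrac12 = 12.5\%$ of conceptuses, and the
conditional knockout pooled over Mmp9 genotypes in 25% — the pooled reading
is the only one consistent with both printed fractions, and is the one
implemented. Fractions are conception-time expectations; lethality before
genotyping is deliberately not modelled. `fisher_exact_2x2()` implements
the exact two-sided test by hypergeometric enumeration (all tables with the
observed margins whose probability does not exceed the observed table's,
with a $10^{-7}$ relative tolerance for floating-point ties) and reports the
sample (cross-product) odds ratio, stated as such in its output. A zero
margin yields a flagged degenerate result rather than an error.

## The synthetic-data generator

The generator emulates the sorted-endothelium study design at desk scale:
two genotypes, three per-embryo replicate libraries each, 2000 genes of
which 18% carry the mark, 50 marked genes truly upregulated on knockout and
6 downregulated, plus 50 responders without the mark — the same proportions
as a genome-scale experiment with thousands of marked genes and an
order-of-magnitude excess of derepressed over downregulated direct targets,
at a size where exhaustive oracles run in seconds. Defaults chosen where
the study design fixes nothing, once, on realism grounds:

| parameter | default | rationale |
|---|---|---|
| `baseline_log_mean`, `baseline_log_sd` | log(300), 1.2 | log-normal relative expression spanning ~2 orders of magnitude, as bulk RNA-seq does |
| `marked_expression_factor` | 0.25 | repressed (marked) genes sit ~4× lower |
| `nb_dispersion` | 0.05 | typical biological replicate dispersion for sorted cells |
| `library_size` | 2×10⁶ | hundreds of fragments per gene at 2000 genes |
| `target_log2fc_mean`, `sd` | 2, 0.25 | \|log2 FC\| ≈ 2 for true responders |
| `chip_background_rate` | 5×10⁻⁵ tags/bp | ~0.2 background tags per 4 kb window |
| `chip_enrichment_factor` | 500 | see below |
| `prop_unmarked_up` | 0.8 | upregulation dominates the unmarked DE set too |

The large ChIP enrichment factor is not a typo: as derived above, the
quantile-anchored scale with its boundary at 2/10 requires marked windows
to exceed background by roughly $(x_b+1)^5$, so an on/off mark at desk
scale needs window rates of ~0.2 vs ~100. The generator reproduces the
*decision structure* the classifier assumes, not the shape of real ChIP
coverage.

RNA counts are negative-binomial at gene level with a common dispersion;
mutant means are the control means times $2^{\mathrm{lfc}}$ (no
renormalisation of the mutant library, so fold changes are exact in
expectation). ChIP tags are Poisson: uniform background along each
chromosome plus extra tags in marked TSS windows. Coordinates are 0-based
half-open throughout; fixtures serialise to BED12/BED6/TSV/YAML with a JSON
manifest, byte-identically for a fixed seed.

What passing tests therefore do and do not show: they verify every formula,
boundary convention and calibration property on data with the assumed
statistical structure. They do not probe isoform complexity, batch effects,
input-chromatin bias, broad H3K27me3 domains, or mapping artefacts — none
of which the generator models — so performance numbers on fixtures are
contracts about the code, not forecasts about any real library.

## Numerical conventions and degenerate inputs

* Permutation exceedance uses a $10^{-9}$ relative tolerance so the
  identity assignment, recomputed by matrix product, always ties the
  observed score.
* Exhaustive per-gene p-values are $\#\{|d^*| \ge |d|\}/K$ over all $K$
  assignments (the identity split is part of the enumeration); sampled
  p-values use the add-one estimator. The minimal exhaustive p at 3 v 3 is
  therefore exactly $2/20 = 0.1$.
* Empirical quantiles use R's default (type 7) interpolation.
* An empty tag set gives all-zero counts; genes on chromosomes absent from
  the tag set get count 0 with a warning; an empty annotation gives an
  empty tag set.
* `scale_to_ten` with an all-zero anchor returns all zeros;
  `classify_mark` rejects values outside $[0, 10]$ as an upstream bug.
* Library sizes default to column sums when not supplied; supplied values
  win, allowing totals that include unassigned fragments.

## Problem sizes

The test suite and examples run the full pipeline at 2000 genes × 6
libraries with 20 exhaustive label assignments (seconds per run), exhaustive
Fisher verification over all 2×2 tables to $N = 30$ plus random tables to
$N = 100$, and permutation-oracle checks across replicate designs up to
5 v 5. These sizes exercise every code path — enumeration and sampling,
pooled and per-gene nulls — while keeping any single check near-instant.

## Known limitations

* The pooled null shares information across genes; a handful of genes with
  pathological count distributions could in principle distort the trend
  floor, though the binned median is robust to ~50% contamination per bin.
* With two replicates per condition the mixed-assignment pool is small
  (4 of 6 splits), so pooled p-values are coarser; three or more replicates
  are recommended.
* The high/low mark call inherits the quantile anchor's dependence on the
  marked fraction: if far more than 5% of genes are truly marked, the
  anchor sits inside the marked distribution (intended); if fewer, the
  anchor falls in the background and the call degrades.
* Mendelian expectations ignore viability selection between conception and
  genotyping; observed fractions in a lethal-phenotype cross will sit below
  them.
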