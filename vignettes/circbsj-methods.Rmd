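---
title: "Methods: characterizing circRNA back-splice junctions with circbsj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing circRNA back-splice junctions with circbsj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circbsj)
```

# Scope and data model

`circbsj` starts where a junction-level circRNA caller stops: one table of
back-splice junctions per sample, a genome FASTA, and a GFF3 gene
annotation. A junction is identified as `Chr<k>:<start>|<end>` with
**1-based inclusive** coordinates on both ends; that convention is used
internally everywhere, and BED-like inputs (junction tables, MITE
intervals) are converted at the I/O boundary. Strand is kept as reported
(`+`, `-`, or `unknown`) and never silently coerced: back-splice callers
frequently cannot orient a junction, and none of the downstream analyses
here require an orientation (splice signals are deliberately read
strand-naively, see below).

Unanchored scaffolds can be merged into a single `ChrUn` pseudo-chromosome
(`merge_unanchored()`). The spacer between scaffolds defaults to 100 `N`
bases — long enough that no dinucleotide or flank-window computation can
silently bridge two scaffolds — and the flank scanner truncates windows at
runs of five or more `N`s for the same reason. The scaffold map (offset,
length per scaffold) makes the lift exactly invertible, which the test
suite asserts.

# Abundance: SRPBM

Junction reads are normalized to spliced reads per billion mapped bases,

$$\mathrm{SRPBM} = \frac{\text{junction reads}}
{(\text{mapped reads}/10^9)\cdot \text{read length}},$$

which is linear in the count and zero exactly when the count is zero.
Replicate handling is deliberately simple: SRPBM is computed per sample,
and all per-condition quantities use the mean over replicates. The
circRNA-versus-parent-gene correlation is Pearson's *r* on
`log2(mean + 1)` of both abundances; because published reports are
ambiguous about whether tissues were pooled for such correlations, both a
pooled mode and per-tissue groups are exposed
(`correlate_with_parents(sample_groups = ...)`). Gene abundances are an
input, not something this package estimates from reads.

# Origin and architecture calls

Gene annotations give no unique answer to "where does a circle come from",
so the package fixes a deterministic precedence:

1. **exonic** if both back-splice coordinates fall inside exon intervals
   of one and the same gene;
2. otherwise **intronic** if the whole span lies inside a single intron of
   one gene;
3. otherwise **intergenic** (including spans that cross gene boundaries).

Ties between overlapping or nested candidate genes go to the gene whose
exons overlap the span most, then to the lexicographically smallest gene
id, so the call never depends on annotation row order. "First" and "last"
exon positions are biological, not genomic: exon 1 is the 5'-most exon of
the gene, which is genomically last on minus-strand genes; the test suite
checks that flipping every strand swaps first and last counts while
leaving middle counts unchanged.

Lengths are reported as the spliced length (sum of circularized exon
segments) where exon structure is known, and as the genomic span
`end - start + 1` for intronic and intergenic circles; the length
histogram bins at 200 nt by default, the resolution at which such
distributions are conventionally drawn.

# Alternative circularization

No standard defines a "locus" for back-splicing isoforms. Here genic
circles group by parent gene and intergenic circles by connected
components of span overlap (at least 1 bp, same chromosome), which makes
every circle a member of exactly one locus and reduces to the intuitive
"isoforms of one gene" in the genic case. A locus is *alternative* when it
has two or more members. The dominant isoform is the member whose mean
SRPBM over all samples is at least twofold that of **every** sibling —
exactly twofold qualifies, a zero-expression sibling is always dominated,
and an all-zero locus has no dominant isoform. At most one member can
satisfy the rule.

# Splice signals

The donor dinucleotide is read on the plus strand immediately 3' of the
junction end, the acceptor immediately 5' of the start; the pair is
labelled `donor/acceptor`. GT/AG and its reverse-strand mirror CT/AC are
both counted as canonical, and no strand inference is attempted — this
matches how back-splice signal spectra are conventionally reported, with
CT/AC, CT/AT and similar labels listed as such rather than
strand-resolved. Positions outside the chromosome degrade to `N`, which is
never canonical and is excluded from the position-frequency-matrix
denominator. The canonical percentage is reported at one decimal (the
field's convention); all other percentages at two.

# Flanking reverse-complement search

The search reports all **maximal exact ungapped** matches in which a
substring of the upstream window equals the reverse complement of a
substring of the downstream window, with length at least `min_len`
(default 18 bp in 1000-bp windows; a discussion threshold of "longer than
17 bp" is the same rule). Maximal means non-extendable at either end while
preserving equality — the definition under which a brute-force scan over
all substring pairs gives the identical match set, which the suite
verifies on 100 random fixtures at `min_len` 4, 10 and 18. Implementation
is seed-and-extend over a k-mer index of the reverse-complemented
downstream window with `k = min(min_len, 12)` and per-diagonal
deduplication; `N` matches nothing, including another `N`. Near-matches
with mismatches or gaps are out of scope: the biological question is
whether perfect pairing potential of a stated length exists, and an exact
rule keeps the statistic reproducible.

MITE (miniature inverted-repeat transposable element) evidence is
consumed as precomputed intervals (BED); a circle is flagged only when its
upstream **and** downstream windows each overlap at least one interval.

# Differential expression

The DE stage is a documented stand-in for empirical-Bayes NB modelling:
junction counts are pooled over the replicates of each condition and the
two pooled counts are compared against the pooled library sizes with the
conditional exact binomial test (the standard exact comparison of two
rates). Fold changes are
`log2((mean SRPBM treated + c)/(mean SRPBM control + c))` with
pseudocount `c = 0.01` SRPBM so zero counts stay finite, and calls use the
conventional rule: `up` iff `log2FC > 1` (strict) and BH FDR `<= 0.05`
(non-strict). Externally computed p-values (e.g. from an NB package) can
be substituted by passing any table with `circ_id`, `log2fc`, `p_value`
to `de_call()`.

The pooling has a known consequence that the package states rather than
hides: replicate variation is treated as Poisson, so p-values are
calibrated (conservative, in fact, by discreteness) when biological
variability is shallow, and anticonservative under strong overdispersion.
The acceptance script measures this directly on a 500-circRNA benchmark
(20% DE at 4-fold, NB dispersion 0.2, i.e. var = mu + 0.2 mu^2, two
replicates per condition): the pooled caller reaches a sensitivity around
0.6–0.75 with an empirical FDR around 0.33–0.43, depending on seed. No
test can do much better under those conditions — with dispersion 0.2 and
two replicates the standard error of log2FC is at least
`sqrt(0.2)/ln 2 = 0.645` even at infinite depth, so a true 4-fold effect
sits near z = 3.1 while FDR control over 400 null features demands a
threshold near 2.8 sigma, capping sensitivity near 0.6 for *any*
replicate-aware procedure. The operating point is therefore reported as a
measured property of the method, and studies needing calibrated error
control under strong overdispersion should drop in NB-model p-values.

The global abundance-shift comparison is a two-sided Wilcoxon rank-sum
test on per-circle `log2(SRPBM + 1)` values; the exact distribution is
enumerated when the combined sample size is at most 20 and tie-free,
otherwise the normal approximation with continuity correction is used
(the two branches agree within 0.01 at n = m = 10, asserted in the
suite).

# Enrichment

Term enrichment is the classic one-term-at-a-time upper-tail
hypergeometric test with BH adjustment, over the background of all parent
genes of detected circRNAs in the analysed tissue — the only defensible
universe when the gene sets of interest are themselves parent genes of
detected circles. Term-graph decorrelation (elim/weight-style) is
deliberately not attempted; terms are treated independently, and the
results table carries `k, K, n, N` so any downstream correction can be
reproduced.

# miRNA target scoring

Because plant target predictors share a penalty convention rather than a
formal standard, the scheme is fixed explicitly so results are
reproducible without external tools: penalties per miRNA position from
the 5' end — mismatch 1.0, G:U wobble 0.5, gap 2.0 — doubled at positions
2–13, perfect complement 0, site reported when the total is at most 4.
Scanning slides a window of the miRNA's length along the target and keeps
non-overlapping local minima, best score first. Circle sequences are the
back-splice-joined sequence (spliced exons for exonic circles, genomic
span otherwise) with the first `miRNA length - 1` nucleotides appended
once so junction-spanning sites are visible to a linear scanner; wrapping
can be disabled. One asymmetry is intrinsic and worth stating: because
the seed-proximal doubling is anchored at the miRNA 5' end and G:U
complements to A:C, the *score* is not invariant under
reverse-complementing both sequences — only the Watson–Crick pair
structure is, which is what the suite asserts.

# The synthetic data generator

`simulate_circ_dataset()` emulates the statistical structure the analysis
assumes, not sequencing itself. Background sequence is i.i.d. uniform
ACGT, so sequence-level truth is unambiguous: boundary dinucleotides are
overwritten after placement (signal truth exact by construction), and
inverted repeats exist only where planted. Planted-flank circles sit in
dedicated intergenic zones with at least a full flank window of clearance
from every other circle's windows, so flank precision and recall against
truth are exactly 100% at the configured window. Subset sizes (origin
mix, canonical fraction, planted flanks, MITEs, DE fraction) are exact
quotas, `round(fraction * n)`; which circles land in each subset is
random under the seed. Junction counts are negative binomial with
`var = mu + dispersion * mu^2`, means scaled by each library's depth, with
tissue-specific expression patterns (defaults: 70% root-only, 13%
leaf-only, 17% shared, echoing the strong root bias of tissue-specific
circRNA surveys) and salt-induced fold changes applied to the stress
condition. Default baseline means are lognormal with median 8 junction
reads at 5x10^7 mapped reads — the order of magnitude implied by typical
published per-sample junction totals (about 150,000 junction reads over
about 2,800 circles in 8 libraries). Library sizes are lognormal around
5x10^7 mapped reads; read length 150 bp.

What the generator does **not** emulate — realistic repeat landscapes,
GC structure, codon-aware genes, read-level errors, caller artefacts —
bounds what passing tests show: they validate the algorithms against
unambiguous truth, not the upstream caller, and real genomes will contain
incidental complementary flanks that are genuine sequence features rather
than false positives of the search.

Fixture sizes were chosen to keep the full suite around a minute and a
half on one core: `tiny` (12 circles) for end-to-end wiring, `paper_mix`
(500 circles at the default mixes) for recovery checks, `de_bench` (500
circles, one tissue) for the DE operating point, and `null_de` for null
behaviour. Each fixture's seed is part of its definition.

# Numerical and degenerate-input choices

* Percentages: `round(100 k/n, 2)`, canonical splice percentage at 1
  decimal; report percentages always recompute from the same row's
  integers (self-checked at run time).
* Empty inputs return empty, correctly-typed tables; an empty cohort
  summary has zero totals and no percentages.
* Windows clamp at chromosome edges; a circle starting at position 1 has
  an empty upstream window and can never have complementary flanks or an
  upstream MITE.
* `N`-containing dinucleotides count under `Others` and never as
  canonical.
* BH adjustment never decreases a p-value and preserves rank order; note
  it is not idempotent (re-adjusting adjusted values changes them), which
  is a property of the step-up definition, not an implementation detail.
* All randomness flows from a single configuration seed; the pipeline
  itself draws no random numbers, and rerunning it on identical inputs
  produces byte-identical output files.

# Known limitations

* Origin precedence resolves every junction deterministically but cannot
  recover caller-internal evidence; a junction whose ends fall in exons
  of two *different* genes is intergenic here.
* The pooled DE test's error control degrades with overdispersion, as
  quantified above.
* Enrichment ignores the term graph; strongly nested term sets will
  co-enrich.
* The target scanner is ungapped within a window except for
  length-difference bulges, and scores only complementarity — no
  accessibility or conservation evidence.
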