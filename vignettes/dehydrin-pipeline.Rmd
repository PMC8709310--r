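---
title: "Dehydrin family analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dehydrin family analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhnkit)
```

`dhnkit` analyzes dehydrin (group-2 LEA) gene families: it identifies
dehydrins from their conserved segments, assigns architectures, computes
biochemical descriptors, calls gene duplications, clusters multi-ecotype
panels, scans promoters for cis-regulatory elements, tests drought
expression and trait responses, classifies climate niches and measures
phylogenetic signal. This vignette explains the models behind each stage,
the parameters that matter, and the choices made where the underlying
procedures were genuinely open.

## Segment model and the dehydrin rule

Each conserved segment is a short consensus: K `EKKGIMDKIKEKLPG` (15 aa),
Y `VDEYGNP` (7 aa), ϕ `EDDGQGR` (7 aa), F `DRGLFDKFIGKK` (12 aa),
NLS `KKDKKKKKEKK` (11 aa); the S-segment is a run pattern (five or more
consecutive serines). Matching is **ungapped Hamming distance over a
sliding window of the query length**. The family rule admits up to
`max_mismatch = 4` mismatches; with 7–15-mer queries this deterministic
matching is reproducible and can be checked exactly against brute-force
window enumeration (which the test suite does), whereas a heuristic
gapped search cannot.

Overlapping candidate windows are resolved greedily — lowest mismatch
count first, then leftmost, then segment type — which is deterministic
and independent of scan order. `X` is tolerated in input and always
counts as a mismatch. Coordinates are 0-based, half-open throughout.

Two open points were settled as follows:

* **K\* tier.** HIRD11-type dehydrins are architecturally K\*-bearing yet
  fail the 4-mismatch rule. The scanner therefore reports a relaxed tier
  (5–8 mismatches to the K query, `relaxed = TRUE`, bound configurable via
  `dhn_consensus(k_relaxed_max=)`). In `strict` mode such proteins are not
  dehydrins; in `extended` mode a K\* hit co-occurring with an S-run or NLS
  qualifies.
* **S-runs and mismatches.** The run pattern is treated as exact
  (`S{5,}`); a "mismatch" inside a homopolymer run has no natural
  definition.

Architecture strings list segments in positional order, collapsing
consecutive repeats (`K,K` → `K2`); NLS joins what follows with a hyphen
(`NLS-K*S`). When two printed token orders disagree for one protein, the
canonical output follows hit positions.

## Biochemical descriptors

Molecular weight uses the ProtParam convention of average (not
monoisotopic) residue masses plus one water. GRAVY is the mean
Kyte–Doolittle index, so it is composition-only. The isoelectric point is
the unique zero of the Henderson–Hasselbalch net charge (N/C termini plus
D, E, C, Y, H, K, R side chains) found by bisection to |charge| < 1e-4;
the pKa set is the EMBOSS default table, stored as a named, swappable
constant (`PKA_EMBOSS`) because published tools differ in their exact
Bjellqvist variant. The instability index is the Guruprasad dipeptide
score `(10/L) Σ DIWV(x_i, x_{i+1})` with the published 20×20 weight
table embedded. A structural property of the family falls out of the
segment composition: every protein built purely from the consensus
segments has negative GRAVY (dehydrins are hydrophilic), which the tests
assert across all reference layouts.

## Duplication calling

A homologous pair is two loci of the same family, or of families declared
homologous in the configuration (defaults: Bdhn1–Bdhn2, Bdhn4–Bdhn5,
Bdhn7–Bdhn8). Within one genome, a pair is **tandem** when both loci share
a chromosome and the intergenic gap (end of the upstream gene to start of
the downstream gene — the natural reading of "sequence distance") is at
most 50 kb, boundary inclusive; it is **segmental** otherwise. Segmental
is thus defined negatively — any non-tandem homologous pair — inferred
from the family's cross-chromosome exemplars. Calls collapse to one
event per (pair, kind) within a genome group; the same pair in different
groups stays distinct, which is how the packaged five-genome layout
yields four tandem plus two segmental events.

## Ecotype clustering at 95% identity

Similarity is the fraction of identical aligned positions over the full
global BLOSUM62 alignment (gap open 11, extend 1), gap columns included —
"95% similarity" is read as identity, with the score-based alternative a
one-line switch. Clustering is greedy centroid: sequences in descending
length order (ties by id) join the first cluster whose *founding member*
they match at ≥ 95%, else found a new cluster; clusters under 3 members
dissolve, and a rescue pass re-compares the unplaced against surviving
representatives. Sequences matching two representatives within one
percentage point are flagged `ambiguous` rather than resolved silently,
mirroring the manual curation such cases receive in practice.

A quantitative caveat documented here because it shapes what the tests
can assert: when copies carry an independent 2% substitution load, two
copies of one gene lie ~3.9% apart in expectation, so copy-to-centroid
identity straddles the 95% threshold (for a 200-aa protein the binomial
tail gives roughly a one-in-five chance per comparison of falling below
it). The procedure then recovers every gene as a pure primary cluster but
also produces occasional splinter clusters and leaves ~15% of copies
unclassified. The tests therefore assert exact partition recovery at
divergence 0 and, at 2% divergence, purity, full gene coverage and a
classified fraction ≥ 75% — the quantities that are stable properties of
the procedure rather than of a particular random draw.

## Promoter windows and PWM scanning

Promoter windows run from 500 bp upstream to 200 bp downstream of the
TSS; minus-strand windows are reverse-complemented so positions read
5′→3′ relative to the gene, and windows truncate with a warning at contig
edges. A PWM is stored as column-normalized probabilities with
pseudocount 0.01; every offset on both strands scores
`Σ log2(p_base/bg_base)` and hits must reach the bit-score threshold.
The default threshold of 9 bits follows the source procedure's cutoff;
since the original tool's exact score semantics are not recoverable, the
value is a plain configurable cutoff here. Planted consensus sites score
the column-maximum sum, so any threshold below that recovers them with
100% recall; sharp short motifs can also admit near-consensus background
windows, which affects precision but not recall.

## Expression statistics

Rank-sum tests run per gene between contrast groups (`"W-D"` pooled,
`"C-H"`, or explicit cells like `"CW-HW"`); the test is exact by full
enumeration when both groups have ≤ 8 samples and no ties, with the
tie-corrected normal approximation otherwise, and all-tied degenerate
groups return p = 1. BH adjustment spans all genes and contrasts of one
call — one family, conservative and stated. Rank tests use raw TPM
(ranks are transform-invariant); correlations use `log(TPM+1)` ecotype
means. Percent change is computed per ecotype as
`(mean_D − mean_W)/mean_W × 100` and averaged unweighted across ecotypes
("on average" read as the unweighted ecotype mean). Kruskal–Wallis tests
ecotype differences within each treatment, and Tukey HSD pairwise
p-values are summarized as a compact letter display via insert-absorb.

## Traits and climate

Trait change summaries use the paired Wilcoxon signed-rank test with the
watered mean as denominator; the ecotype is the unit of analysis, so
replicates are averaged before regression. Trait-on-expression
regressions are ordinary least squares on the raw expression scale by
default (log is a switch). The climate classifier standardizes the 19
variables, eigendecomposes their correlation matrix and anchors the PC1
sign so that the negated coldest-quarter temperature loads positively;
scores above +2.5 are `cold`, below −2.5 `warm`, `mesic` between. The
printed source for these cutoffs contains a sign typo (warm listed as
"<2.5" against a mesic band of −2.5..2.5); it is resolved as warm < −2.5.

## Phylogenetic signal

Blomberg's K is the observed MSE₀/MSE ratio (deviations from the GLS
phylogenetic mean, unweighted vs C⁻¹-weighted) divided by its Brownian
expectation `(tr(C) − n/1'C⁻¹1)/(n−1)`, computed analytically. The
p-value is a tip-label permutation test (default 999 permutations,
add-one smoothing, so p is never exactly zero) with an explicit seed —
reproducible bit-exact. Pagel's λ scales the off-diagonal of C and is
estimated by bounded scalar likelihood maximization (tolerance 1e-8) with
the Brownian rate profiled out; the upper bound is the largest λ keeping
C positive-definite, capped at 1.1, and endpoints are evaluated
explicitly so boundary optima are exact. Significance is a χ²₁
likelihood-ratio test against λ = 0, whose likelihood reduces to the
closed-form independent-normals limit (a unit-tested identity). Both
statistics are validated against independent dense-algebra oracles and
against established implementations (`picante::Kcalc`,
`phytools::phylosig`) used strictly as cross-checks.

## The synthetic-data generator

The generator emulates the study's data-generating conditions with known
truth:

* **Proteins**: consensus segments concatenated per architecture, joined
  by low-complexity linkers over `{G,E,T,H,Q,A}` (small/polar,
  dehydrin-like, and mostly disjoint from the consensus queries). Because
  a random 7-mer linker can still imitate a short query within 4
  mismatches, linkers are redrawn (deterministically under the seed)
  until the zero-mutation assembly scans back to exactly the planted
  spans; the mutation load is applied afterwards. K\* renders the K
  consensus with exactly 6 substitutions — beyond the 4-mismatch rule,
  inside the relaxed tier. The reference layout carries the family's
  eleven proteins covering its eight architectures with YSϕK2 on four
  genes; the gene-by-gene assignment of the remaining architectures is a
  synthetic reconstruction consistent with the published per-gene
  structure classes, and is labelled as such in its documentation.
* **Loci**: planted tandem pairs (same chromosome, configurable gap ≤ 50
  kb) and segmental pairs (distinct chromosomes) plus singleton decoys.
* **Expression**: TPM is log-normal around `baseline` (watered) or
  `baseline × (1+θ)` (dry). Default effects are the study's printed
  values — θ = 0.0574, 0.39, 0.678, 0.978 for the four expressed genes —
  at 32 ecotypes × 4 replicates per watering level, replicate noise sd
  0.2 on the log scale, baseline 100 TPM (a typical constitutive
  dehydrin level). The percent-change estimator applied to one such
  experiment has expectation ≈ 99.8 for θ = 0.978 (a +2-point
  small-sample ratio bias from the 4-replicate watered mean in the
  denominator) and a cross-experiment sd of ≈ 5 points; the acceptance
  test therefore averages 20 replicate experiments under one master
  seed, which is the scale at which the recovered mean is a stable
  quantity.
* **Traits**: linear in mean dehydrin expression with per-trait slopes
  whose default signs follow the observed association pattern (positive
  pro, blwgrd, rmr, WUE, leafc, cn; negative leaf_rwc, leaf_wc, leafn),
  Gaussian noise; a separate generator plants paired W/D percent effects
  directly for change-summary testing.
* **Trees and traits**: Yule (pure-birth) topology, branch lengths iid
  Exp(1), tip traits multivariate normal with the λ-transformed
  shared-path covariance — λ = 1 is exactly Brownian motion, λ = 0 gives
  independent tips.
* **Climate**: 19 variables linear in one latent coldness gradient
  (temperature variables negatively, precipitation positively), so with
  zero noise the table is rank one and PC1 carries all variance.

What the generator does **not** emulate: real sequence content beyond
segment composition (no codon structure, no indels, no paralog-specific
rate variation), read-level noise (TPM is simulated directly, not
quantified from reads), trait nonlinearity, or spatial structure in the
climate variables. Passing tests therefore demonstrate that the
algorithms recover what was planted under the stated noise models — not
that the biological conclusions would survive, say, assembly artifacts or
quantification bias in real data.

## Problem sizes, determinism and degenerate inputs

The test suite runs the clustering criterion at the full 10-gene × 54
ecotype panel, the K calibration at 200 Brownian simulations of 15-tip
trees and the λ recovery at 60 simulations of 30-tip trees; these sizes
give standard errors well inside the asserted bands while keeping the
suite under a minute. Every stochastic component takes an explicit seed
(`withr::with_seed`), so identical seeds give byte-identical outputs —
`run_pipeline()` reruns reproduce every TSV exactly, and the run manifest
records the configuration hash and seed. Degenerate inputs have defined
behavior: empty sequences error, sequences shorter than a query yield
zero hits (not an error), all-tied expression groups give p = 1,
zero-variance genes are flagged rather than propagating NaN, constant
climate columns are dropped with a warning, and promoter windows
truncate with a warning at contig edges.

## Known limitations

* The segment scanner is exact-Hamming; genuinely gapped segment variants
  (insertions inside a K-segment) are found only through the relaxed tier
  or not at all.
* Tukey HSD operates on group means under normal-theory assumptions while
  the omnibus test is rank-based — a pragmatic mixed design carried over
  from the source procedure.
* The duplication caller trusts the input family labels; it performs no
  sequence-level homology detection of its own.
* Pagel's λ uses a scalar profile likelihood; no measurement-error or
  within-species variance extensions.
* The PWM threshold is a plain bit-score cutoff; no p-value calibration
  against a background model.
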