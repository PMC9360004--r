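---
title: "Methods: threshold classification of transcriptome and translatome reprogramming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold classification of transcriptome and translatome reprogramming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translatome)
```

## The measurement model

The pipeline consumes paired count tables from two assays over the same
transcript universe: mRNA-seq (transcript abundance) and Ribo-seq
(ribosome-protected footprints, a snapshot of translation). The design it
targets is a three-point stress time course — an unstressed control
(`CON`), an acute stress point (`CPA1`) and a chronic stress point
(`CPA18`) — with independent replicate cultures per condition and assay
(three by default).

Counts are normalized to **RPKM**,

$$\mathrm{RPKM}_{t,s} \;=\; \frac{c_{t,s}}{(L_t/10^{3})\,(N_s/10^{6})},$$

with $c_{t,s}$ the raw count of transcript $t$ in sample $s$, $L_t$ the
transcript length in nucleotides and $N_s$ the column total of the input
table. Totals are computed on the table *as given* — before any
filtering — so RPKM is exactly linear in a sample's counts and invariant
to sequencing depth.

**Ribosome occupancy** of a transcript in a condition is

$$\mathrm{occ}(t, c) \;=\;
\frac{\overline{\mathrm{RPKM}}^{\,\mathrm{ribo}}_{t,c}}
     {\overline{\mathrm{RPKM}}^{\,\mathrm{mrna}}_{t,c}},$$

the ratio of replicate means. It is the package's proxy for translation
efficiency: a transcript whose footprint signal rises faster than its
abundance is being translationally activated. Because occupancy is built
from RPKM it is invariant to a change of sequencing depth in either
assay; the test suite asserts this directly by rescaling all Ribo-seq
counts and comparing.

A transcript enters the analysis only if it passes the **detection
filter**: RPKM > 0 (at least one aligned read) in *every* replicate of
*every* condition in *both* assays. A transcript present in 17 of 18
samples is excluded. This strict rule is what guarantees that every
downstream log-ratio is finite without pseudocounts; the package uses no
pseudocounts anywhere.

## Contrasts and classification rules

All differential expression is **L2DE**, the log2 ratio of replicate-mean
RPKM between two conditions. Three contrasts are formed: *acute*
(`CPA1/CON`), *chronic* (`CPA18/CPA1`) and *overall* (`CPA18/CON`). For
each contrast the pipeline records $x$ (mRNA L2DE), $y$ (footprint L2DE)
and the occupancy L2DE; with RPKM-based occupancy the identity
$\mathrm{occ\_l2de} = y - x$ holds algebraically and is asserted to
$10^{-9}$ in the tests.

### Temporal groups G1–G12

Each transcript gets an abundance group from its acute and chronic
abundance L2DEs against a symmetric cutoff $c = 0.32$ (about a 25%
change; $2^{0.32} \approx 1.25$):

| group | acute | chronic | overall |
|---|---|---|---|
| G1 | up | up | — |
| G2 | up | down | — |
| G3 | no change | up | up |
| G4 | down | down | — |
| G5 | down | up | — |
| G6 | no change | down | down |

"Up" and "down" are inclusive ($\geq c$, $\leq -c$); "no change" is
strict ($|{\cdot}| < c$). The same geometry applied to occupancy L2DEs
yields G7–G12, in the conventional code order **G7** up/up, **G8**
up/down, **G9** none/up, **G10** none/down, **G11** down/up, **G12**
down/down — note this ordering differs from the abundance codes. The six
rules are mutually exclusive by construction; the suite asserts at most
one rule fires anywhere on a dense grid, and that the vectorized
classifier agrees with an independently coded scalar evaluator on $10^6$
random triples.

Transcripts failing every rule are reported as `none`, never silently
dropped, so the per-group marginal counts always sum to the detected
universe.

### Regulation modes

For a single contrast, the joint behaviour of $x$ and $y$ is classified
with a band of half-width $0.6$ ($2^{0.6} \approx 1.52$, at least a 50%
change) around the diagonal:

* `up_both`: $-0.6 \leq x - y < 0.6$, $x \geq 0.6$, $y \geq 0.6$;
* `up_occ_only`: $x - y < -0.6$, $y > 0.6$;
* `down_both`: $-0.6 \leq x - y < 0.6$, $x \leq -0.6$, $y \leq -0.6$;
* `down_occ_only`: $x - y > 0.6$, $y < -0.6$.

The band on $x - y$ is half-open: $x - y = -0.6$ lies inside it,
$x - y = 0.6$ outside. These boundary conventions are fixed once, stated
in the function documentation, and pinned by boundary-value tests.

No p-values enter group membership: the scheme is purely threshold-based
on replicate means, which is exactly what makes it reproducible from
count tables alone. Users wanting inferential calls should run a
moderated-statistics tool alongside; see *Limitations*.

## Gene-set derivations

**Cell-specific set (regulome construction).** Starting from per-gene
change calls in the target cell type (direction × channel × contrast),
every gene that changed *in the same direction* in a reference cell type
— in any channel — is excluded; opposite-direction genes are retained.
The derivation is monotone (a larger reference never yields a larger
set), which the suite checks property-style. "Changed" defaults to the
analysis cutoff of 0.6 in either abundance or occupancy; the threshold is
a parameter because the exact recipe is a policy, not a law, and the
output records its provenance (excluded genes, thresholds) for audit.

**Adaptome.** For a pathway $P$ (e.g. ER protein processing), the
adaptome is $(\mathrm{up}_{\mathrm{abundance}} \cup
\mathrm{up}_{\mathrm{occupancy}}) \cap P$, with each member flagged by
whether the reference cell type also regulated it; the unflagged part is
the cell-type-specific adaptome.

**Over-representation** uses the one-sided upper-tail hypergeometric test
($p = P(X \geq \mathrm{overlap})$ with the pathway intersected with the
universe first), delegated to `stats::phyper` and cross-checked in the
tests against exhaustive subset enumeration for universes up to 12 genes.
Pathway membership always comes from user-supplied GMT files; the package
never calls an annotation web service, and the shipped pathway fixture is
synthetic (generated, labelled as such).

**Cohort comparisons** (e.g. disease vs control expression of a derived
set) use the two-sided Wilcoxon–Mann–Whitney test per gene — exact when
both groups have ≤ 20 samples and no ties, normal approximation with tie
correction otherwise — with Benjamini–Hochberg adjustment across the
tested set and a deliberately stringent default cutoff of FDR ≤ $10^{-3}$.
BH flags are compared against a hand-coded step-up reference in the
tests. Genes absent from the expression table are reported as untested
rather than erroring, since derived sets routinely contain genes not
measured on a given platform.

## Ribo-seq quality control

Footprints are reduced to `(transcript, 5' position, length)` records.
Frame statistics offset each 5' end by the **P-site offset** (default
+12 nt, the standard for ~28-nt footprints; a parameter, optionally a
function of read length, because the offset is a property of the library
protocol) and keep reads whose P site falls in `[cds_start, cds_end)`.
The frame is $(p - \mathrm{cds\_start}) \bmod 3$; genuine elongating
ribosomes concentrate in frame 0, while RNA background is flat at 1/3.
Reads on transcripts without CDS annotation are excluded and counted in
the report, not silently lost. CDS enrichment compares the fraction of
Ribo-seq P sites inside the CDS with the fraction of mRNA-seq 5' ends
there; for uniform mRNA coverage the expected ratio approaches
transcript length over CDS length.

Coordinates are transcript-local, 0-based, half-open throughout. The
aligner upstream maps to a transcriptome reference, so genomic strand
never arises in this package by design.

## The synthetic-data generator

`simulate_experiment()` emulates the *structure* of the target study —
10,000 transcripts by default, 3 conditions × 3 replicates × 2 assays,
negative-binomial counts with variance $\mu + \alpha\mu^2$ (default
$\alpha = 0.05$ per assay, a typical biological-replicate dispersion for
cell-line RNA-seq), planted temporal classes for abundance and occupancy,
and footprint records with a planted frame-0 fraction. Default class
proportions put roughly 20% of transcripts in a planted class per
channel, concentrated in the chronic phase for abundance and in the acute
phase for occupancy, mirroring the qualitative shape of chronic-stress
reprogramming. All randomness flows from one integer seed through a
hash-based stream splitter (`split_seed`), so stages are independently
reproducible.

Two design points matter for interpreting the tests:

* **Margin-separated effects.** Planted effect magnitudes are drawn
  uniformly on [0.9, 1.2] log2 units and rejection-sampled until *every*
  derived planted quantity — acute/chronic/overall L2DE per channel, and
  $x$, $y$, $x - y$ per contrast — keeps at least 0.3 from the 0.32 and
  0.6 boundaries. No transcript is planted "on the fence", so at
  dispersion 0 the classification of every transcript is determined and
  recovery must be exactly 100% (which the acceptance suite asserts).
* **Count floor.** RPKM is not compositionally robust: planting changes
  shifts library composition and biases all log-ratios slightly. Baseline
  expression is floored at 10 RPKM, combined planted log2 change is
  bounded below at −2.8 per condition (class pairs that cannot satisfy
  this, i.e. strong joint down-regulation of abundance and occupancy, are
  not co-planted), and planted proportions are kept small and roughly
  direction-balanced, so the residual compositional bias plus integer
  rounding stays well inside the 0.3 margin.

What the generator does *not* emulate: sequence content and mappability,
positional coverage bias, correlated dispersion between assays,
transcript-isoform ambiguity, batch effects. Passing tests therefore
demonstrate correctness of the *computations* under a clean generative
model, not robustness of the thresholds to every real-data pathology.

With NB noise at the default $\alpha = 0.05$ and 3 replicates, the
standard deviation of an estimated L2DE is comparable to the width of the
±0.32 "no change" band, so planted `none_up`/`none_down` classes leak
into neighbouring groups at an appreciable rate. The regression test
freezes the recovery achieved by the fixed fixture (2,000 transcripts,
dispersion 0.05, seed 7) and guards against regressions from that value,
rather than asserting an aspirational accuracy; the acceptance script
reports the same recoveries at the 10,000-transcript scale.

## Open design choices

Several points are underdetermined by the analysis description; the
package fixes them explicitly and exposes each as a parameter:

* **Occupancy basis.** Occupancy is defined on mean RPKM (it is a
  normalized quantity); `basis = "raw"` preserves the literal
  ratio-of-mean-counts reading. With equal transcript length the two
  differ only by depth factors.
* **L2DE as a ratio.** The log2 *ratio* reading is adopted (a log2 of a
  difference is not scale-free and contradicts the stated equivalence of
  0.6 log2 units with a ≥50% RPKM difference).
* **`mode_y`.** The regulation-mode rules are stated in terms of the
  footprint L2DE $y$; `mode_y = "occupancy"` substitutes the occupancy
  L2DE for sensitivity analysis.
* **G7–G12 cutoff.** The occupancy grouping reuses the abundance cutoff
  0.32; it is a separate parameter should users want to decouple them.
* **Gene-level summaries.** Classification is transcript-level. Where a
  gene-level universe is needed (enrichment), each gene is represented by
  its transcript with the highest mean control mRNA RPKM, ties broken by
  input order — a policy, recorded in the outputs, not a fact about the
  data.

## Degenerate inputs and numerical conventions

Zero-total samples, non-positive values passed to `l2de()`, transcripts
with zero mRNA mean requested for occupancy, contrasts naming unknown
conditions, and hit lists outside the universe are hard errors naming the
offending record. Empty footprint sets after CDS filtering yield a
flagged `NA` distribution, and a missing mRNA denominator in CDS
enrichment yields a flagged `NA` ratio — both are QC outcomes, not
crashes. Frame fractions satisfy $f_0 + f_1 + f_2 = 1$ exactly by
construction (tabulation of a partition). Pipeline outputs are plain TSV
with `# key=value` provenance headers; re-running a config reproduces
byte-identical tables, which the suite checks by hashing.

## Problem sizes in the shipped tests

The suite favours many small, fully checked cases: unit fixtures of 1–30
transcripts with hand-computable totals; property grids of ~8×10⁵ points;
10⁶ random triples against the naive rule evaluator; synthetic
experiments of 120–2,000 transcripts (noise-free and NB); cohorts of up
to 100 samples; 10⁴ footprints for frame recovery. The acceptance script
runs the classification recovery at the full 10,000-transcript scale.

## Limitations

* The threshold scheme has no error control on group membership; near
  the 0.32 cutoff, group counts are noise-sensitive (quantified above).
  It reproduces the bespoke analysis faithfully rather than improving on
  it — pairing with DESeq2/limma-style inference is deliberately out of
  scope.
* RPKM totals make all L2DEs mildly compositional; strongly asymmetric
  global shifts would bias the "no change" band.
* Upstream alignment, read filtering and multi-mapping policy are out of
  scope: counts are taken as given and must be integers.
* The P-site offset is not learned from the data; supply a
  length-stratified offset function if your protocol needs one.
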