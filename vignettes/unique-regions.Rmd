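---
title: "Detecting and annotating unique genomic regions with urscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and annotating unique genomic regions with urscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urscan)
```

## The statistic

Repeats — transposons, satellites, segmental duplications — leave a
signature that needs no repeat library to read: sequence that occurs more
than once in a genome produces long exact matches against the rest of the
genome, while sequence with no close homolog produces only the short matches
expected by chance. `urscan` quantifies this with the *match complexity* of
a sliding window.

For every position $i$ of every chromosome, the *matching statistic*
$\mathrm{MS}[i]$ is the length of the longest prefix of the suffix starting
at $i$ that occurs at least once at a different position of the genome, on
the forward strand or anywhere in the reverse complement. These are maximal
matches: extending them by one residue loses the match. Each chromosome is
then greedily factorized left to right: the factor starting at $p$ spans
$\max(\mathrm{MS}[p], 1)$ positions and the next factor starts immediately
after it, so the factors tile the chromosome. For a window $w$, let $m_o$
be the number of factors whose span intersects $w$ by at least 1 bp, and
let $m_e$ be the expectation of $m_o$ on random sequence of matched length
and composition. The match complexity is

$$ C_m = \frac{m_o - 1}{m_e - 1}. $$

The subtraction of 1 in numerator and denominator pins the statistic's
range: a window spanned by a single factor — one long exact copy of
sequence found elsewhere, i.e. a perfect repeat — has $m_o = 1$ and hence
$C_m = 0$ exactly, while on random sequence the expectation of $C_m$ is 1.
Repetitive windows depress $m_o$ (few, long factors); windows
indistinguishable from random sit near 1.

Windows whose $C_m$ passes a null-quantile test are merged into *unique
regions* (URs): maximal runs of windows with no close homolog elsewhere in
the genome, filtered to a minimum length. URs are then annotated against
gene models, and the genes whose promoters (or transcripts) intersect them
are tested for GO-term enrichment by an interval-shuffling Monte Carlo
test.

## Implementation of the match index

The index concatenates every chromosome and its reverse complement, with a
unique sentinel symbol after every segment, and builds a suffix array over
the integer-coded text (SA-IS induced sorting, linear time), followed by
the LCP array (Kasai's algorithm). The matching statistic of a position is
then the larger of its LCP values with its two suffix-array neighbours.
Because every sentinel — and every `N` — is a unique symbol, no match can
extend across a chromosome boundary, a strand boundary, or an assembly gap,
and `N` matches nothing, not even another `N`: gaps must not create
artifactual repeats. The suffix array is 32-bit; genomes up to roughly 1 Gb
(2 Gb of indexed text) fit a single index.

Two readings of "maximal matches that intersect a window" are possible:
re-factorize every window from its own start, or factorize each chromosome
once and count intersecting factors. `urscan` factorizes once per
chromosome, starting at position 0. A single parse makes $m_o$ well-defined
across overlapping windows and makes window counts a pure counting query
against one factorization; this choice is recorded here because the
alternative yields slightly different $m_o$ at window boundaries.

## The null model and the uniqueness test

The closed-form expectation of $m_o$ is not used; instead the null is
calibrated by simulation, which also yields the full null distribution of
$C_m$ rather than only its mean. `calibrate_null()` draws `replicates`
(default 20) i.i.d. random sequences of the genome's total length and
global non-N base composition (one null per genome, not per chromosome),
indexes each, and collects $m_o$ over all windows. $m_e$ is the mean of
that sample, and the empirical distribution of $(m_o - 1)/(m_e - 1)$ is the
null distribution of $C_m$. Calibration uses a single sequence of the total
genome length rather than the genome's chromosome partition; for
chromosomes much longer than the window the difference in chance-match
lengths is negligible.

A window is classified *unique* iff its $C_m$ is at least the
$\alpha$-quantile of the null $C_m$ sample (empirical quantile with linear
interpolation; the comparison is inclusive at the threshold, with a
$10^{-9}$ tolerance absorbing interpolation round-off). This is a one-sided
lower test: only depressed complexity — repetitiveness — is rejected.
Consequently a *larger* $\alpha$ is a stricter uniqueness test, and on pure
random sequence the fraction of windows *not* flagged unique is
approximately $\alpha$. The default $\alpha = 0.05$ is a package default,
not a claim about any reference implementation's internals. Windows with
more than 50% `N` get a missing $C_m$ and are never unique.

Key parameters, defaults, and units:

| parameter | default | unit | role |
|---|---|---|---|
| `window` | 10000 | bp | sliding window length; headline mammalian analyses use 10 kb |
| `step` | `window/10` | bp | window stride; the stride is stated with every experiment below |
| `replicates` | 20 | — | null-calibration replicates |
| `alpha` (uniqueness) | 0.05 | — | lower-quantile level of the null $C_m$ test |
| `min_length` | 10000 | bp | minimum merged UR length ("at least 10 kb", inclusive) |
| `upstream` | 2000 | bp | promoter length upstream of each TSS |
| `iterations` | 10000 | — | Monte Carlo shuffling iterations (genome studies use $10^6$) |
| `min_genes` | 10 | genes | genome-wide filter on tested GO terms |
| `alpha_enrich` | 0.01 | — | threshold on the Bonferroni-corrected p-value |

## Annotation choices

Promoters are the 2 kb immediately upstream of each transcription start
site, strand-aware, truncated (not discarded) at chromosome edges, one per
distinct TSS per gene. "Intersect" means an overlap of at least 1 bp in
0-based half-open coordinates, so book-ended features do not intersect.
Transcript mode uses the full mRNA feature span, introns and UTRs included.
Gene identity prefers the NCBI `Dbxref` GeneID and falls back to the
feature `ID`. Every gene with a transcript feature contributes promoters,
coding or not. *Anonymous* URs intersect neither any promoter nor any
transcript; they are candidates for unannotated genes.

The gene2go table is the inner join of gene→protein (from the GFF3 CDS
features), protein→GO (an input TSV, as produced by homology-transfer
annotators), and GO id→name/namespace (from the OBO file). Annotations can
optionally be propagated to all `is_a`/`part_of` ancestors
(`propagate_gene2go()`); propagation is **off** by default since counting
tools differ on whether gene counts are per directly annotated term or per
ancestor closure, and the pipeline records which mode produced its output.

## The enrichment test

Observed counts are distinct genes per GO term among the genes whose
promoters (or transcripts) intersect the URs. Each iteration re-places
every interval uniformly across the genome — a chromosome drawn with
probability proportional to its number of valid start positions for that
interval's length, then a uniform valid start — preserving the length
multiset exactly; shuffled intervals may overlap each other and may land in
N runs, as no collision or gap avoidance is modelled. The raw p-value is
the add-one estimator $(1 + k)/(1 + n)$ with $k$ the number of iterations
whose null count reaches the observed count, so p-values are never exactly
0 and floor at $1/(n+1)$ — with $10^6$ iterations and 2,953 tests the
smallest attainable corrected p-value is below 0.003. The `min_genes`
filter is applied genome-wide (to the whole gene2go table within the tested
namespace), not to the UR gene set: the number of tests should not depend
on the outcome being tested. Bonferroni correction multiplies by the number
of tests, capped at 1; the test runs within one GO namespace at a time
(default `biological_process`). The enrichment ratio is the observed count
over the null mean, missing when the null mean is 0.

## The detection-decay experiment

How diverged can a repeat be and still depress $C_m$? The simulation
plants two identical copies of a random 3.7 kb unit into a random 25 kb
background (insertion, so the composite is 32.4 kb), mutates **each copy
independently** at the nominal per-site substitution rate (substitutions
only, uniform over the three alternative bases; no indels, and the
background is left alone — mutating i.i.d. random sequence leaves it i.i.d.
random), and scores the composite with **non-overlapping 1 kb windows**
against a null calibrated for the composite length. The *detected*
percentage is the share of copy nucleotides covered by at least one window
not classified unique; the curve's *breakpoint* is the smallest grid rate
where the mean detected percentage first falls below 50%.

Two choices deserve a note. First, the mutation regime: mutating each copy
at rate $r$ makes their pairwise divergence roughly $2r(1-r)$; the
alternative single-copy regime (only one copy mutated, so the rate equals
the expected pairwise divergence) is available as
`mutate_all_copies = FALSE`. With the default regime and the default grid
(0–0.6, step 0.05, 20 replicates per rate, $\alpha = 0.05$) the breakpoint
lands at 0.15–0.20 substitutions/site; with the single-copy regime it lands
near 0.30. Second, the stride: the experiment uses non-overlapping windows
because with a `window/10` stride every nucleotide is covered by ten
overlapping windows and a 5% per-window false-flag rate would put a ~40%
floor under the detected percentage of even random sequence, destroying the
high-rate limit of the curve.

## The synthetic fixture

`make_fixture()` builds the whole test world in a few hundred kilobases:
chromosomes assembled from 10 kb blocks, most of them concatenations of
five 500 bp library units (each unit recurring dozens of times across the
genome, so those blocks score $C_m \approx 0$), with designated blocks of
i.i.d. random sequence — the planted URs. Signal genes, all annotated to
one "developmental-like" GO term, get promoters placed inside the unique
blocks; background genes and their terms are placed uniformly. The fixture
emits FASTA, NCBI-dialect GFF3, a go-basic-style OBO, the protein→GO TSV,
and truth tables, and is byte-deterministic given its seed.

What the fixture does *not* emulate — and hence what passing end-to-end
tests do and do not show: real repeat families are nested, fragmented, and
internally diverged, not exact unit concatenations; real base composition
is heterogeneous (isochores, CpG islands) while the fixture is uniform;
real annotations have alternative transcripts, pseudogenes, and errors; and
real GO annotation is much deeper than the fixture's two-level ontology.
Passing tests demonstrate that the statistics, the interval algebra, and
the test calibration are correct, not that biological URs will be as
cleanly separable as the fixture's.

## Numerical and degenerate-input conventions

All internal coordinates are 0-based half-open, converted only at I/O
boundaries (FASTA/GFF3 1-based inclusive, BED 0-based half-open). Lowercase
residues are uppercased and anything outside `{A,C,G,T,N}` becomes `N` on
load. An all-N genome is a degenerate-input error; a chromosome shorter
than the window contributes zero profile rows (not an error); an empty
region factorizes to an empty factorization; a zero-match position is its
own length-1 factor, which guarantees tiling and termination. If the
calibrated $m_e \le 1$ the calibration aborts with an instruction to use a
larger window. Ties at the uniqueness threshold are inclusive. Fixed seeds
make every stage bit-reproducible; the pipeline derives per-stage seeds
deterministically from one global seed.

## Problem sizes used by the built-in checks

The test suite and the acceptance script calibrate the statistic's
normalization on 1 Mb random sequences (null from 20 independent 1 Mb
replicates, 10 kb windows stepped 1 kb — mean $C_m$ agrees with 1 within
Monte Carlo error), run the detection-decay experiment at its native size
(32.4 kb composites, 13 rates × 20 replicates), verify matching statistics
against a brute-force all-substring oracle on 100 random genomes of up to
200 bp, and check Monte Carlo p-values against exhaustive enumeration of
all placements of one interval on a 50 bp toy genome. These sizes are the
package's choice of a thorough-but-quick default; all of them scale up by
changing the corresponding arguments.

## Known limitations

The 32-bit suffix array caps a single index at ~2 Gb of text (genome plus
reverse complement), below full mammalian genome scale; the statistic's
null is global, not GC-stratified, so locally GC-extreme windows can be
mis-calibrated; detection is blind to repeats whose closest homolog has
diverged beyond the breakpoint, and to single-copy transposons, which are
unique by the statistic's definition; and the enrichment test conditions on
the observed UR lengths, not on their chromatin context or gene density.
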