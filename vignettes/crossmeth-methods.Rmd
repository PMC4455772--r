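---
title: "Methods: cross-species validation of Infinium 450K probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species validation of Infinium 450K probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`crossmeth` decides, probe by probe, whether a human Infinium 450K 50-mer
can be trusted to report DNA methylation in another species, and quantifies
how much trust is warranted by comparing array beta values against bisulfite
sequencing on the same samples. This vignette documents the model behind
each stage, the tunable parameters, the synthetic data the package validates
itself on, and the design choices made where the underlying procedure left
room for interpretation.

## Alignment model

Each probe is aligned to both strands of the target genome by local
alignment under blastn-style scoring: match +2, mismatch −3, and affine
gaps in which a run of length $L$ costs $g_o + L \cdot g_e$ (defaults
$g_o = 5$, $g_e = 2$). Raw scores are made comparable through the
Karlin–Altschul transform

$$ S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad
   E = m \cdot n_\mathrm{eff} \cdot 2^{-S'} $$

with $\lambda = 0.625$ nats and $K = 0.41$ (gapped parameters appropriate
for the +2/−3 scheme), $m$ the probe length and
$n_\mathrm{eff} = 2n$ the genome length counted on both strands. No
edge-length correction is applied: the naive search space is simpler and
monotone in the same direction as the corrected statistic, which is all the
downstream thresholding uses. All of these are fields of
`scoring_params()`.

Two readings exist for the e-value threshold written "e⁻¹⁰": $e^{-10}
\approx 4.54\times10^{-5}$ and $1\times10^{-10}$. The package defaults to
the literal $\exp(-10)$ — consistent with the gloss that this many matches
would be expected purely by chance, a statement that only makes sense for a
number that is not absurdly small — and accepts `evalue_max = 1e-10` for
the other reading.

### Seed-and-extend and its oracle

The production aligner (`align_probe()`) indexes the probe's 11-mers,
scans each contig with a rolling 2-bit code, and runs a banded affine-gap
Smith–Waterman (±5 diagonals) around every distinct seed diagonal. The
band comfortably contains the admissible gap structure (at most two gaps of
at most 4 bp). No X-drop termination is used: over a 50 × 11 band the full
DP is already negligible, and omitting the heuristic keeps extension exact
within the band. Overlapping candidate alignments whose diagonal ranges lie
within one band of each other collapse to the highest-scoring one; among
equal scores, ties break by (contig, start) lexicographically, which makes
every output deterministic.

`brute_force_align()` is an independent oracle: a full Smith–Waterman over
every position of the genome (guarded to ≤ 1 Mb, as it is quadratic) with
the same output contract. The test suite asserts that the two engines
return identical best hits — scores, coordinates, strand, mismatch counts
— across planted probe sets. The guarantee is conditional: a hit whose
optimal alignment contains no exact 11-mer cannot be seeded. The synthetic
generator therefore re-draws substitution positions until each planted
probe keeps a mismatch-free stretch of at least 12 bp, so on generated
cohorts the equivalence is unconditional. On real data the same
seed-sensitivity caveat applies to any word-seeded aligner.

Non-ACGT bases (IUPAC ambiguity codes in the genome) mismatch everything,
including themselves, and never seed.

## Locating and classifying the CpG

The Infinium chemistries anchor the assayed CpG differently: a type I probe
covers the CpG cytosine with its 3′-terminal base (probe offset 49), while
a type II probe ends immediately 5′ of the CpG, so the CG occupies virtual
offsets 50/51. `locate_cpg()` isolates this convention so it can be swapped
if a different manifest convention is ever needed.

`project_cpg()` maps the CpG C through the gapped alignment columns onto
the + strand of the target, handling hits on either strand (on a − strand
hit the design-strand C lands on the + strand G, so the canonical C
coordinate is one base 5′ of the mapped position). Anchors outside the
aligned probe span — always the case for type II — are extrapolated
ungapped past the alignment end. The projection is `NONE` when it runs off
the contig or the C falls inside a target deletion. Whether the CpG is
*present* is read directly from the genome at the projected interval, not
from the alignment columns.

Every mismatch is then labelled with its signed offset from the CpG C in
probe design-strand coordinates (negative = 5′). Offsets 0/+1 are the CpG
itself; −1/+2 are its flanks, the configurable "near" window. Gap columns
count as mismatches at the probe offsets they touch. Categories follow the
precedence `cpg_absent` > `at_cpg` > `near_cpg` > `clean`, and the
`cpg_mismatch` flag groups `at_cpg` with `cpg_absent` — the same grouping
used in the published probe bookkeeping ("a mismatch in the CpG site
itself, including those that do not have the CpG site").

One subtlety matters in practice: local alignment trims terminal
mismatches, and for a type I probe the CpG *is* the terminus. A planted
mismatch on the CpG or its flank would silently vanish from the alignment.
`classify_mismatches()` therefore also compares probe positions not covered
by the local alignment against the genome by ungapped extrapolation
(positions falling off the contig count as mismatches). This makes the
classification invariant to trimming; the cost is that a heavily-trimmed
alignment is judged partly by ungapped extension, which is the conservative
direction for a filter.

## The three-step filter

`three_step_filter()` sets, per probe:

* `pass_bitscore`: best-hit bitscore strictly greater than 70 (the
  published threshold is written "bitscore > 70", so the boundary fails);
* `pass_unique`: exactly one admissible alignment below the e-value cutoff
  — no best-to-second-best margin rule;
* `pass_mismatch`: category `clean` (default), or, with
  `exclude_near_cpg = FALSE`, anything except `at_cpg`/`cpg_absent`.

Admissibility (`admit()`) is applied first: at most 4 mismatches, at most
2 gap runs, no gap longer than 4 bp, all inclusive. The "CM probe" set is
mapped ∧ CpG present ∧ no CpG mismatch, and `summary()` of an annotation
reports the sequential counts (bitscore → +uniqueness → +mismatch) plus
the identity CM = mapped − (CpG-mismatch-or-absent), which
`filter_bookkeeping()` exposes as plain arithmetic for any set of counts.

Gene reconciliation takes the nearest target gene to the projected CpG
(distance 0 inside the interval, ties to the alphabetically first name) and
classifies agreement with precedence exact > ortholog > partial > none,
where partial means any shared alphanumeric token between names and
comparisons are case-insensitive.

## Concordance definitions

`join_shared()` pairs a probe with a sequencing call when the call
coordinate equals the projected CpG C or the G immediately after it (calls
made on the reverse strand fold onto the C). Sequencing tables are assumed
coverage-filtered; the filter boundary ("at least 10×") is inclusive.
"Within x%" always means an absolute methylation difference ≤ x/100 on the
0–1 scale, inclusive, so the error bins nest by construction. Methylation
tiers cut the pair mean at 0.3 and 0.7 with the middle tier closed (the
published tier notation leaves the boundary points unassigned; the middle
tier absorbs them). Bitscore bins default to {<70, 70–80, >80}. Bland–Altman
differences are sequencing minus array. Cross-sample summaries are computed
per sample and averaged unweighted by default; pooling all pairs is
available (`method = "pooled"`), and zero-variance or single-pair strata
report `NA` correlation rather than propagating `NaN`.

## What the synthetic generator emulates

`plant_probes()` carves non-overlapping windows out of a random genome,
forces a CG where the probe chemistry expects it, copies the window as the
probe, and then perturbs the *genome* according to the probe's divergence
class: `clean`, `mm_far` (1–4 substitutions away from the CpG), `mm_near`
(a flank substitution plus 2–3 far ones — diverged regions carry several
substitutions, and this keeps the class's bitscores below the clean bin),
`mm_cpg`, `cpg_lost` (CG destroyed), `duplicated` (target planted twice),
`absent` (no target). Default proportions are 0.4 / 0.2 / 0.1 / 0.1 /
0.05 / 0.1 / 0.05, realised exactly by largest-remainder rounding; probe
types alternate I/II and design strands alternate +/−.

`mm_cpg` splits by chemistry: on type I probes the *probe* base over the
CpG C is mutated, leaving the genomic CpG intact — these are the probes
that mismatch the CpG yet still have an assayable, sequenceable CpG, which
is what populates the at-CpG stratum of the concordance analysis. On
type II probes the 50-mer does not cover the CG, so the class mutates one
base of the genomic CG and the CpG is simply absent.

`simulate_methylomes()` draws each CpG's true level from the bimodal
mixture $0.4\,\mathrm{Beta}(0.5,8) + 0.4\,\mathrm{Beta}(8,0.5) +
0.2\,\mathrm{U}(0,1)$, emulating the unmethylated/methylated modes of real
methylomes. Sequencing is binomial at Poisson depth (default mean 30,
typical of reduced-representation data after deduplication), emitted
alternately on the C and G so the strand-fold in the join is exercised.
The array reads the true level plus Gaussian noise whose sd scales with
the probe's planted divergence, $\sigma = \sigma_0 (1 + 0.8\,k)$ for $k$
substitutions ($\sigma_0 = 0.03$): hybridization degrades continuously
with sequence divergence, which is what produces the bitscore-graded
concordance the filter exploits. Corrupted classes (near-CpG and CpG
mismatches, lost CpGs, absent targets) decouple the array signal entirely
(uniform betas) — the strong reading of the observation that flank
mismatches degrade probes as badly as CpG mismatches. Duplicated probes
report the average of their two loci (cross-hybridization), which is why
multi-mapping probes agree worse with single-locus sequencing. Detection
p-values rise noisily with divergence and are uniform for absent probes.
Eleven individuals are simulated by default, matching the reference study
design.

What the generator does **not** emulate: bisulfite conversion failure,
restriction-fragment library geometry, PCR duplicates, probe GC/type
intensity bias, SNPs under probes, and correlated methylation along the
genome. Passing tests therefore certify the pipeline's logic — coordinate
arithmetic, classification, filtering, statistics — not the biological
error model of any particular platform.

Under the default admissibility rules a mismatch-only cohort cannot
produce bitscores below 70 (four substitutions still score 73.6), so the
"<70" bin is empty on default synthetic cohorts and qualitative
bitscore-gradient checks run over the populated bins.

## Validation problem sizes and numerical choices

The package validates itself on 400-probe cohorts over 120 kb genomes with
11 simulated individuals (the oracle-equivalence suite uses 100 probes
against 50 kb, within the brute-force guard), and the qualitative
concordance orderings are asserted across 10 independent seeds. All
generators take explicit seeds and restore the caller's RNG state.

Numerical conventions collected in one place: strict `>` on the bitscore
threshold; inclusive admissibility, coverage and error-bin boundaries;
DP tie preference diagonal > gap-in-query > gap-in-subject and
hit ties by (contig, start); e-values compared strictly below the cutoff;
floats written with 4 decimals (e-values with 4 significant digits) in the
annotation file.

## Known limitations

* Karlin–Altschul parameters are taken as configuration, not estimated
  from the scoring scheme; with non-default scores the defaults for
  λ and K are not appropriate.
* Uniqueness counts admissible hits only; a probe with one admissible hit
  and several near-admissible ones still counts as unique.
* The nearest-gene rule is interval distance to a flat BED; transcript
  structure and promoter annotation are out of scope.
* Repeat-matched probes are summarised once by their best hit; analyses
  that count each hit separately will differ for multi-mapping probes.
* The per-sample-averaged correlation treats samples as exchangeable;
  unbalanced pair counts across samples are not reweighted.
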