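---
title: "Methods: misincorporation-based tRNA modification profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: misincorporation-based tRNA modification profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroseq)
```

## The measurement model

Several tRNA base modifications — m^2^~2~G26, m^1^G9, m^3^C32, m^1^A58, and
inosine at A34 — disrupt Watson–Crick base pairing. When a reverse
transcriptase copies across such a site it inserts an incorrect nucleotide in
a reproducible fraction of molecules. Sequencing short fragments of purified
tRNA produced by limited alkaline hydrolysis (gel-selected to 19–35 nt, so
each fragment carries few modifications and little structure) therefore turns
modification stoichiometry into a countable signal: the **misincorporation
fraction** at a reference position, the share of covering reads whose base
differs from the reference base.

The package models the observed fraction at a site as

$$ f = m\,q + (1 - m\,q)\,e $$

where $m$ is the modification efficiency (mole fraction of molecules carrying
the modification), $q$ the probability that the RT misreads a modified site,
and $e$ the uniform per-base sequencing error. `expected_misinc()` implements
this analytic form; it is the twin against which the simulator and the
pipeline are checked. One deliberate approximation: the simulator's error
model flips a base to a uniformly chosen *different* base, so an already
misread base can be flipped back to the reference with probability $e/3$,
making the exact expectation smaller than the formula by $O(mqe/3)$ (about
$7\times10^{-4}$ at $m q = 0.72$, $e = 0.003$ — far below counting noise at
the coverages used).

$m$ is not identifiable separately from $q$ with sequencing alone, which is
why calls are made on the raw fraction (the operational proxy used throughout)
rather than on a deconvolved $m$. An optional deconvolution dividing by a
user-supplied $q$ exists in the simulator's bookkeeping but is never applied
by default.

## Two-tier references

A tRNA gene catalog (genome FASTA + GFF3 with `tRNA` and `tRNA_intron`
records) is collapsed into two deduplicated tiers:

* **mature tier** — unique intron-spliced gene bodies, 3′ CCA appended
  (sequenced fragments derive from CCA-bearing mature tRNA; the append is a
  config switch and cannot affect deduplication since it is applied
  uniformly);
* **precursor tier** — unique `upstream flank + body (introns retained) +
  downstream flank` sequences, one per distinct gene.

Multicopy genes encode identical mature tRNAs but usually differ in leader,
trailer or intron, so the precursor tier is the finer partition. Reads are
mapped to the mature tier first; only reads with no qualifying mature
placement proceed to the precursor tier. Because every mature body is a
subsequence of its precursors, a read compatible with both is mature by
construction — precursor-tier evidence is thus specifically leader-, trailer-
or intron-derived.

Flank length defaults to 40 nt per side. The catalog formats in circulation
do not state how much flanking sequence belongs to a "precursor gene
sequence", so the value is a configuration knob recorded in the reference
set's provenance; 40 nt comfortably contains the leader/trailer lengths seen
in yeast pre-tRNAs while keeping flank-flank collisions between unrelated
genes negligible.

## Canonical numbering

Positions are reported on canonical (Sprinzl-style) labels so that "26" or
"58" means the same structural position in every tRNA regardless of length.
When a catalog supplies secondary-structure strings they are used to restrict
anticodon placement (only unpaired occurrences are eligible); otherwise a
layout-anchored heuristic applies:

* the annotated anticodon is located by exact (overlapping) search, keeping
  only placements consistent with cloverleaf geometry, nearest to the
  canonical offset; its first base is **always** label 34;
* the first 9 nt are labels 1–9 (acceptor stem, 8, 9);
* the 25 nt preceding the CCA are labels 49–73 (T arm, acceptor 3′ side,
  discriminator), which pins the conserved T-loop A at 58 for any
  variable-loop length;
* labels 27–43 surround the anticodon at fixed offsets; whatever lies between
  43 and 49 is the **variable loop** (labels 44–48, longer arms receive
  `e1, e2, …` insertions); the remainder between 9 and 26 is the D arm
  (labels 10–25, insertions suffixed after 17).

Ambiguities are resolved deterministically (nearest candidate wins; D-loop
insertions after 17; variable-loop insertions before 48). A sequence whose
anticodon cannot be placed consistently is flagged *unnumbered* and excluded
from position-indexed outputs with a warning — silent misnumbering is the
failure mode to avoid. The map is a bijection over linear indices, a property
enforced by test.

## Mapping

The aligner is an exhaustive ungapped scan: every offset of every reference
is scored by mismatch count, and all placements achieving the minimum are
returned if that minimum is at most `max_mm`. Design choices:

* `max_mm = 3` by default — a fragment of ≤35 nt must be allowed to carry a
  modification-induced mismatch plus sequencing error without losing its
  placement; three is generous enough for two modified sites per fragment
  while keeping random placements rare;
* substitutions only — hydrolysis fragments have no indel-generating step
  (RT-induced indels at some m^1^A58 contexts in other protocols are not
  modeled; see Limitations);
* sense strand only (the library is stranded);
* ties are reported, never broken: a read equally well placed on $n$
  references is *multi-mapped* with `n_equal_best = n`.

Two read-use policies follow from the tie structure. **Profiling** uses
uniquely placed reads only — near-identical family members would otherwise
smear each other's signal (the same policy makes it possible to profile a
single allele, e.g. a suppressor tRNA differing from its siblings by one
anticodon base, using only the reads that distinguish it). **Abundance**
uses all mapped reads with fractional weights $1/n$, which conserves the
mapped read count exactly; a read tied at several offsets of the *same*
reference still counts once there.

## Profiling and calling

Pileups count every aligned base of every unique read once; coverage is
A+C+G+T, with `N` excluded from numerator and denominator (an optional
quality mask turns low-quality bases into `N`). The mismatch fraction is
`NA` — never 0 — where coverage is below `min_coverage` (default 50): thin
positions must not masquerade as unmodified, nor noise as modification.
Replicate summaries report the arithmetic mean and sample (n−1) standard
deviation, with the *complete* policy (any `NA` replicate nulls the cell) as
default. The browser-display flag marks fractions ≥ 0.15, mirroring the
convention of the IGV display used to eyeball such data.

G26 calls compare the fraction in a designated reference condition against
two thresholds: ≥ 0.10 calls a Trm1 **target**, ≤ 0.01 a **non-target**
(the level observed when the methyltransferase is absent), and the band in
between is reported as *ambiguous* rather than silently assigned — the two
operating thresholds genuinely leave a gap, and hiding it would overstate
certainty. References without G26, or without coverage, are *unassessed*.
The structural prediction `g26_present & variable_loop_length >= 5` encodes
the known substrate preference of the Trm1 methyltransferase (short-loop G26
tRNAs show essentially no modification) and is kept separate from the
data-driven call so the two can be confronted.

Condition comparisons use a two-sided paired t test on per-reference
fractions at one canonical position over complete pairs (≥ 3 required).
All-zero differences return $t = 0, p = 1$ by convention; a numerically
constant nonzero difference returns $p = 0$ with an infinite statistic
rather than a spurious error. By default only the designated subset (e.g.
called targets) enters the test, with a flag-equivalent (`ref_subset`) to
widen it; no multiple-testing correction is applied for a single-position
comparison, and `stats::p.adjust` composes naturally when scanning several
positions.

## Counting and normalization

Per-tier count tables carry fractional weights (columns sum to mapped
reads). Size factors are the classic median-of-ratios: per sample, the
median over references (nonzero in all samples) of the count divided by the
reference's across-sample geometric mean. It is implemented in-repo — the
normalization is needed only for depth-matched scatter comparisons here, not
for differential testing, which is out of scope — and is cross-checked in
the test suite against an established implementation. Correlation summaries
use `log2(count + 1)`; the pseudo-count is configurable.

## The simulator

`simulate_library()` emulates the generative process the measurement model
assumes:

* source molecules drawn by relative abundance, defaulting to member-gene
  count per mature reference (tRNA abundance roughly tracks gene copy
  number); a `precursor_frac` knob (default 0.05) draws from precursor
  molecules to exercise the second tier;
* two uniform cut sites per molecule, rejection-sampled until the fragment
  length falls in [19, 35] — the computational analogue of gel selection;
* per-molecule Bernoulli($m$) modification state at each configured site;
  modified sites misread with probability $q$ using a per-site substitution
  preference (uniform over non-reference bases unless configured). The
  default $q = 0.9$ for pairing-blocking sites is an explicit simulator
  parameter, not an empirical claim — true misread probabilities are not
  measurable from fraction data alone. Modifications are also placed on the
  homologous positions of precursor molecules (the methyltransferase acts on
  pre-tRNA), so mature-tier fractions are not diluted by precursor-derived
  fragments;
* uniform per-base error $e$ (default 0.003) flipping to a uniformly chosen
  different base; constant Q40 qualities.

Ground truth (per-fragment source and per-site modification states, plus the
analytic per-site expectation) is returned alongside the reads, and the same
seed reproduces the library byte for byte.

What the simulator deliberately does **not** emulate: RT fall-off and stop
signatures, position-dependent hydrolysis preferences, adapter-ligation and
PCR biases, quality-score error profiles, and indels. Tests passing on
simulated libraries therefore demonstrate that the pipeline recovers the
parameters of *this* measurement model — they bound algorithmic error, not
protocol artifacts on real libraries.

## Blot quantification

Two northern-blot ("PHA": positive hybridization in the absence of
modification) formulas are included because they quantify the orthogonal
validation data such experiments produce:
`pha_percent_modification()` computes
$[1 - (\mathrm{ACL}/\mathrm{BP})_{exp} / (\mathrm{ACL}/\mathrm{BP})_{null}]
\times 100$ against a modification-null strain, and `pha_mod_index()`
computes the control-normalized ratio $(\mathrm{Tloop}/\mathrm{DAC}) /
(\mathrm{Tloop}/\mathrm{DAC})_{ctrl}$, anchored at 1.0 on the control lane.
Noisy blots can push the percent below 0 or above 100; values are reported
as-is with a warning, never clamped, because clamping would hide exactly the
lanes that need inspection. Background subtraction is the caller's job.

## Numerical and testing choices

All randomness flows through a single seed per simulation; reference
building, mapping and counting are fully deterministic (radix-sorted
ordering, ties kept). Problem sizes in the test suite are chosen so that
binomial counting noise, not runtime, is the limiting factor: recovery
checks run at ≥ 2,000× per-site coverage where a 3-standard-error band is
±3% or tighter; the efficiency-grid check uses 27 cells (a 9-point grid in
$m$ over three independent libraries of 80,000 fragments); the null-calibration
of the paired test uses 1,000 replicate comparisons. The catalog-scale
accounting check uses a synthetic 171-gene catalog engineered to collapse to
61 mature / 150 precursor references with 36 G26 and 11 A34 matures — it
exercises deduplication, orientation handling and numbering at realistic
scale, but it is constructed data, not a reproduction on a downloaded
genome catalog.

## Limitations

* Misincorporation is a proxy: fractions confound $m$ and $q$, so absolute
  efficiencies are comparable across conditions, not across sites with
  different chemistry.
* No RT-stop information is used; modifications that terminate rather than
  misread are invisible.
* Multi-mapped reads are excluded from profiling rather than statistically
  reassigned; a family whose members are identical around a site contributes
  no per-allele signal there.
* The numbering heuristic assumes a standard cloverleaf; exotic layouts
  (e.g. severely truncated D arms) are flagged unnumbered rather than
  guessed.
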