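---
title: "Models and methods behind retrotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retrotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrotrace)
library(dplyr)
```

retrotrace studies endogenous retrotransposition — the ongoing mobilization
of LINE-1 (L1), Alu, SVA and LTR elements — in cell populations profiled by
junction-capture sequencing. Capture assays enrich the 5′ and 3′ junctions
between a recently inserted element and its flanking genome, so the raw
material downstream of alignment is a table of junction-spanning amplicons.
The package covers the whole downstream path: a synthetic-data generator
with known ground truth, a junction caller, a de novo filter cascade,
structural hallmark annotation, subsampling sensitivity modelling with an
insertion-rate estimator, and a permutation test for positional bias of
insertions within genes. This vignette explains the models, the defaults,
and the choices made where the design was genuinely open.

## Coordinates and conventions

All coordinates are 0-based, half-open. An insertion *point* is the index of
the first base of the 3′ genomic flank. A planted insertion modifies a
haplotype as

```
genome[0, p + tsd) | cassette | genome[p, ...)
```

so the target site duplication (TSD) — the short direct repeat created by
staggered cleavage during target-primed reverse transcription (TPRT) —
appears once at the end of the left flank and once at the start of the
right flank. The cassette, in element orientation, is

```
[untemplated 5' nucleotides] [inverted 5' segment + spacer]
[element body from the truncation offset] [poly-A tail]
```

reverse-complemented for minus-strand integrations. The L1 endonuclease
motif is written 5′-TTTT/AA-3′ with the cleavage site between positions 4
and 5; the simulator stores the 6-mer context `genome[p-4, p+2)` and scans
both strands, and the annotator scores a context by its minimum Hamming
distance to the motif over both strand readings (verdict threshold: at most
2 mismatches, exposed as a flag — "resembling the motif" implies tolerance).

## The synthetic-data generator

The generator is first-class, tested code, not a fixture: its defaults
define the study conditions every downstream claim is tested under.

* **Genome.** Random sequence at 41% GC (human-like) split over two
  chromosomes (default 1 Mb total), with non-overlapping gene models of
  5–30 kb and random strands. This is a *toy* genome: no repeats, no
  chromatin, no sequence composition structure beyond GC.
* **Consensus library.** Synthetic stand-ins for the five active
  subfamilies (L1-Ta, L1-preTa, AluYa5, AluYb8, SVA_E) plus an LTR control:
  one random backbone per family with subfamily-diagnostic bases forced at
  fixed positions. Lengths are scaled down (L1 1.5 kb rather than 6 kb) to
  keep alignment fast; every structural computation is length-agnostic.
  Backbones end in a non-A trinucleotide so an appended poly-A tail has a
  well-defined start.
* **Hallmark repertoire.** Per family: a full-length fraction (0.55 for L1,
  reflecting the unusually high full-length rate of de novo events in
  pluripotent cells; 1 for the non-autonomous families), a twin-priming
  fraction among truncated L1 (0.5), an endonuclease-independent fraction
  (0.1; these events land uniformly rather than at motif matches and may be
  3′ truncated near the poly-A signal), TSD lengths of 4–20 bp, poly-A
  tails of 10–60 bp, untemplated 5′ G nucleotides ("G" or "GG") with
  probability 0.2 for L1, and a 25-bp random spacer between the inverted
  segment and the element body of twin-priming events.
* **Reads.** Each junction emits a Poisson(depth × VAF) number of unique
  amplicons whose alignment starts scatter uniformly within ±30 bases of
  the junction without collisions; PCR duplicates are added per unique
  amplicon at the configured rate and share a duplicate-group id. There is
  no sequencing-error or base-quality model: downstream inputs are aligned
  amplicon tables, and the empirical offset distribution of real capture
  libraries is unknown to us — the uniform jitter is a stand-in whose only
  role is to create realistic "unique amplicon" diversity for the ≥5 nt
  separation rule.

**Unambiguous junctions.** The generator resamples truncation points,
spacer termini and untemplated bases so that no junction base could equally
be attributed to the neighbouring segment under the annotator's alignment
scoring (for instance, the two terminal spacer bases must mismatch the
adjacent consensus continuation, because a single blocked base can still be
crossed by a mismatch-then-match extension at net positive score). This
makes "exact structural recovery" a well-posed round trip. Real genomes do
produce ambiguous junctions — that is precisely what microcomplementarity
is — so the round-trip tests tolerate the rare residual ambiguity (e.g. a
homopolymer TSD whose boundary is not unique) by requiring ≥99% exact
recovery rather than 100%.

What passing round-trip tests show, therefore, is that the annotation logic
is correct on clean data; they do not show robustness to sequencing error,
alignment artefacts, nested repeats, or transductions, none of which the
generator emulates.

## Junction calling

Duplicate collapse keys on (sample, chromosome, alignment start, junction
side, family) — alignment-start identity is the standard proxy for PCR
duplicates, and the assay literature counts "unique amplicons" without
defining uniqueness further. Separation is measured on alignment starts
(the natural choice given start-keyed uniqueness). Unique amplicons are
clustered by single linkage with a 200-base window (junction amplicons of
one event fall within an insert-size-scale neighbourhood; exposed as a
flag). A cluster is reported as a call iff it contains **at least 2 unique
amplicons** whose maximum pairwise start separation is **at least 5 nt** —
the minimum reporting threshold. The junction coordinate per side is the
maximum-multiplicity member start, ties broken toward the 5′-most
coordinate (deterministic). Calls may be single-sided: a real SVA event was
resolvable only at its 3′ junction, and the caller mirrors that. Subfamily
assignment reads the diagnostic positions of the resolved sequence;
ties are reported as "unresolved" rather than guessed.

Catalog matching declares a call "known" when a same-family catalog entry
lies within ±100 bases (typical TSD-plus-breakpoint uncertainty; exposed as
a flag).

## The de novo filter cascade

A call in a pluripotent sample is de novo iff it fails none of:

1. **catalog** — present in a non-reference insertion database;
2. **parental** — found in the parental cell line;
3. **earlier passage** — for hESC samples only: found in an earlier passage
   of the same line. Presence only in the *later* passage is compatible
   with de novo (an event arising during cultivation). hiPSC lines have a
   parental sample, which is the stronger comparison, and events present in
   both passages of one hiPSC line have been validated as genuinely de
   novo — so the passage filter is not applied within hiPSC lines;
4. **recurrent across lines** — found in a different cell line; two
   passages of one line count as one line.

All filters are evaluated (the failed set is complete, not just the first
hit), and every presence check shares the ±100-base window, since no
tighter tolerance is published. On cohorts simulated with labelled
germline-shared / parental-private / pluripotent-private classes the
cascade recovers the pluripotent-private set exactly in noise-free mode; a
de novo event in an hESC line that predates the earliest surveyed passage
is *constructed not to occur* in the simulator, because such an event is
observationally indistinguishable from germline.

## Hallmark annotation

Orientation and subfamily are decided by banded local alignment of the
inserted sequence against each candidate consensus (match 2, mismatch −3,
gap open −5, gap extend −2 — standard parameters, deterministic). Then:

* **TSD**: longest exact suffix of the left flank equal to a prefix of the
  right flank, capped at 30 bp (published TSDs are short and exact); the
  blunt case is the empty string, never an error.
* **Poly-A**: maximal 3′-terminal A run permitting one single-base
  interruption per 20 consumed bases; an interruption must be flanked by
  further A, so two consecutive non-A bases end the tail. This pragmatic
  definition (exposed as a flag) prevents a long tail from walking through
  the element terminus into body sequence.
* **Truncation and inversion**: the consensus offset of the body alignment
  is the 5′ truncation offset; offsets ≤3 bases count as full length
  (absorbing untemplated additions). A leading unaligned segment of ≥15
  bases is tested antisense; a hit is a twin-priming inversion, reported
  with its breakpoint and the spacer length between the inverted segment
  and the body.
* **Untemplated 5′ nucleotides**: leading bases matching neither flank nor
  consensus. **Microcomplementarity** (1–5 bases of identity between the
  flank suffix and the consensus immediately 5′ of the truncation point —
  junction ambiguity) is reported only when no untemplated bases are
  present; the two are mutually exclusive by definition. For inverted 5′
  ends the microcomplementarity readout still uses the sense consensus and
  should be read with care — resolving it against the antisense
  continuation is future work.
* Single-sided or unalignable inserts are reported with structure fields
  `NA` ("unresolved") rather than inferring genomic deletions.

## Sensitivity and the insertion-rate model

**Baseline false-negative rate.** Germline insertions found in a parental
line or early passage should reappear in the matched later sample; the
per-family recovery fractions are combined into one overall rate by
weighting with the average per-sample insertion counts
(`family_weights_default`: 214 L1, 1411 Alu, 53 SVA, 14 LTR):
`FN = 1 − Σ w_f d_f / Σ w_f`. With the reference detection fractions
(88.5/92.8/88.3/89.8%) this gives 7.9%.

**VAF adjustment.** Sampling a library at depth `v` models an insertion
carried by a fraction `v` of cells. The depth-specific detection fractions
compose with the baseline **multiplicatively**:
`FN(v) = 1 − d̄(v) · (1 − FN_baseline)`. The composition rule is not
published as a formula; this multiplicative form, with all four families
(including LTR) in the weighted mean, reproduces both published
percentages (30.5% at v = 50%, 94.4% at v = 5%) from the published inputs,
and is adopted for that reason. Excluding LTR gives 30.6%/94.6% — the LTR
family matters despite its small weight.

**Subsampling implementation.** Reads are thinned per-read independently
(Bernoulli at depth `s`), not without replacement — at library scale the
two coincide, and Bernoulli thinning admits the closed-form check that an
insertion with `k` unique amplicons is detected with probability
`1 − (1−s)^k − k s (1−s)^(k−1)`. Each replicate draws one uniform variate
per unique amplicon (the minimum over its duplicate copies), so one draw
yields the whole depth grid with exact per-depth marginals; replicate
curves are monotone by construction, and the replicate *mean* curve — the
reported quantity — is unbiased at every depth. Default 10 replicates per
percentile on a 1% grid.

**Rate estimator.** Observed de novo insertions are corrected by inverse
detection probability: insertion `i` contributes `1/p̄_i`, with `p̄_i` its
mean detection probability over the depth grid from the 5% VAF floor to
100%, scaled by the baseline detection rate `1 − FN_baseline`. The floor
reflects that events below 5% VAF are essentially invisible at these
thresholds and are excluded from the estimand, not extrapolated. The
published description ("normalized to the corresponding false negative
rate", then a cumulative sum over 5–100%) does not pin down the estimator;
this inverse-probability reading is isolated in one function
(`estimate_insertion_rate()`) for easy revision. The per-cell figure
multiplies the corrected per-line count by the mean VAF of the observed
insertions — an insertion at VAF `v` is carried by a fraction `v` of
cells — and is explicitly model-dependent. In simulations with VAF drawn
uniformly on [0.05, 1] and realistic depth the corrected count recovers the
true per-line rate within 20% over 50 replicates (the grid-mean correction
is consistent when true VAFs are uniform over the grid, and mildly biased
upward otherwise).

## Positional bias

For an intragenic insertion the statistic is its percentile of gene length
measured from the annotated TSS (0 at the TSS, 100 at the 3′ end;
strand-aware). The null draws positions uniformly over the *intragenic
genome* — gene chosen with probability proportional to its length, position
uniform within the gene — because "random sampling of genomic coordinates
with respect to annotations" most naturally means uniform coordinates
conditioned on landing in a gene (the statistic is undefined elsewhere). A
uniform-per-gene alternative sits behind the `null` flag. Exceedances use
`≤` and the p-value is `k/N` (not `(k+1)/(N+1)`): this rule reproduces the
published p-value exactly from the published counts (6,000 of 10^6 →
p = 0.006). Insertions overlapping several genes contribute the minimum
(most 5′) percentile, and the event is logged. Under the null the p-value
is uniform to Kolmogorov–Smirnov precision at α = 0.01 over 200 simulated
nulls.

## Numerical and engineering choices

* Every stochastic operation takes an explicit seed; a fixed configuration
  yields byte-identical outputs, down to file checksums in the run
  manifest.
* Tabular writers stamp a `#` header with package version, stage and seed.
  FASTA output carries no such header — comment lines are not part of the
  format and break downstream parsers.
* Problem sizes in the test suite are desk-scale by design: genomes of
  0.2–2 Mb, tens to hundreds of insertions, 10^4 permutations in the null
  uniformity check, 50 replicates in the rate-recovery check. These sizes
  give the property checks comfortable statistical power while keeping the
  whole suite fast; the pipeline itself runs unchanged at larger sizes.
* The single-sample demo pipeline applies only the catalog filter of the
  cascade (the other filters need a cohort); `annotate_de_novo()` is the
  full cascade and is exercised by the cohort simulator.

## Known limitations

* The generator does not emulate sequencing error, mappability, reference
  repeats, source-element transductions or target-site deletions; passing
  tests certify the downstream logic, not robustness to those upstream
  artefacts.
* Microcomplementarity at inverted 5′ junctions uses the sense consensus
  (see above).
* The per-cell extrapolation inherits every assumption of the VAF-weighted
  model; treat it as an order-of-magnitude statement.
* The hESC-specific false-negative figures cannot be recomputed here
  because their per-family inputs are not published; the package makes no
  attempt to reproduce them.
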