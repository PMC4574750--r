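---
title: "Models and methods behind ribostep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribostep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostep)
```

This vignette explains the statistical and geometric model the package
implements, the conventions and parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
choices made where several reasonable options existed.

## The data model and coordinate conventions

All positions are 0-based, half-open intervals in transcript space;
plots and reports display 1-based positions and codon positions 1–3.
A mapped footprint is reduced to `(transcript_id, five_prime, length,
sample, weight)`, where `five_prime` is the transcript offset of the
leftmost aligned base (SAM `POS − 1`) and `length` is the aligned read
length after soft clipping. Transcriptome alignments are sense by
definition, so reverse-strand records are dropped (and counted).
Reads aligning to several transcripts are assigned to exactly one,
uniformly at random under a mandatory seed, which conserves the total
read count; a `"all"` policy duplicating them exists for diagnostics.
Where alignments contain indels we anchor on the leftmost aligned base;
other conventions are conceivable and would shift 5′ ends by the indel
offset.

A CDS interval *includes its stop codon*. This makes the stop codon
addressable inside the CDS, which the stop-anchored metagene and the
readthrough classification need. Consequently an ORF of $k$ sense
codons spans $3(k+1)$ nt, and `codon_length` everywhere counts sense
codons with the stop *excluded* (the minimal ORF `AUG-stop` has
`codon_length` 1). Reported uORF sizes follow this convention; a
stop-included convention would read one codon larger.

## Frame calling

Framing statistics use *interior* reads only — the entire read contained
within the CDS — which excludes most initiating and terminating
ribosome footprints. The phase of a read on a CDS is
$(\mathrm{five\_prime} - \mathrm{cds\_start}) \bmod 3$, i.e. the codon
position of its 5′ end *relative to that CDS's own frame*. Per length
class the phase histogram is tallied and the predominant phase called;
its fraction of the class measures framing fidelity. Exact ties break
toward the smallest phase index with a warning.

The per-transcript view uses a different, deliberate convention: frames
relative to transcript nt 1 (`position mod 3`), which is what makes
ORFs in different frames visually separable. The two conventions are
never mixed within one operation.

## Filtering translated coding regions

A candidate region passes when

1. at least `min_reads` (default 50) focal-length reads in the expected
   phase lie inside it,
2. at ≥ `min_locations` (default 10) distinct 5′-end positions, and
3. if the phase holding the *most* reads is not the expected phase, a
   phase-consistency test passes.

The focal length and expected phase default to the predominant class of
the frame call. The phase test exists because a highly translated
region sheds a small out-of-phase fraction of reads onto overlapping,
out-of-frame candidates, which can carry enough raw support to pass the
count rules. It compares the candidate's expected:maximal read ratio
with the ratio aggregated over all count-passing regions, via a 2×2
Pearson χ² (df = 1, no continuity correction by default — switchable);
the candidate survives only if its ratio *exceeds* the global ratio and
the difference is significant at `alpha` (default 0.05). Design choices
here that were genuinely open:

- The test is applied only to discordant candidates (maximal ≠
  expected); `phase_test_all = TRUE` applies it everywhere.
- The 2×2 table `[(candidate expected, candidate maximal); (global
  expected, global maximal)]` is our concretisation; the global counts
  pool each count-passing region's expected-phase and maximal-phase
  reads. Pooling *before* the phase test avoids circularity. Since
  concordant regions contribute equally to both global cells, the
  global ratio sits slightly below 1 and discordant shadows (ratio ≈
  the off-phase:in-phase background) fall well under it.
- No multiple-testing correction across candidates: the gate is a plain
  0.05 threshold by design.

These thresholds make the filter sharp: (50 reads, 10 locations) passes
and (49, 10) or (50, 9) fail, and raising either threshold can only
shrink the pass set.

## De novo ORF discovery

Every start codon (default `ATG`; near-cognate initiators such as `GTG`
can be added when footprint evidence warrants, as non-AUG initiation is
detected by reads, not by scanning) is paired with the nearest
downstream in-frame canonical stop. Nested starts sharing a stop yield
distinct candidates; codons containing `N` never match (conservative).
Discovered candidates are filtered with exactly the same support gate as
annotated ones. Annotation matching counts a region *recovered* when a
candidate shares its stop (and hence frame) and *exact* when the start
agrees too. Classification relative to the main CDS is total and
single-valued; configurations outside the six named relations (e.g. an
in-frame nested start, or an out-of-frame ORF straddling the main stop)
are reported as `other` rather than forced into the nearest category.

## Metagene profiles and footprint geometry

For a length class $n$, each selected CDS contributes its positional
counts of $n$-nt 5′ ends around the start and stop codons, divided by
its mean per-nt density of $n$-nt reads (total $n$-nt reads with 5′
ends inside the CDS over CDS length). The profile is the simple mean of
these normalised counts over contributing CDSs, so scaling any CDS's
reads by a constant leaves the profile unchanged and deep transcripts
cannot dominate. A read-weighted mean of the normalised profiles is the
natural alternative; the simple mean was chosen for its exact
scale-invariance property and the alternative left out to keep one
well-defined estimator.

Geometry is read off the profile maxima under a two-codon (P- and
A-site) core model, $L_5 + 3 + 3 + L_3 = n$:

- start anchor, initiating ribosome with the start codon in the P-site:
  maximum at offset $-L_5$, elongation-state geometry;
- stop anchor, terminating ribosome paused with the stop codon in its
  empty A-site: maximum at offset $-(L_5 + 3)$, termination-state
  geometry.

Maxima are searched within ±($n$ + 5) nt of the anchor; exact ties
resolve toward the offset nearest the canonical mid-read expectation
and are flagged ambiguous. A geometry row is produced for every
(length, anchor) pair; classes with no true peak (e.g. a termination
anchor for a purely elongating class) simply reflect noise, and
downstream summaries should use the classes with clear peaks. End
extensions are reported as $(\Delta 5', \Delta 3')$ against a reference
elongation class (default: the shortest one present).

Peaks a few codons from the anchors caused by ligation/nuclease
sequence bias in real data are not modelled.

## Depletion QC

Library composition is the per-sample read fraction by transcript
category; the enrichment factor of a treatment is the ratio of mRNA
fractions. Species-level diagnostics treat each distinct read sequence
as one species. The fixed-slope R² measures agreement with the
no-depletion line $y = s\,x$, $s = N_B/N_A$ the ratio of mapped mRNA
read totals — not a regression fit, so R² may be negative; it is
computed in linear count space over species with more than 5 reference
occurrences (a log-space variant sits behind a flag). The denominator
uses the standard total sum of squares around the mean treated count.
The χ² envelope is *pointwise* with df = 1: a species with counts
$(x, y)$, $n = x + y$, is inside when
$(x - p_A n)^2/(p_A n) + (y - p_B n)^2/(p_B n) \le
\chi^2_{1,\,0.95} \approx 3.841$, with $p_A = N_A/(N_A+N_B)$. Pointwise
(rather than simultaneous) coverage was chosen and is verified by
simulation: under a binomial no-depletion split of 10,000 species the
empirical coverage matches the nominal 95% within binomial error.
Folding/binding energies are consumed from an external table keyed by
read sequence — nucleic-acid folding is not reimplemented — and missing
species are reported as a coverage fraction, never imputed as zero.

## The synthetic generator

The generator is the package's study-condition bed: transcripts of
60–150 sense codons with 30–80 nt leaders and 30–60 nt trailers at GC
0.5, log-normal translation levels, 30% of transcripts carrying a
planted uORF (3–16 codons), 10% an internal overlapping ORF (5–12
codons, shifted frame, placed by bounded rejection so the main frame
stays stop-free), plus rRNA-like transcripts contributing ~5%
contaminant reads. Footprints are placed with the P-site uniform over
sense codons; the start codon is up-weighted by an initiation pause
factor and the stop codon (A-site) by a termination pause factor (both
default 3, in line with the initiation/termination accumulation visible
in cycloheximide-arrested profiling data). The initiation weight is a
deliberate addition: with strictly uniform placement the start-anchored
profile is flat in expectation and has no unique maximum to read
geometry from; real metagene profiles have exactly such a start peak.
Each footprint's length class is drawn from the per-state mixture of
its geometry preset and its 5′ end jittered ±1 nt with probability
$(1-f)/2$ per side — the concretisation of imperfect framing
(*f* defaults to 0.95, within the 85–96% range typical of
well-digested libraries). The built-in presets encode a
Chlamydomonas-like geometry (27-nt elongation class protecting 11 nt
5′ of the P-site codon and 10 nt 3′ of the A-site codon; 28-nt
elongation +1 nt at the 5′ end; 28/29-nt termination classes +1 nt at
the 3′/both ends) and a mouse-like geometry (28–30-nt elongation
classes with $L_5 = 12$; 30-nt termination +1 nt at the 3′ end).
RNA-seq reads are placed uniformly (an alkaline-fragmentation-like
model) with abundance proportional to RNA level × length.

What the generator does *not* emulate — hence what passing tests do not
show about real data: sequencing errors, ligation/nuclease sequence
bias, codon-specific dwell times and pause sites, disome footprints,
isoform ambiguity beyond random multimap assignment, and non-uniform
RNA-seq coverage. Parameter-recovery results should be read as
correctness of the estimators under the stated model, not as accuracy
guarantees on any particular library.

## Numerical and degenerate-input choices

- Seeds are mandatory wherever randomness occurs (generator, simulator,
  multimap assignment, thinning); identical seeds reproduce outputs
  byte for byte.
- Sliding-window means use truncated windows at the edges (mean over
  available codons); a window larger than the series returns the global
  mean; even window sizes are rejected.
- `fixed_slope_r2` with zero variance in the treated counts is
  undefined and reported `NA`, not forced to a number.
- Empty length classes are dropped from frame calls; an empty metagene
  selection warns rather than errors; absent property species are `NA`.
- χ² tests run without continuity correction by default (switchable);
  degenerate 2×2 tables (a zero margin) yield a failing, `NaN`-valued
  test rather than an error.

## Problem sizes

The test suite and the acceptance script run on simulations of
10,000–120,000 footprints over 10–100 transcripts and 10,000-species
depletion tables — sizes chosen so each statistical check has
comfortable power (3σ margins on binomial/multinomial oracles) while
the full suite stays fast. The pipeline itself is vectorised and
handles realistically sized libraries (10⁷ reads) in memory.

## Known limitations

- One CDS per transcript in the annotated model (candidate tables may
  hold arbitrarily many candidate regions per transcript).
- No modelling of periodicity drift along ORFs, ribosomal
  frameshifting, or readthrough efficiency; readthrough appears only as
  classification evidence.
- The phase-consistency test's global pooling is one of several
  defensible definitions (see above); runs log the pooling used.
- Static figures only.
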