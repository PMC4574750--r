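# ribostep

Frame-calling, ORF discovery and footprint-geometry analysis for ribosome
profiling (Ribo-seq) data aligned to a transcriptome.

## The problem

A translating ribosome shields a ~27–30 nt fragment of mRNA from nuclease
digestion. Sequencing these ribosome-protected fragments (RPFs) and mapping
their 5′ ends back to the transcriptome reveals where ribosomes sit — and
because elongation advances in steps of exactly one codon, the 5′ ends of
RPFs of a given length concentrate on one of the three codon positions.
This *triplet periodicity* is the key signal: it tells you the reading
frame being translated, distinguishes genuine coding regions from
overlapping out-of-frame shadows, and exposes short upstream ORFs (uORFs),
internal overlapping ORFs, downstream ORFs and stop-codon readthrough.

`ribostep` is for researchers who have RPF (and optionally RNA-seq) reads
aligned to a transcriptome and want to go from alignments to biology
without writing bespoke scripts. It provides:

- **Frame calling** — per length class *n*, the phase histogram of 5′ ends
  over codon positions and the predominant phase with its fidelity.
- **Coding-region filtering** — a coding region is retained when it holds
  at least 50 focal-length reads in the expected phase at ≥ 10 distinct
  locations, and (when its maximal phase disagrees with the expected
  phase) survives a χ² phase-consistency test at α = 0.05 against the
  pooled expected:maximal ratio of all supported regions.
- **De novo ORF discovery** — every AUG paired with its nearest in-frame
  canonical stop (UAG/UAA/UGA), matched against annotation and classified
  relative to the main CDS (uORF, overlapping uORF, internal overlapping,
  dORF, readthrough extension).
- **Metagene geometry** — weighted average 5′-end profiles around start
  and stop codons (each CDS down-weighted by its mean read density so deep
  transcripts do not dominate), from which the protected-fragment geometry
  is read off the profile maxima: with the start codon in the initiating
  ribosome's P-site, the start-window maximum sits at −L5, so
  L5 = nt protected 5′ of the P-site codon and L3 = n − L5 − 6 (3 nt each
  for the P- and A-site codons); the stop-window maximum, with the stop
  codon in the terminating ribosome's empty A-site, sits at −(L5 + 3) and
  gives the termination-state geometry. Terminating ribosomes protect 1–2
  nt more than elongating ones; `termination_extension()` reports each
  class as (Δ5′, Δ3′) relative to a reference elongation class.
- **Depletion QC** — library composition by category (rRNA/mRNA/…),
  FPKM concordance, the fixed-slope R² of distinct read-species counts
  against the no-depletion expectation *y = (N_B/N_A)·x* (not a fitted
  regression — R² can be negative), a pointwise 95% χ²(1) envelope for
  species counts, and read-property distributions (length, GC, external
  folding energies) with total-variation divergences between samples.
- **Counts export** — per-CDS count matrices over chosen (length, frame)
  combinations, paired with RNA-seq counts, ready for count-based
  differential-translation tools.
- **A footprint simulator** — synthetic transcriptomes with planted
  uORFs/overlapping ORFs and reads generated under a configurable
  footprint geometry, phase fidelity and pause factors, so every stage is
  testable with known ground truth and no external data.

Everything is tibble-in/tibble-out and pipe-friendly; results have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a Chlamydomonas-like experiment and run the analysis:

```r
library(ribostep)

truth  <- make_transcriptome(n_transcripts = 50, seed = 1)
preset <- geometry_preset("cr27")          # 27-nt elongation footprints
sim    <- simulate_reads(truth, preset, n_reads = 100000, seed = 2,
                         n_rna = 20000)

cds   <- cds_table(truth$transcripts)
calls <- sim$ribo |> interior_reads(cds) |> phase_by_length() |> frame_call()
glance(calls)
#>   sample  predominant_length predominant_phase framing_fidelity total_reads
#> 1 sample1                 27                 1            0.946       82405
```

The predominant 27-nt class maps to phase 1 — codon position 2 — with
94.6% framing fidelity (the preset simulates 95%). Filter the annotated
coding regions and infer the footprint geometry:

```r
report <- filter_cds(cds, sim$ribo, filter_config(), calls = calls)
glance(report)
#>   n_candidates n_pass focal_length min_reads min_locations alpha
#> 1           50     50           27        50            10  0.05

sel <- select_metagene_transcripts(sim$ribo, cds, calls)
geo <- infer_offsets(metagene_profile(sim$ribo, sel, lengths = c(27, 28, 29)))
tidy(geo)
#>   sample  length state       peak_offset    L5    L3
#> 1 sample1     27 elongation          -11    11    10
#> 2 sample1     28 elongation          -12    12    10
#> 3 sample1     28 termination         -14    11    11
#> 4 sample1     29 termination         -15    12    11
```

27-nt elongation footprints protect 11 nt 5′ of the P-site codon and
10 nt 3′ of the A-site codon. Relative to that reference class,

```r
termination_extension(geo)
#>   length state       delta5 delta3
#> 1     28 elongation       1      0   # +1 nt at the 5' end
#> 2     28 termination      0      1   # +1 nt at the 3' end
#> 3     29 termination      1      1   # +1 nt at each end
```

— the enlarged termination-state footprint. `plot_phase_histogram()`,
`autoplot()` on metagene profiles and `transcript_profile()` +
`autoplot()` reproduce the standard framing, metagene and per-transcript
views; `run_pipeline(pipeline_config(...))` runs all stages and writes
TSV outputs with a provenance log.

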