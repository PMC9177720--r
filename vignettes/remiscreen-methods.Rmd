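---
title: "Methods: differential SNP calling, in-silico plasmid rescue and screen metrics"
author: "REMIscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential SNP calling, in-silico plasmid rescue and screen metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(REMIscreen)
```

REMIscreen models the computational side of a strain-engineering workflow
in *Komagataella phaffii*: a random genome-disruption library is built by
restriction enzyme-mediated integration (REMI) of a linearized plasmid, the
library is screened for secretion of a heterologous protein in 96-well
format, hits are genotyped by plasmid rescue, and suspicious clones are
resequenced against the parental host to separate insertion effects from
incidental point mutations. This vignette explains the models behind each
stage, the parameters that matter, and the choices made where the design
was open.

## The differential SNP caller

### Model

Reads from the mutant and the host strain are aligned against a reference
set that deliberately mixes the genome contigs with the integrated
construct sequences. Mixing matters: a phenotype-causing variant can sit on
the expression construct itself (in the motivating case, inside the
secretion-signal coding sequence), and it is only callable if the construct
is part of the mapping target.

The caller consumes alignments in the LAST tabular (TAB) dialect — 12
whitespace-separated columns with a `"n[,d:i,n]*"` blocks string — or the
package's internal TSV, which appends the strand-corrected read bases as a
13th column. Three steps follow:

1. **Best-alignment selection.** For each read, only the alignment with the
   maximum score survives. Score ties are broken by a single uniform draw
   per tied read from a generator seeded by the caller, with reads
   processed in sorted read-id order. The underlying protocol only says
   the selection is random; pinning the iteration order and the per-read
   draw makes runs reproducible, and reads with a unique best alignment
   provably never consume randomness, so the seed influences nothing else.

2. **Pileup.** Every matched (non-gap) alignment column contributes the
   read base at that reference position; gap columns contribute nothing
   (the TAB dialect does not carry inserted-base identity, so nothing else
   is possible). `N` bases are dropped from both counts and depth.

3. **Two-tier classification.** Per position with depth `d`, reference
   count `R`, aggregate non-reference count `V = d − R`:
   * `d < 10` → `not_evaluated`;
   * `V ≤ R` → `no_variant`;
   * `V > R` and `V/d ≥ 0.90` → `plausible`;
   * `V > R` otherwise → `potential`.

   A differential call requires `plausible` in the mutant and neither
   `potential` nor `plausible` in the host.

### Parameters and open readings

All thresholds live in `snvParams()`:

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 10 alignments | minimum coverage to evaluate a position |
| `plausible_fraction` | 0.90 | variant fraction promoting potential → plausible |
| `strict_majority` | `TRUE` | variant count must strictly exceed the reference count |

Two readings of the majority rule are defensible: aggregate all
non-reference bases, or test only the most frequent alternative allele. The
package aggregates — the most literal reading of "a nucleotide change
observed more frequently than the original nucleotide" — and reports the
most frequent non-reference base (ties broken alphabetically) as the
allele. With `plausible_fraction` at 0.90 the two readings can only
disagree at positions where two different alternative alleles are each
common, which at clonal purity is vanishingly rare; the per-allele behavior
is reachable by adjusting the exposed parameters.

Host positions with *no or low coverage* pass the exclusion filter: an
unevaluated host position is "not labeled" as a SNP, which is the filter's
letter. It is also the riskiest case — the host data cannot actively
exclude a shared variant there — so such calls carry a
`low_host_coverage` flag rather than being dropped.

No base-quality weighting is applied: the classifier counts alignments,
and the simulator writes a constant placeholder quality precisely because
qualities play no role downstream.

## The REMI rescue model

A cut is abstracted to a single top-strand coordinate at
`site_start + cut_offset`; sticky ends, Klenow blunting and ligase
chemistry are collapsed into "digestion produces fragments, self-ligation
concatenates them into a circle". This is deliberate: every downstream
decision (which fragment carries the plasmid, what the flanks are, where
they map) depends only on sequence content, not on end chemistry.

The shipped enzyme table covers the two linearization enzymes (BamHI,
KpnI) and the eight-enzyme rescue mixture (AflII, EcoRI, EcoRV, HpaI,
MluI, NheI, SpeI, XhoI), with recognition sequences and cut offsets from
standard enzyme reference data. Site scanning is IUPAC-aware, scans both
strands (palindromic sites are reported once) and wraps across the origin
for circular molecules, so "zero sites on the plasmid" is an exact circular
statement, not a linear approximation.

`rescuePlasmid()` requires the full inserted sequence as its marker. If a
digestion enzyme cuts inside the insert, the marker is split across
fragments and the function raises a protocol violation naming the enzyme —
the in-silico analogue of a rescue that cannot yield an
antibiotic-resistant circle. Insertion junctions can *create* such a site
even when the plasmid itself is clean; the round-trip tests treat those
rare events as failed rescues, which mirrors how a small number of
screening positives typically resist locus determination.

`locateFlank()` maps flanks by exact substring search on both strands of
the genome contigs only (constructs are excluded — a flank matching the
plasmid would be uninformative). Flanks shorter than `min_length` (default
20 bp) are reported unmapped and multi-hit flanks ambiguous. The 20 bp
floor is this package's choice — below it, exact matches stop being
specific in a megabase-scale genome; the source protocol names no
threshold.

## The synthetic-data module

The generator produces everything the pipeline consumes, with ground
truth:

* `generateGenome()` — i.i.d. bases at a target GC (default runs use 0.41,
  a realistic yeast-like GC content), length ≥ 1 kb.
* `generatePlasmid()` — rejection/repair sampling of a circular sequence
  with exactly one site per linearization enzyme and zero circular sites
  for the rescue mixture; unsatisfiable constraint sets (a forbidden site
  nested inside a required one) fail fast naming the enzyme.
* `plantSNV()` — a single-base edit with an allele-purity attribute, so
  both near-clonal mutations (purity 1.0, the case that matters) and
  sub-threshold contamination (e.g. purity 0.5, which must *not* be called
  plausible) can be simulated.
* `simulateReads()` — uniformly placed fixed-length single-end reads,
  i.i.d. substitution errors, both strands; each read carries its true
  placement as an oracle alignment record (score = matches − mismatches,
  one ungapped block), so the caller can be tested in isolation from any
  aligner.

Defaults mirror the study conditions the pipeline is meant to reproduce:
30× mean coverage per strain (the source protocol does not print its
depths; 30× is a routine resequencing depth at which the ≥10× rule is
comfortably satisfied almost everywhere), 150 bp reads, and a 0.5%
substitution rate typical of short-read data. Single-end reads suffice
because the classifier is strictly per-position; paired-end information
adds nothing. The simulator deliberately omits indels (the classifier
addresses substitutions only), quality-score error profiles, PCR
duplicates and structural variants beyond the single REMI insertion —
so passing tests demonstrate the *logic* of the caller and rescue
procedure, not robustness to alignment artifacts around indels or repeats
in real data.

All generators are deterministic given a seed, implemented by saving and
restoring the session RNG state, so library code never perturbs a user's
random stream.

## Screen metrics

* **Relative titer**: per plate, the mean blank signal is subtracted
  (floored at zero), signals are scaled by the single-point dilution
  factor (default 25; it cancels in the ratio) and divided by the mean
  corrected host-control signal of the *same* plate. Per-plate rather than
  global host normalization is the default because plate-to-plate assay
  drift is the dominant nuisance in 96-well ELISA screens; the source
  protocol does not state which was used.
* **Hit calling**: strictly greater than 1.3× the host. The boundary is
  strict because the defining phrase is "more than 1.3-times"; a softer
  screen-stage band can be emulated by lowering the threshold.
* **Growth rate**: µ is the least-squares slope of ln(OD660) versus time
  over the contiguous window (≥ 4 points) inside OD ∈ [0.05, 1.0] that
  maximizes R², ties broken toward the longer and then the earlier window.
  The OD bounds are this package's definition of "exponential phase" for
  a 30-minute-interval photorecorder series: below 0.05 readings are
  noise-dominated, above 1.0 cultures leave exponential growth. On a
  noiseless exponential the fit is exact to floating-point accuracy; a
  flat series returns µ = 0 with R² = 0 and a `"flat"` flag rather than an
  error.
* **Welch's t-test**: closed-form unequal-variance t with
  Welch–Satterthwaite degrees of freedom, two-sided. No multiple-testing
  correction is applied by default, matching how the screen's raw
  per-strain comparisons are reported; users screening many strains can
  apply `p.adjust` to the returned p-values.
* **Generations**: `transfers × log2(1/dilution_fraction)`, assuming
  regrowth to the same density every cycle; 55 transfers at 0.2% v/v give
  ≈ 493, the arithmetic behind "approximately 500 generations".

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open everywhere internally; written call
tables and VCF output use 1-based positions. The reference strand is
normalized to `+` with strand carried on the read side, as in the TAB
dialect. Variant-base ties break alphabetically; best-alignment ties break
by seeded draw; growth-window ties break longer-then-earlier. Digestion of
a circular molecule with no sites returns the molecule whole; a linear
molecule with `k` cuts yields `k + 1` fragments and a circular one `k`.
Fragment concatenation always reconstructs the input (up to rotation for
circles), a conservation law the test suite checks on a thousand random
draws.

## Problem sizes in the test suite

The shipped tests run the full pipeline at the protocol's desk scale — a
50 kb genome plus 4 kb construct, 30× coverage per strain, 0.5% error,
fifty independently seeded resequencing runs, and two hundred random
insertions for the rescue round trip — sizes at which every stochastic
check has comfortable margins while the whole suite stays fast enough to
run on every change.

## Known limitations

* The caller has no indel, mapping-quality or base-quality model; it is a
  faithful reimplementation of a counting classifier, not a general
  variant caller.
* `locateFlank()` uses exact matching; Sanger-read errors in real flank
  sequences would need an alignment-based mapper.
* Partial digests, multi-copy/tandem integrations, star activity and
  methylation sensitivity are out of scope for the rescue model.
* The plate model has no spatial-effect correction and no standard-curve
  (4PL) conversion; inputs are raw absorbances (relative mode) or
  pre-quantified titers.
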