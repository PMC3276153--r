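---
title: "Characterizing a recent tandem segmental duplication: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a recent tandem segmental duplication: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupchar)
```

This vignette documents the models, conventions and design decisions behind
`dupchar`. The package characterizes a recently formed tandem segmental
duplication — the motivating case is the ~37.5 kb duplication behind Paris
*sex-ratio* drive in *Drosophila simulans* — from assembled sequence, and
ships a ground-truthed synthetic generator so that every stage can be
validated without external data.

## The synthetic region and what it emulates

`dup_scenario()` with no arguments describes the canonical region: a left
flank, a distal copy of 37,500 bp, a junction of six ~3.6 kb modules (each a
2,226 bp TE carrying 11 bp terminal inverted repeats, followed by two 687 bp
rIST repeat units), a proximal copy, and a right flank. The two copies
differ by substitutions at 1.25% of sites (mean identity 98.75%) everywhere
except a 10,344 bp tract that is kept 100% identical, and by six planted
indels: three microhomology-delimited deletions and one tandem-unit
insertion in the proximal copy, one tandem-unit insertion in the distal
copy, and one 65 bp neutral deletion in the distal copy of the fourth
spanned gene. Six gene intervals span the copy. All of these values are the
region's published characteristics; the generator's job is to realize them
exactly, with machine-checkable ground truth.

Deliberate simplifications, and hence what passing tests do *not* show
about real data:

* Flanks, the TE core, the rIST unit and the copy template are i.i.d.
  uniform random DNA. Real flanking sequence has repeats, composition bias
  and low-complexity runs that can seed spurious k-mer chains; the detector's
  specificity on real genomes is not exercised here beyond random-sequence
  negative controls.
* Between the copies only substitutions are simulated outside the planted
  events; the planted indels are the only gaps. This keeps the true
  alignment trivially recoverable, which is exactly what makes the ground
  truth exact — but it means alignment robustness to dense background indels
  is untested.
* No assembly errors, no N runs, no sequencing noise.

Three generator conventions deserve explanation:

* **`dup_length` is the emitted length of the distal copy.** The copies
  differ in length by the planted indels, so "the copy length" must name one
  of them; the published figure is a measured copy length, and the detector
  reports the distal extent, so the two meet. The shared pre-edit template is
  correspondingly longer (37,556 bp by default: the distal copy loses a net
  56 bp to its indels).
* **Truth is forced to be maximal.** The recorded identical tract claims to
  be the *longest* identical run, and the copy intervals claim to be the
  maximal homologous extents. A purely random realization would violate both
  with high probability (at 1.25% divergence the expected free extension
  beyond an unforced tract boundary is ~80 bp per side). The generator
  therefore forces the template bases immediately flanking the identical
  tract to differ between the copies (only when divergence > 0), and forces
  the flank bases just outside each copy boundary to differ from their
  counterpart positions. These are constraints required for the ground truth
  to mean what it says, not tuning.
* **Every TE insertion is rIST-flanked.** The junction is one leading rIST
  followed by `n_modules` × (TE + rIST + rIST); the 8 bp target-site
  duplication (TSD) is host sequence, realized as the rIST unit beginning
  and ending with the same 8 bp, masked from per-copy mutation and guarded
  against accidental extension past 8 bp. The leading rIST is recorded in
  the truth layout and reported by `decompose_junction()` as a TE-less
  element.

Other defaults chosen once: per-copy rIST divergence 0.3% (pairwise
identity ~99.4%, matching the ">99%" regime of the real tandems), per-copy
TE divergence 0.5%, flanks of 5,000 bp, the reversed module at junction
index 0, the TE length 2,226 bp (so that TE + 2 rIST = 3.6 kb exactly; the
element length is inferred from the module arithmetic, it is not an
independently published figure), and one GGATCC site planted 100 bp into
each TE (scrubbed elsewhere in the junction components) to support the
restriction-digest arithmetic. Signature positions sit in the first ~8 kb
of the copy (the region corresponding to the gene in whose intron the
repair traces were found) and the two tandem-repeat insertions beyond the
identical tract. All randomness flows from one integer seed;
identical (scenario, seed) pairs give byte-identical fixtures.

## Boundary detection

`kmer_self_matches()` enumerates all exact k-mer self-matches (default
k = 16, effectively unique in a random background of this size) on both
strands. `detect_tandem_duplication()` then

1. clusters forward matches by offset `pos_j - pos_i` (offsets within 50 bp
   belong to one chain — enough to absorb the within-chain jitter, small
   enough to keep distinct repeats apart),
2. discards chains with fewer than 5 matches (chance 16-mer repeats come as
   singletons),
3. merges chains whose extents are within 2 kb on both axes *and* whose
   offsets are within 2 kb of each other (indels between the copies shift
   the offset by their summed length, far below 2 kb; junction-internal
   repeat chains have offsets tens of kb away from the copy-to-copy offset
   and must not be absorbed — the offset test is what keeps them out),
4. takes the largest merged candidate with non-overlapping copy extents, and
5. refines all four boundaries by gapless X-drop extension (+1 match,
   −3 mismatch, drop 20), trimming back to the best-scoring position.

On the synthetic region the refinement is exact by construction (the forced
boundary mismatches stop it at the true edge); a chance run of flank
matches can move a boundary by a few bases with small probability, which is
why the end-to-end test allows a ±50 bp margin on the copy length while all
other fixture quantities are asserted exactly. The reported `copy_length`
is the distal-copy extent. The junction is the gap between the copy
intervals; inverted matches are flagged but not resolved further.

## Copy alignment

`align_copies()` produces an optimal global affine-gap alignment with
scoring (match 1, mismatch −1, gap open −5, gap extend −1) under the
convention that a gap of length L costs `|open| + L·|extend|`. Short inputs
go straight to full dynamic programming (Biostrings). Long copies use
anchor-and-fill: maximal runs of exact 20-mers unique in both copies are
chained by a weighted longest-increasing-subsequence selection, overlaps
trimmed, and the inter-anchor segments aligned by full DP — so around any
local difference the result equals the full dynamic program, which the test
suite checks directly against a brute-force Gotoh implementation on short
strings and against full DP on multi-kb constructions. Under this scoring a
mismatch (−1) always beats a 1-bp gap pair (−12), so no mismatch/gap tie
exists; residual gap-*placement* ties inside repeats are resolved by the DP
engine's deterministic traceback, and every consumer that cares
(signature classification) is made placement-invariant instead of relying
on a particular tie-break.

## Identity profiling

Windows are anchored on copy-A coordinates (window 50 bp, step 10 bp by
default). Gap columns count as differences and are attributed to their
left-flanking copy-A position (leading gaps to position 0), so that windows
with `step = window` partition the alignment columns exactly and their
weighted mean equals the global identity. Percentages are reported to two
decimals, matching the precision of the published identity figures. The
longest identical run is the maximal run of match columns (leftmost on
ties); the mean identity outside an excluded interval uses the same
gap-as-difference convention, which is why on the canonical fixture it
comes out a few hundredths below the nominal 98.75% — the planted indel
columns and the mutation-protected margins around them are part of the
denominator. The fixture tests therefore derive the expected value from the
ground truth rather than from the nominal divergence alone.

## Repair-signature classification

`extract_indels()` reports one feature per maximal gap run with the
segment and its flanking context (30 bp by default) from the copy that
carries the segment. `classify_indels()` applies two patterns:

* **tandem_repeat** — the segment is an exact repetition (unit ≥ 3 bp) of
  the immediately adjacent upstream or downstream sequence. The copy
  carrying the insertion is voted neosynthesized, with a slippage caveat:
  polymerase slippage after the duplication produces the same trace.
* **microhomology_jump** — the segment shares a terminal homology of 2–25 bp
  with the retained flank, *strictly shorter than the segment*. The copy
  carrying the gap is voted neosynthesized.

The periodicity test runs first. This ordering is deliberate: a tandem-unit
insertion *always* carries full-length flank homology (the unit equals its
neighbour), and a partial-unit gap placement carries partial homology, so a
homology-first rule would silently absorb every tandem repeat into the
microhomology class and flip its vote. Requiring microhomology to be
shorter than the gap, and letting full periodicity win, makes the two
classes mutually exclusive in practice and reproduces both planted kinds.
Because the aligner may place a gap anywhere within a repeat, each gap is
also virtually slid to its leftmost and rightmost score-equivalent
placements and classified on all three; the classification is therefore
invariant to gap placement (tested). The thresholds (min 2, max 25 bp
homology, min 3 bp unit, 30 bp context) bound chance matches — a 2 bp flank
match arises by chance with probability ~1/16 per side, which is why the
minimum is exposed as a parameter and reported with the evidence string so
users can raise it.

Polarization uses the gap-carrier convention only; comparison against an
outgroup allele to polarize indels independently is not implemented and is a
known limitation. `infer_neosynthesized()` is a plain majority vote with
ties and empty inputs reported as `undetermined`, plus per-kind and per-copy
counts and the number of slippage-flagged votes.

## Junction modules, digests, PCR

`scan_te_copies()` seeds candidate element copies with shared 12-mers on
both strands, clusters them by implied element start, and scores candidates
gaplessly at the dominant diagonal when it carries most of the consensus
(the common case for intact copies), falling back to affine-gap re-alignment
of the candidate window otherwise; overlaps are resolved greedily by score
and hits below 90% identity dropped. `detect_tir_tsd()` tests the TIR at
the element's first bases and its reverse complement at the last (a
TIR-bounded element is invariant under reverse complement, so the test is
orientation-independent) and finds the TSD as the longest exact repeat of
4–12 bp flanking both ends — exact match only, because the modelled TSD is
by definition an identical host-sequence duplication. `decompose_junction()`
tiles the junction from each TE hit to the next, so module intervals plus a
possible leading TE-less element cover the junction exactly; coverage below
95% produces a warning record rather than a failure.

`insilico_digest()` cuts at site starts (a fixed, documented convention —
the fragment arithmetic it supports is approximate to begin with), counts
palindromic sites once, and always conserves total length.
`insilico_pcr()` requires exact primer matches (≥ 15 bp) and reports
end-to-end amplicon lengths. `southern_module_count()` takes the flanking
distance explicitly because the published flank figures (1.6 + 10.1 kb)
reproduce the published module-count range only approximately —
(26−11.7)/3.6 = 4.0 and (36−11.7)/3.6 = 6.8 against a printed 4.1–6.9 — so
the operation exposes the inputs rather than hard-coding a reconciliation.
Similarly, the RT-PCR fixture encodes the published band lengths (784 and
699 bp) directly, since the published deletion size and band difference
disagree by a few bp.

## Quantification

`ddct_ratio()` aggregates multiple reference genes by the arithmetic mean
of their Cts (the geometric mean of quantities — standard multi-reference
practice), pairs replicates by index when counts match and by all pairs
otherwise, and fixes efficiency at 100% (base 2), exposed as a parameter.
`ratio_ci()` computes the mean and Student-t interval on the log2 scale and
back-transforms, because ratios are log-normal under Gaussian cycle noise;
the point estimate is thus the geometric mean. `mann_whitney()` uses
mid-ranks and enumerates all group assignments exactly up to a pooled size
of 12 (two-sided p as the probability of a U at least as far from its null
mean); beyond that it switches to the tie-corrected normal approximation
with continuity correction and says so. The exact branch exists because the
stock rank-sum test abandons exactness under ties. `copies_from_ratio()`
rounds half away from zero and reports raw values alongside, so a ratio of
1.15 over 4 copies reads as 0.6 extra copies — compatible with "no extra
copy" — rather than silently becoming 1.

Parameter recovery under the study conditions (true ratio 2.76, 6
replicates, 0.2-cycle noise) is tested over 200 seeded simulations: the
mean estimate must sit within 5% of truth and the 95% CI must cover it in
at least 90% of runs.

## The age model

The probability that two copies of a tract of length *L* remain fully
identical for *t* generations, with per-bp per-generation mutation rate μ
and recombination rate *r* (events that introduce differences from
non-carrier haplotypes), is `P = exp(-2 (r + μ) L t)` — a Poisson
zero-count over `2 L t` base-generations at rate `r + μ`. `solve_age()`
inverts it: `t = ln(1/P) / (2 (r + μ) L)`, reported in generations and in
years (default 10 generations/year), raw and rounded. With the default
parameters (r = 2×10⁻⁸, μ = 10⁻⁸, P = 0.05) and L = 10,344 the estimate is
4,826.8 generations ≈ 482.7 years, i.e. the rounded "less than 483 years".
Two caveats are attached verbally to every estimate, as flags rather than
computations: a high-frequency driving haplotype recombines with standard
haplotypes less often than *r* implies (the event may be older), and the
non-recombined region may exceed the detected tract (the event may be
younger). The solver round-trips through the survival probability to 1e-12
relative, and the closed-form scaling laws (inverse in *L* and in r+μ) are
tested exactly.

## Problem sizes and runtime choices

The unit suites run on a scaled scenario (4 kb copies, 1.5 kb identical
tract, two junction modules, one signature of each kind) that exercises
every code path in seconds; the end-to-end suite and the acceptance script
run the full-size canonical region (~107 kb, ~1 minute), where boundary
detection, the 10,344 bp run, all five signature calls, the six TE hits and
the 8 bp TSDs are recovered at their published values. Oracles are
implemented independently of the code they check: a dense Gotoh DP for
alignment scores, bitmask permutation enumeration for the rank-sum test, a
column scan for the longest run, and quadratic all-pairs comparison for
k-mer matching.

## Known limitations

* Polarization of signatures has no outgroup mode; votes rest on the
  gap-carrier convention.
* Inverted duplications are flagged, not resolved; multiple independent
  duplications in one input are not decomposed (the largest candidate
  wins).
* The TE scanner assumes a reasonably intact consensus copy (≥ 90%
  identity); heavily decayed elements need a dedicated annotator.
* The identity profile has no changepoint segmentation; recombination-tract
  boundaries are read qualitatively from the profile.
* The generator's realism limits (random background, substitutions-only
  divergence) are described above.
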