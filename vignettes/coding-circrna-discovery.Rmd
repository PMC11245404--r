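---
title: "Calling translated circRNAs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling translated circRNAs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circpep)
```

## The discovery model

A circRNA is represented by its mature circular sequence: the
concatenation of its exon blocks in genomic order, reverse-complemented
for minus-strand circles, with the back-splice junction (BSJ) defined as
the boundary between the last and the first base. Everything specific to
circRNA translation happens at that boundary, and every stage of the
pipeline is phrased in terms of junction-crossing evidence:

* **RNA level.** A circle is a *candidate* when its BSJ is supported by
  at least `min_rna_reads = 2` independent (sequence-deduplicated)
  back-spliced reads. One read is compatible with template switching or
  ligation artefacts; two independent reads are the conventional floor.
* **Ribosome level.** Footprints are matched into a *junction window* —
  the last `flank = 25` nt of the circle concatenated with its first 25
  nt — and a circle is *ribosome-associated* when at least
  `min_unique = 2` unique reads cross the boundary with at least
  `min_overhang = 4` nt on both sides. The overhang requirement rejects
  reads that merely brush the junction, where a few terminal bases can
  match either side of the joint by chance.
* **ORF level.** The mature sequence is pseudo-circularised by
  replicating it `copies = 4` times and scanned for ORFs whose start
  codon lies in the first copy. Only ORFs that cross the junction are
  retained: any ORF contained within one copy also exists on the linear
  host transcript and is not circRNA-specific.
* **Peptide level.** An observed peptide is circRNA evidence only when
  it is absent from the canonical proteome (criterion i) *and* covers
  the BSJ of a predicted CEP (criterion ii). Acceptance is controlled at
  `fdr = 0.05` by a target–decoy procedure at the peptide level only.

### Why four copies suffice

When the circle length `L` is not a multiple of 3, the reading frame
relative to the circle shifts at every wrap, so a frame returns to
itself only after three wraps. An ORF that has survived three full
wraps without an in-frame stop can therefore never terminate: it is a
rolling-circle (stop-less) ORF. Four copies give every start position in
the first copy at least `3L` nucleotides of runway, which is exactly
enough to decide between "terminates" and "stop-less" for every start.
Stop-less ORFs are truncated at the last complete codon of the
replicated sequence and flagged rather than discarded — the flag, not
the truncated length, is the meaningful quantity (see below).

### Inclusion filtering happens on the circle

When several ORFs are related by sequence inclusion, only the longest is
kept. Two terminating ORFs are inclusion-related exactly when they end
at the same circular stop codon: the codon walk backwards from a stop is
unique, so the shorter call is always a suffix of the longer one. The
implementation therefore groups calls by stop position modulo `L` and
keeps the longest, *after* junction retention. Grouping by the frame of
the linearised 4x string instead — the naive reading — misses inclusion
pairs whose starts sit in different copies whenever `L %% 3 != 0`, and
makes the call set depend on where the sequence string happens to begin.
With circular grouping the call universe is intrinsic to the circle:
rotating the mature sequence changes only which ORFs span the (moved)
junction, a property the test suite checks explicitly.

Stop-less ORFs have no intrinsic "longest" form — truncation length is
an artefact of the linearisation — so every stop-less start is emitted
and flagged, and no inclusion collapse is applied to them. Equal-length
overlapping ORFs in different frames encode different peptides and are
all kept.

### Junction residues and junction-covering peptides

The junction can fall inside a codon (one residue straddles it) or
between two codons (no single residue straddles; the flanking residues
sit on either side). A peptide *covers* the junction when its
nucleotide span crosses the boundary — a rule that handles both cases —
and the CEP database stores, per entry, the residue intervals a covering
peptide must contain. An edge case falls out naturally: an ORF whose
only post-junction codon is its stop can never produce a junction
peptide (the stop is not a residue), and such entries are excluded from
the database.

## The FDR estimator

For a score threshold `s`,
`FDR(s) = (1 + #decoys >= s) / max(1, #targets >= s)`, with q-values
taken as the running minimum over all thresholds that admit a peptide,
and targets accepted at `q <= alpha`. The `+1` makes the estimate
conservative and is the package default for a concrete reason: with the
plain decoy/target ratio, a single top-scoring target receives
`FDR = 0/1 = 0` and is accepted — under a null in which targets and
decoys are exchangeable this produces a false acceptance in roughly half
of all datasets. The acceptance suite verifies, over 500 null
repetitions with 200 targets and 200 decoys each, that the mean realized
FDR of the accepted set stays at the nominal level; the uncorrected
ratio (`correction = "none"`) is retained as an option for comparison
with tools that use it. A consequence of the `+1` worth knowing: no
acceptance is possible unless at least `1/alpha` targets outrank the
decoys (20 targets at 5%), which is the statistically honest behaviour
for very small experiments.

FDR is controlled within each sample by default (`pool = "sample"`);
pooling across samples is available. Protein-level FDR is deliberately
not applied: CEPs are short, yield very few theoretical peptides each,
and a protein-level correction would be dominated by that artefact.

## Parameters at a glance

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `flank` | 25 | nt | window of ±25 nt around the BSJ captured by footprints |
| `min_unique` | 2 | reads | unique junction reads required for ribosome association |
| `min_overhang` | 4 | nt | minimum read overhang on each side of the BSJ |
| `min_rna_reads` | 2 | reads | independent back-spliced reads for candidacy |
| `copies` | 4 | — | pseudo-circularisation copies (3 wraps + start runway) |
| `start_codons` | ATG, CTG, GTG, TTG | — | canonical plus near-cognate initiators |
| `min_peptide_len` | 11 | aa | CEPs must exceed 10 aa to be detectable/searchable |
| `fdr` | 0.05 | — | peptide-level acceptance threshold |
| `max_mismatch` | 0 | nt | substitution budget of the window matcher |
| `missed_cleavages` | 0 | — | tryptic digestion setting shared by all databases |

Read matching is substitution-only (Hamming) within the 50-nt window: at
window scale an indel-tolerant aligner adds nothing but ambiguity.
"Unique" reads means distinct read sequences per junction; distinct
alignment offsets can be selected instead (`dedupe_unique(by =
"offset")`). Reads are matched in the given orientation — mature
sequences are strand-resolved, and a reverse-complement pass is the
caller's choice. `N` bases never match anything, including other `N`s:
an ambiguous base cannot support evidence. A read hitting several
junctions counts toward each, which is how several circles sharing one
junction are all credited.

## Physicochemical calculators

Molecular weight uses average residue masses plus one water
(18.0153 Da). The theoretical pI solves `charge(pH) = 0` by bisection on
pH 0–14 to a default interval width of 0.001; the charge model is the
Bjellqvist set used by the familiar web calculators, including the
residue-specific pKa corrections for N-terminal A/M/S/P/T/V/E and
C-terminal D/E. Net charge is strictly decreasing in pH, so the root is
unique (also asserted numerically in the tests). The instability index
is the Guruprasad dipeptide-weight sum scaled by `10/L`, with `II < 40`
classified stable; a length-1 sequence has no dipeptides and gets 0 with
a warning. GRAVY is the mean Kyte–Doolittle hydropathy, bounded by
[-4.5, 4.5]. All calculators are case-insensitive and reject ambiguous
residues (B, J, O, U, X, Z) — predicted CEPs cannot contain them, so a
rejection always indicates an input problem. The test suite pins all
four calculators to 50 frozen values from an independent reference
implementation within 0.01 units.

Group comparisons follow the conventions of the field: distributional
shapes (length, theoretical tryptic peptide count) by two-sample
Kolmogorov–Smirnov; location shifts on skewed quantities (molecular
weight, GRAVY) by Mann–Whitney U; the stable/unstable split by
chi-square on the 2×2 table, without Yates correction by default (the
correction is available). Direction summaries are CEP minus LEP.

## The translation ratio

`TR = (junction footprint count / ribosome library size) /
(BSJ read count / RNA library size)` — the relative enrichment of a
junction in ribosome-protected fragments over its RNA abundance. It is
computed as a product of two ratios so that jointly rescaling both
library sizes cancels exactly in floating point, not merely to rounding.
Records with zero RNA support are reported with `TR = NA` and excluded
from comparisons rather than imputed (the default pseudocount is 0).
Groups of TRs are compared by two-sample Kolmogorov–Smirnov tests with a
median-difference direction summary.

## What the synthetic data emulates — and what it does not

`simulate_circ_dataset()` generates, from one seed: a random four-
chromosome genome with multi-exon genes; one circle per gene (contiguous
exon runs, 100–3000 nt); a planted junction-spanning ORF in a
configurable fraction of circles (default 30%); junction footprints for
coding circles (default depth 20, lengths 25–35 nt peaked at 28–30,
frame-biased 5' ends with `frame0_prob = 0.7`, substitution errors at
0.001/nt); at most one stray junction read for noncoding circles plus
non-junction background reads; BSJ-level RNA support (5–50 reads per
circle); and peptide identifications mixing true junction peptides
(normal scores, mean 30, sd 3), canonical tryptic peptides, decoy-
derived fragments and random noise (mean 12, sd 3). Planted ORFs place
the start codon at least 4 nt before the junction, the stop after the
wrap, and keep the interior free of K/R so that one junction-covering
tryptic peptide is guaranteed; the designed sequences are written back
into the genome so the BED12 + FASTA route reproduces them exactly.

Noncoding circles are *actively scrubbed*: candidate sequences are
rejection-sampled (up to 50 attempts) until they carry no junction-
spanning ORF that would enter the CEP database. Random sequence carries
such ORFs surprisingly often, so without scrubbing the negatives would
be meaningless; circles where scrubbing fails are flagged
`coding_ambiguous` in the truth manifest and excluded from the negatives
of the ORF-stage evaluation.

The generator is junction-centric by design: it does not simulate full
linear-transcriptome reads, rRNA contamination, indels, base-quality
models, or footprints from the linear host isoform competing for the
junction. Consequently, passing tests demonstrate that the *inference
chain* is correct under its stated assumptions — they do not certify
performance on real libraries, where the linear-unmapped pre-filter
(recorded as a provenance flag) and rRNA cleanup happen upstream. Score
distributions for true and noise peptides are well separated by default;
sensitivity claims are conditional on that separation, while the FDR
guarantee is tested precisely where separation fails (the null
simulation).

Problem sizes in the shipped tests were chosen to make every statistical
check sharp at interactive runtimes: the end-to-end recovery runs on the
generator's default 100 circles; oracle equivalence uses 200 random
circles up to 60 nt; the null-FDR simulation uses 500 repetitions of
200 targets + 200 decoys; periodicity checks use 10,000–30,000 offsets.

## Degenerate inputs and tie-breaks

* Circles shorter than one codon produce no ORFs, with a warning;
  circles shorter than `flank` use their whole sequence on each side of
  the window and are flagged `short_circle` (windows are truncated, not
  wrapped — a wrapped window would let one read be counted twice).
* Equal-length ORF ties across frames are kept (distinct peptides);
  within a circular stop group the longest call is unique by
  construction.
* Identical peptides predicted from different circles stay as separate
  database entries in one ambiguity group; an accepted shared peptide
  credits every member circle, flagged `shared`, and unique/shared
  counts are reported separately.
* I and L are treated as distinct by default (`il_equivalent = TRUE`
  merges them for mass-spectrometry-style ambiguity).
* Decoys are resampled on collision with any target or canonical
  peptide (at most 100 attempts, then an explicit degenerate-alphabet
  error).

## Known limitations

The matcher is exhaustive within windows and not meant for genome-scale
alignment; upstream mapping decides which reads are "linear-unmapped",
and how multi-mapping footprints were resolved upstream is outside the
package's control. Stop-less ORF truncation lengths depend on the
(arbitrary) sequence origin. The ORF caller reports the 5'-most start
per stop; internal-start isoforms are not enumerated. P-site offsetting
and per-codon occupancy are out of scope — junction coverage, not coding
frame inference, is the evidentiary unit.
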