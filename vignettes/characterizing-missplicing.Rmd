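---
title: "Characterizing mis-spliced events against matched control constructs"
author: "spliceprops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing mis-spliced events against matched control constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceprops)
```

## The problem

When a core spliceosomal factor is depleted — for example EFTUD2, the
U5 snRNP GTPase whose haploinsufficiency causes mandibulofacial dysostosis —
the transcriptome accumulates mis-splicing: exons skipped more or less than
in wild-type cells, introns retained more or less, alternative 5'/3' splice
sites and mutually exclusive exons. Differential-splicing callers such as
rMATS enumerate these events, but the interesting downstream question is
*which cis-features make particular exons and introns vulnerable*: weak
donor or acceptor splice sites, short or long introns, GC content, the
distance between the branch point and the 3' splice site, and whether a
retained intron introduces a premature termination codon (PTC) that routes
the transcript into nonsense-mediated decay (NMD).

`spliceprops` implements that downstream characterization as a reusable,
testable pipeline:

1. parse rMATS-style event tables (SE, RI, A5SS, A3SS, MXE) and keep events
   with p < 0.05 and FDR < 0.05 (both strict);
2. build two matched background sets per event class — *internal* controls
   drawn from elsewhere within the same genes (exon–intron–exon, E-I-E, for
   retained introns; E-I-E-I-E for skipped exons) and *external* controls
   drawn from the most highly expressed unaffected genes;
3. train donor/acceptor positional log-odds models from the supplied
   annotation and score splice sites in MaxEntScan-compatible windows;
4. predict branch points and BPS–3'SS distances;
5. extract per-item feature vectors, classify the coding consequence of each
   retained intron, and compare event groups against both control sets with
   Welch t tests and multiple-testing adjustment;
6. screen for discriminative k-mers enriched in event sequences relative to
   the control constructs.

Because the original study's inputs (a deep paired-end RNA-Seq experiment,
cluster-scale alignment and rMATS runs) are not reproducible at desk scale,
the package ships a synthetic-data generator that emulates all four inputs
with configurable planted effects and a ground-truth manifest. Every stage
of the pipeline is validated against that ground truth.

## Event model and direction convention

rMATS reports `IncLevelDifference = IncLevel1 - IncLevel2`. With group 1 =
wild type, a negative difference means the focal form is *more included in
the mutant*: increased retention for an RI event, decreased skipping for an
SE event. Because nothing in the tables records which group was which, the
pipeline makes `g1_is_wildtype` a mandatory configuration flag with no
default — a silent sign flip would invert every direction-stratified
result. Groups are labelled as in the field's figure conventions: IRI/DRI
(introns retained more/less in the mutant), ISE/DSE (exons skipped
more/less), ICI/ECI and ICE/ECE for internal/external control introns and
exons.

A zero inclusion difference is treated as an error rather than assigned
arbitrarily: after the significance filter such an event should not exist,
and guessing a side would corrupt the direction-stratified group means.

## Control constructs

Internal controls are enumerated exhaustively: every window of the required
shape over consecutive exons/introns of the gene's *reference transcript*,
excluding any window whose genomic span overlaps the footprint of **any** of
that gene's filtered events (of any class, not only the class being
matched — the strictest reading, which prevents an RI control from sitting
inside an SE event). One window is sampled uniformly per event under the
run's seed. Transcripts with few exons legitimately yield no candidate; the
pipeline counts these rather than forcing a construct.

The reference transcript is the longest protein-coding transcript (summed
exon length, i.e. mature transcript length — not genomic span) that carries
a parsed transcript support level. Ties are broken by lowest TSL, then by
transcript id, so selection is deterministic. Transcripts whose TSL
attribute is missing or `"NA"` never qualify.

External controls come from the `external_pool_size` most expressed genes
(default 1200, matching the scale of the original design; small fixtures
override this) that are not mitochondrial, not present in any filtered
event table, have a qualifying reference transcript, and — for the
five-segment shape — at least three exons. Expression is used exactly as
supplied in the two-column table; ties are broken by gene id.

## Splice-site scoring

The original analysis scored sites with MaxEntScan's published
maximum-entropy tables. This package instead trains a first-order
positional log-odds model from the annotation it is given: donor windows
are the last 3 exonic plus first 6 intronic nt (9-mer), acceptor windows
the last 20 intronic plus first 3 exonic nt (23-mer) — the same window
conventions as MaxEntScan, so externally supplied score tables plug in
unchanged through `load_external_score_tables()`. Training uses each
reference transcript's GT..AG introns (unique by coordinates and strand;
windows containing N and introns shorter than the intronic window part are
skipped and counted), probabilities are smoothed with a pseudocount of 0.5,
and the score of a window is `sum_p log2(p[pos, base] / background[base])`
in bits.

Two points matter for interpretation. First, the claims this pipeline
supports are **group comparisons** of strengths; any calibrated monotone
scorer supports those, which is why a self-contained trained model is an
acceptable stand-in for the published tables. Absolute bit values are not
comparable between scorers. Second, the background is the genome's
mononucleotide composition *symmetrized over strands* (A pooled with T, C
with G, N excluded). A strand-symmetric background is the natural choice
for a double-stranded substrate and makes trained models exactly invariant
under reverse-complementing the genome together with its annotation — an
invariance the test suite asserts.

## Branch points

The branch point is called by a deterministic consensus scorer: every
adenosine whose distance to the intron's 3' end lies in `[search_min,
search_max]` (defaults 15 and 500 nt — stated choices, since no settings
were published for the original SVM-based analysis) is scored as the sum of
a fixed 7 x 4 log-odds matrix over the 7-mer centred on the A (branch A at
position 5), plus `ppt_weight` (default 2 bits) times the pyrimidine
fraction of the following 25 nt (the polypyrimidine tract). The single
best-scoring candidate is reported; ties go to the candidate closest to the
3' splice site. Reporting a single best candidate is an explicit
interpretation — the reported quantity of interest is the BPS–3'SS
distance, which needs exactly one deterministic call per intron.

## Coding consequence of intron retention

For an RI event resolvable to an annotated intron of a CDS-bearing
reference transcript, the classifier computes the codon phase at the intron
insertion point from the CDS annotation and scans the retained intron —
including codons spanning its junctions — for TAA/TAG/TGA:

* a stop overlapping the intron → `in_frame_stop`;
* otherwise, if the intron length is not a multiple of 3, scanning
  continues in the shifted frame through the remaining exonic CDS up to the
  transcript's annotated stop; a hit → `frameshift_ptc_downstream`. The
  scan deliberately stops at the annotated stop: a stop codon at or beyond
  the normal one is not premature;
* a frame-preserving intron without stops → `no_ptc` (a potentially
  functional retained intron);
* no usable CDS context → `frame_unavailable`.

The test suite checks this classifier against an independent brute-force
oracle that reconstructs the retained-intron coding sequence, translates
it, and locates the first stop — 500/500 agreement on randomized
constructs. Control constructs are classified too when CDS context exists,
but consequence summaries are reported for event RIs only.

## Statistics

Group comparisons use Welch's unequal-variance unpaired t test (the safer
reading of "unpaired t tests", and asymptotically identical under equal
variances), with a Kolmogorov–Smirnov normality p-value attached per group
for information only. P-values across a summary table are adjusted with
Benjamini–Hochberg by default; Bonferroni is available, and both raw and
adjusted values are emitted because the original figures do not state which
drove their significance marks. Verdict phrases ("Lower than internal and
external controls", "No significant difference", ...) are composed from the
adjusted comparisons against each control set separately.

The motif screen deliberately replaces a discriminative EM motif finder
with an exact k-mer presence/absence test: for each k in `[k_min, k_max]`
(defaults 5–8 for the operation; the pipeline defaults to 5–6 at fixture
scale), k-mers present in at least 20% of foreground sequences are tested
with the statistic fg-fraction minus bg-fraction under a label-permutation
null, BH-adjusted across all tested k-mers. This preserves the scientific
question — are specific sequences enriched in mis-spliced items versus
matched controls? — with a statistic that is exactly testable. Note that
the prevalence screen conditions on the observed labels, so permutation
p-values are interpreted for the screened candidates; the machinery itself
is validated separately with the screen disabled.

## The synthetic generator

`synthetic_config()` defines the study conditions; its defaults are fixed
and are what the acceptance checks run under:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 400 | genes on a few synthetic chromosomes plus a `chrM` decoy |
| `intron_len$background` | log-normal, median 1500 nt, sdlog 0.6 | control/background introns |
| `intron_len$ri_increased` | median 300 nt, sdlog 0.5 | introns retained more in the mutant (planted shorter) |
| `donor_strength_delta_bits` | 3 | expected donor-score deficit of event sites |
| `bp_offset` | background 20–50 nt, event 25–70 nt | planted BPS–3'SS distances |
| `frac_ri_with_inframe_stop` | 0.93 | fraction of RI events planted with an in-frame stop (exact: `round(frac * n)`) |
| `frac_ri_frameshift` | 0.02 | planted frameshift-PTC fraction |
| `n_ri_events`, `n_se_events` | 60 each | split evenly between directions |

Donor/acceptor windows are sampled from generator position-probability
matrices; event-cohort sites come from a *weakened* matrix obtained by
mixing each position with the uniform distribution over its own support,
with the mixing weight solved numerically so the expected score drops by
the requested number of bits under the generator's own log-odds. Because
the pipeline's trained scorer differs from the generator's matrices, the
planted deficit is meaningful only approximately in trained-score space;
validation therefore asserts direction and significance of group
differences, not absolute bit recovery.

Structural invariants make ground truth exact: every exon's CDS portion is
a multiple of 3 with phase 0 at each intron, every intron is GT..AG and
ends `CAG`, the acceptor polypyrimidine tract contains no adenosine, and
all competing adenosines in the 3'SS-proximal scan window are masked so the
planted branch 7-mer (TACTAAC, or the stop-free-in-every-frame variant
TACCAAC for retained introns planted without stops) is provably the unique
best candidate. Stop codons are planted or scrubbed codon-aligned, away
from the planted splice elements, so the requested consequence-class counts
are hit exactly. `mirror_dataset()` reverse-complements every chromosome
and flips all coordinates and strands; it is an involution and a pipeline
run on the mirror must reproduce every feature value.

What the generator does **not** emulate: read-level noise in inclusion
estimates, multiple transcripts per gene, non-canonical splice sites,
overlapping genes, alternative promoters/UTR structure, and realistic
correlations between features (length, GC and site strength are planted
independently). Passing tests therefore demonstrate the pipeline's
correctness and calibration on data satisfying its assumptions, not the
biological conclusions of any particular dataset. The paper-scale numbers
(thousands of events against a full human annotation) are outside desk
scale by design; the synthetic defaults above are the package's chosen
validation conditions, with `n_genes = 400` and an external pool of 150 at
acceptance scale keeping a complete run within minutes.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; conversion
  happens only at file boundaries (GTF is 1-based closed; rMATS
  `...Start_0base`/`...ES`/`...End`/`...EE` columns are already half-open).
* Items with N inside a scoring window are excluded from strength
  comparisons (flagged, counted) but keep their length/GC features.
* `gc_content` excludes N from numerator and denominator and errors on
  empty or all-N input; `fraction_below` uses strict inequality.
* Introns too short for a window (donor needs 6 intronic nt, acceptor 20,
  branch search `search_min + 7`) are skipped with counts, not errors.
* All sampling flows through one seeded RNG in a fixed stage order
  (internal RI, internal SE, external E-I-E, external E-I-E-I-E, then
  permutations), so identical inputs + configuration + seed give
  byte-identical outputs; run reports store file basenames and no
  timestamps for the same reason.

## Known limitations

* The trained scorer is first-order (no positional dependencies), so its
  absolute scores are not MaxEntScan scores; supply published tables via
  `scorer_mode = "external_tables"` for parity.
* The branch-point caller is a consensus heuristic; on real introns with
  degenerate branch points the single-best-candidate rule underestimates
  multiplicity.
* Internal controls for A5SS/A3SS/MXE events are out of scope (the
  characterization covers RIs and SEs); those events are still parsed,
  filtered, direction-classified, counted, and contribute to the external
  exclusion set.
* The k-mer screen caps k at 8 by default; longer motifs are representable
  but combinatorially sparse at fixture scale.
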