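---
title: "Methods: in-silico proteolysis and bioactive peptide profiling of alpha-zeins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico proteolysis and bioactive peptide profiling of alpha-zeins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zeinpep)
```

## The problem

Corn alpha-zeins, the dominant prolamin storage proteins of the maize
endosperm, are unusually rich in leucine, proline, alanine and glutamine.
Short fragments of them -- released by digestive or industrial proteases --
can inhibit angiotensin-converting enzyme (ACE, blood-pressure regulation),
dipeptidyl peptidase IV (DPP-IV, incretin degradation) and DPP-III, scavenge
radicals, and carry a range of other activities catalogued in bioactive
peptide databases. `zeinpep` implements the desk-scale screening workflow for
such proteins: pick non-redundant representatives from the catalogued
alpha-zein paralogs, match a motif database against the intact sequences,
simulate proteolysis, and score each protein--activity combination with the
occurrence-frequency statistic.

## The occurrence-frequency statistic

For one protein of $N$ residues and one activity, the statistic is

$$A = \frac{a}{N}$$

rounded half-up to four decimals. In **profile mode** (intact protein), $a$
is the total number of positional occurrences, overlapping occurrences
included, summed over all motifs annotated with the activity. In **digest
mode**, $a$ is the number of *released peptide instances* whose full
sequence equals a motif of the activity -- multiplicity counted, substrings
not counted (a released 5-mer containing a bioactive dipeptide contributes
nothing); $N$ remains the parent protein's residue count.

Three conventions are pinned by worked checks in the test suite:

* **Denominator.** Source material for this statistic sometimes prints the
  formula as $a/4N$, but every tabulated reference value satisfies $a/N$
  (e.g. one `IR` occurrence in the 230-residue P06674 gives $1/230 =
  0.0043$, the catalogued CaMPDE-inhibitor value). We implement $a/N$.
* **Overlap and multiplicity.** The P06674 DPP-III count decomposes as
  $4\cdot YL + 1\cdot YR + 1\cdot HL + 7\cdot LA + 5\cdot FL + 6\cdot PF =
  24 = 0.1043 \times 230$; only positional, overlapping counting reproduces
  it.
* **Rounding.** Half-up to 4 decimals matches every reference value; base
  R's banker's rounding does not (`round_half_up()` is exported).

## Sequence records and identity grouping

`read_fasta()` parses headers as `accession name...`, strips all whitespace
(printed sequence blocks carry line-wrap spaces), uppercases, and validates
against the 20 canonical residues. A catalogued length that disagrees with
the sequence sets a `length_mismatch` flag -- it is never silently
reconciled. The packaged P04705 block is such a case (180 residues printed,
186 catalogued).

`percent_identity()` uses a global Needleman--Wunsch alignment
(`Biostrings::pairwiseAlignment`) with an identity scoring scheme: match
+1, mismatch 0, affine gaps with opening 10 and extension 0.5. Identity is
the number of identical aligned positions divided by the alignment length
excluding end gaps. This is deterministic and adequate for a 90% same/
different call; it does not reproduce BLAST's local-alignment percentages
cell by cell, which is why the packaged pairwise matrix
(`table1_identity.tsv`) can be supplied to `group_by_identity()` directly.

Grouping is the single-linkage closure of the pairwise graph at the
threshold: two accessions share a group iff a chain of pairs at or above
the threshold connects them. Representatives are the longest sequence per
group, ties broken lexicographically. A consequence worth knowing: on the
published 17-accession matrix the two 19-kDa subfamilies (around P06674 and
around P06676) are chained into a single component through the
Q548E7--B6SHV3 pair (97.0%), so single linkage yields 5 groups where the
original narrative kept P06674 and P06676 as separate representatives
(their direct identity is only 70.5%). Single linkage was chosen because
the source describes pairwise same/different calls, not an algorithm, and
the chain rule is the weakest closure consistent with them.

## The motif database

`motif_db` objects hold (motif, activity, source) rows: motifs of 1--25
canonical residues, activities from a controlled vocabulary
(`activity_vocabulary()`), pairs unique, one motif possibly carrying many
activities. The packaged database (`biopep_subset_tables23.tsv`, 370
pairs; rebuilt programmatically by `build_fixture()`) is the union of
every fragment listed in the six printed per-protein table blocks, digest
columns included. It is a strict subset of the BIOPEP-UWM database; a full
user-exported TSV loads through the same `load_motifs()` path. Tokens with
non-canonical letters (the OCR artefact `OS`, and `O` inside longer
table-4 tokens) are excluded and reported, not guessed.

The vocabulary carries the 32 legend activities plus the five labels that
occur only in individual table blocks (alpha-amylase inhibitor, celiac
toxic, opioid, immunostimulating, alanine carboxypeptidase inhibitor);
without them the packaged fixture itself would be rejected.

## Golden tables and flagged inconsistencies

`golden_tables()` ships every printed (protein, mode, activity) cell with
its fragment list and 4-decimal frequency, plus an `inconsistent` flag.
Three whole blocks (P06678, P06679, P04705) are flagged: their printed
sequences or frequencies contradict themselves (fragments that never occur,
frequencies implying a different $N$). Brute-force re-counting on the
printed sequences additionally flags seven rows inside the otherwise
consistent blocks -- the three ACE profile rows, P06676 alpha-glucosidase
and DPP-IV (its printed fragment `DQ` never occurs), and the two Q94IM1
"stimulating" rows, where the printed 0.0639 equals the glucose-uptake
value but the six printed dipeptides occur only 16 times ($16/266 =
0.0602$). Flagged rows are transcribed verbatim and excluded from golden
regression checks; they are listed by `reproduce_golden()`. All 67
unflagged profile rows are reproduced exactly.

## Simulated proteolysis

A cleavage rule is data, not code: a P1 residue set (cut after these) and
an optional P1' exclusion set (cut suppressed before these), stored in
YAML (`inst/extdata/enzymes.yaml`). Bonds are indexed 0-based: bond $i$
lies between residues $i$ and $i+1$. Multi-enzyme digestion is
simultaneous: one pass at the union of all sites, modelling co-incubation;
because rules are context-local, iterated re-digestion would change
nothing (released peptides are fixed points, a tested invariant along with
conservation -- released peptides always tile the parent exactly).

The verbal specificities behind the defaults are: trypsin after K/R;
chymotrypsin after F/Y/W; pepsin after F/L/E; subtilisin after "large
uncharged" residues. Because the exact dialect used by database digestion
tools is not published, `calibrate_rules()` scores candidate variants
against the digest columns of the golden tables (consistent blocks only):
a cell is a hit when both the released-fragment set and $A$ match exactly.
The shipped defaults are the winners: pepsin {F,L,E}, trypsin {K,R} and
chymotrypsin {F,Y,W} with the classical proline block (all proline-block
choices tie on these data; the conventional variant is listed first and
wins the tie), and subtilisin {F,L,I,M,V,W,Y,A} without a block -- the
"+A" reading of "large uncharged" outscores the narrower set 9 to 6 cells.

The calibration ceiling is low and irreducible: the winners reproduce
15/29 gastrointestinal and 9/27 subtilisin cells. The golden digest
columns cannot be matched by *any* context-local P1/P1' rule set: released
fragments such as Q94IM1 `MNP`, `PP`, `VAY` and `VN` would require cuts
after proline or asparagine that would shatter other golden fragments;
P06674's gastrointestinal column lists `IR` though no stated specificity
cuts an N--I bond; and one golden cell implies a non-integral count (3
fragments with $A = 0.0083$ on $N = 240$, i.e. $a = 1.99$). The harness
therefore itemizes every residual mismatch rather than forcing a fit, and
the digest columns are treated as calibration evidence, not blind targets.

## Ranking

Bioactivity-likelihood scores in $[0,1]$ (e.g. PeptideRanker output) are
consumed as data; the neural network itself is out of scope.
`filter_by_score()` applies a strict `>` threshold (study convention 0.8)
and orders by descending score. The packaged score table keeps duplicated
peptides (PF, AFL) as single entries with merged activity annotations,
flagged in a `merged` column rather than silently deduplicated.

## Synthetic data

The generator exists so every stage is testable without external data:

* `synth_background()` -- i.i.d. residues from a given composition
  (default uniform; a zein-like composition uses leucine 0.193, proline
  0.090, alanine 0.083). Seeded, and the global RNG stream is untouched.
* `plant_motifs()` -- overwrites non-overlapping random windows with motif
  copies, then *re-scans* the result so the recorded truth reflects actual
  occurrences (accidental background matches included). With motif
  alphabets disjoint from the background, truth counts equal planted
  counts exactly and profiling must recover them.
* `sequence_with_cuts()` -- concatenates fragments engineered to be
  exactly the released peptides of a rule set, with precondition checks
  (terminal P1 residue, no internal sites, no blocked junction) that
  report the offending fragment.

What the generator does **not** emulate: residue autocorrelation, the
tandem-repeat architecture of real zeins, homology between sequences, or
partial/kinetic digestion. Passing recovery tests therefore demonstrates
correctness of the counting and cutting machinery, not realism of the
sequences.

## Numerical and scale choices

Rounding is half-up at 4 decimals with a $10^{-9}$ guard against binary
representation of exact halves. Frequency comparisons against 4-decimal
reference values use an absolute tolerance of $5\times10^{-5}$ (half a
unit in the last printed place). Report ordering and all character sorts
use byte order (radix), independent of locale. The property suites run
1,000 random digests (lengths 5--120), 1,000 occurrence-oracle pairs
(lengths 2--80, motifs 1--5), and 100 seeded synthetic instances for
planted-motif and planted-cut-site recovery; these sizes keep the full
suite in the low minutes while exercising every branch of the engines.

## Known limitations

* The packaged motif database covers only motifs printed in the six
  reference blocks; genome-wide aggregate statements (e.g. activity counts
  across all 17 paralogs) require a full BIOPEP-UWM export, which the
  loader accepts but cannot ship.
* Digest-mode reference columns are only partially reproducible (see the
  calibration section); residual mismatches are reported, by design.
* Identity percentages differ from BLAST's; only the thresholded
  same/different structure is reproduced, and the packaged pairwise matrix
  can be used verbatim instead.
* Scores are external inputs; no bioactivity likelihood is computed.
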