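# zeinpep

In-silico proteolysis and bioactive peptide profiling of corn
(*Zea mays*) alpha-zein storage proteins.

Alpha-zeins — the major prolamins of the maize endosperm, in 19-kDa and
22-kDa classes — are a cheap, abundant protein source whose hydrolysis
releases short peptides with documented ACE-inhibitory (antihypertensive),
DPP-IV-inhibitory (antidiabetic), DPP-III-inhibitory and antioxidative
activity. `zeinpep` is for food-protein and peptidomics researchers who
want a reproducible desk-scale screen of such proteins:

* **Sequence handling** — FASTA records with strict alphabet validation,
  global-alignment percent identity, and single-linkage grouping of
  paralogs at an identity threshold (default 90%) to pick non-redundant
  representatives.
* **Motif profiling** — a database of short bioactive motifs (packaged:
  370 motif–activity pairs across 35 activities, distilled from published
  alpha-zein screens; any BIOPEP-style TSV export loads the same way)
  matched against intact sequences.
* **Simulated proteolysis** — composable P1/P1′ cleavage rules for
  pepsin, trypsin, chymotrypsin and subtilisin, applied simultaneously in
  one pass, plus a calibration harness that ranks rule variants against
  golden digest tables.
* **Scoring** — the occurrence-frequency statistic and strict threshold
  filtering of externally scored peptides (e.g. PeptideRanker, threshold
  0.8).
* **Synthetic ground truth** — seeded background sequences, planted
  motifs and engineered cleavage sites for end-to-end testing.

The core statistic is the frequency of occurrence of bioactive fragments:
for a protein of *N* residues and one activity,

```
A = a / N        (rounded half-up to 4 decimals)
```

where *a* counts, in **profile mode**, all (possibly overlapping)
positional occurrences of the activity's motifs in the intact sequence
and, in **digest mode**, the released peptide instances exactly equal to a
motif (multiplicity counted, substrings not).

## Worked example

```r
library(zeinpep)

recs <- read_fasta(system.file("extdata", "alpha_zein_printed.fasta",
                               package = "zeinpep"))
db   <- load_motifs(system.file("extdata", "biopep_subset_tables23.tsv",
                                package = "zeinpep"))

prof <- profile_potential(recs$P06674, db)
subset(prof, activity %in% c("CaMPDE inhibitor", "Hypouricemic",
                             "Dipeptidyl peptidase III inhibitor",
                             "Xaa-Pro inhibitor"))
#>                            activity              fragments  a   N      A
#>                    CaMPDE inhibitor                     IR  1 230 0.0043
#>  Dipeptidyl peptidase III inhibitor FL, HL, LA, PF, YL, YR 24 230 0.1043
#>                        Hypouricemic                 LT, PT  3 230 0.0130
#>                   Xaa-Pro inhibitor                     PL  3 230 0.0130
```

The 230-residue zein P06674 contains a single `IR` (a CaMPDE-inhibitor
motif), so A = 1/230 = 0.0043; its DPP-III motifs occur 24 times in total
(4·YL + 1·YR + 1·HL + 7·LA + 5·FL + 6·PF), giving A = 0.1043. Digesting
the same protein and profiling only the released peptides:

```r
d <- digest(recs$P06674, "subtilisin")
d
#> <digest_result> P06674 | subtilisin | 118 cut(s), 119 peptide(s)
head(profile_digest(d, db), 3)
#>                                   activity                  fragments  a      A
#>                              ACE inhibitor CF, GI, GL, HL, PF, PL, RA 12 0.0522
#>  Activating ubiquitin-mediated proteolysis                         RA  1 0.0043
#>                              Antioxidative                         HL  1 0.0043
```

Grouping the 17 catalogued alpha-zein accessions with the packaged
pairwise identity matrix:

```r
grp <- group_by_identity(zein_catalog(), threshold = 90,
                         pairs = read.delim(system.file("extdata",
                           "table1_identity.tsv", package = "zeinpep")))
grp
#> <identity_grouping> threshold=90%, 5 group(s)
#>   [P04698] P04698, Q94IM1
#>   [P04700] P04700, P06679
#>   [P04705] P04705
#>   [P06678] P06678
#>   [Q548E7] B6SHV3, B6SIF7, P02859, P04702, P04703, P04704, P06674, ...
```

A command-line front end wraps the same functions
(`inst/cli/zeinpep profile|digest|rank|cluster|reproduce|synth`); see
`?zp_cli`.

The methods vignette (`vignettes/zeinpep-methods.Rmd`) documents the
statistic's conventions, the cleavage-rule calibration and its limits, the
flagged inconsistencies in the golden tables, and what the synthetic
generator does and does not emulate.

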