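---
title: "Methods: reference-anchored conservation and constriction-site analysis of FNT channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-anchored conservation and constriction-site analysis of FNT channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fntscan)
```

## The coordinate system

Every analysis in fntscan is expressed in the residue numbering of the
*E. coli* FocA crystal structure (PDB 3KCU), the common reference frame for
the Formate/Nitrite Transporter (FNT) family. The frame declares ten
secondary-structure segments — TM1 31–56, TM2a 64–85, Ω-loop 86–93, TM2b
94–101, TM3 107–134, TM4 161–184, TM5a 188–204, S-loop 205–209, TM5b
210–224, TM6 247–275 — and the two constriction sites: the central
constriction (75, 202, 209, 212) and the cytoplasmic slit in its closed
(79, 89, 91, 175) and open (79, 89, 90, 172, 175) states. TM2a, the
Ω-loop and TM2b are contiguous in the numbering, as are TM5a, S and TM5b;
real inter-segment loops exist only at five places (loops A–E) plus the
termini.

The bundled reference *sequence* is synthetic: it satisfies every residue
the family literature asserts for specific positions (Phe-75, His-209,
Asn-262, the glycines of the helix-interface positions, and so on) but is
not the crystal sequence, which we do not redistribute. The annotation
file documents its own schema, and `load_reference()` accepts a
user-supplied annotation, so the real sequence can be dropped in without
code changes. Validation is strict: wrong segment count or order,
overlapping bounds, site positions outside segments, or a sequence that
contradicts an asserted residue all fail loudly, naming the position.

## Position mapping as a proxy for structure-based alignment

The family is too diverse for naive multiple alignment, and the original
analyses anchored sequences via homology models. fntscan substitutes a
sequence-level proxy: global pairwise alignment to the reference with
affine gaps (BLOSUM62, gap open 11, extend 1), free end gaps so that long
N/C-termini are not penalised, and the gap-open penalty multiplied by 3
wherever a gap would fall between two segment-covered reference positions.
That last rule implements "no gaps inside transmembrane regions": it
applies inside each segment *and* at the junctions of numbering-contiguous
segments (Ω|TM2b, S|TM5b, …), where there is no loop to absorb an indel —
restricting the inflation to single segments measurably allowed
one-residue register shifts across those junctions on synthetic cohorts.

Traceback ties are resolved deterministically (aligned pair, then gap in
query, then gap in reference), so maps are reproducible. The DP kernel is
~100 lines of Rcpp; an independent pure-R Gotoh implementation serves as a
brute-force oracle in the test suite (50 random pairs per run, score
equality to 1e-9). Ambiguity codes (X, B, Z, U) are accepted but score at
the substitution floor, so they can never create favourable matches.
Alignments scoring below a configurable floor (default 60) raise an
`fnt_unalignable` condition, which the QC stage records as a discard
reason.

The result of mapping is a monotone map from every reference position
31–275 to a query index or gap, plus per-segment coverage fractions. All
downstream statistics operate on these maps, never on raw alignments.

## Sequence QC

Records shorter than 150 residues are discarded (`too_short`): a complete
FNT channel must hold six TM helices. Records whose map leaves any segment
below 50 % coverage are discarded (`missing_segment`); the 50 % default is
our choice, since the source procedure states only that sequences with
missing TM segments were removed. Redundancy is removed greedily at 98 %
identity, CD-HIT style: records sorted by descending length (ties by id)
join the first representative at ≥ 98 % identity (matches over the shorter
length) and are dropped as `redundant` — unless their species label
differs from the representative's, in which case they are retained, since
cross-species near-duplicates are informative for taxonomic coverage.

## Conservation statistics

Column statistics are computed over mapped residues only: gaps are
excluded from the denominator, so percentages are "of the channels that
possess this position", and an all-gap column is reported as missing
rather than 0 %. Class (group) conservation sums member frequencies over
the same denominator; the default registry is small/weakly-polar
{G,A,S,T,C}, aromatic {F,Y,W}, hydrophobic {A,V,L,I,M,F,C,W}, acidic
{D,E}, basic {K,R}, hydrophilic {N,Q,S,T,H,D,E,K,R}. The family
literature names these classes without enumerating all of them; the sets
are configurable, and these defaults are our documented convention.
Percentages are reported to one decimal.

Loop and termini lengths are measured in query residues outside the
mapped segment blocks: the N-terminus before TM1's first mapped residue,
loops A–E between consecutive segment blocks, and the C-terminus after
TM6. Summaries are mean ± SD per user-supplied group.

## CHI and CVV

The two constriction-site scores are plain sums over the site's residues:
CHI over the Kyte–Doolittle hydropathy scale, CVV over Creighton's
per-residue van der Waals volumes in Å³. The scales ship with the package
and are locked by golden tests: a dozen published site strings with their
printed values (FFHA = +4.2 and 455 Å³, IIII = +18.0, YFQS = −2.8,
VLSV = 407 Å³, YLFNI = 620 Å³, …) over-determine the residues involved, so
there is no freedom left in the constants. We treat the volumes as
volumes: sums of van der Waals *radii* would be of order 8 Å, wildly
inconsistent with the 407–620 Å³ magnitudes these scores take, so the one
sentence in the source describing CVV as summed radii is read as loose
wording (its own Table also once labels an obvious volume as "CHI"; both
are treated as typographical slips). Positive CHI values are formatted
with an explicit "+" in reports, following the field's convention.

Sites containing a gap are scored as incomplete (`complete = FALSE`, no
numbers) rather than erroring: incompleteness is data.

## Flagging unusual constrictions

The source identifies channels with unusual constrictions by inspecting
distributions; no threshold is printed. We therefore provide two explicit
rules, applied per (site, state, group) stratum with at least 10 complete
scores: a z-score rule flagging |x − mean|/SD ≥ k (default k = 2.5; a
zero-spread stratum flags nothing) and a percentile rule flagging values
outside [p, 100−p] (default p = 1; note that duplicating entries moves
percentile bounds, unlike the z-rule under duplication of typical
entries). The typical per-subfamily site strings (LLTV, FLTV, FFHV, …)
ship as annotation metadata, not as thresholds.

## Subfamily classification

The eight prokaryotic subfamilies were originally defined by phylogenetic
inference. fntscan deliberately does **not** reproduce trees; it encodes
the published subfamily-diagnostic conservation table as position-specific
profiles: per subfamily, each diagnostic position carries an allowed
residue set and a weight equal to the stated conservation fraction
(cells listing several residues become one set with the aggregate
weight; empty cells are omitted). `score_sequence()` returns the
normalised weighted match fraction in [−0.5, 1]; a gapped diagnostic
subtracts half its weight, since missing evidence is weaker than
contradicting evidence.

Ranking profiles needs care: because empty cells are omitted, one
profile's claimed positions can be a subset compatible with another
subfamily's consensus (every YfdC-β diagnostic is satisfied by a typical
YfdC-α sequence), and normalised scores then tie at 1.0 for both. We
therefore rank by the raw matched evidence — the unnormalised weighted
sum — which resolves nested profiles in favour of the more specific one,
exactly as a naive-Bayes view of the profiles would. The margin rule
(best minus second evidence below `margin_min` ⇒ "unclassified", default
0.25, a quarter of one fully-conserved diagnostic) is this package's
stand-in for the source's "poorly resolved" sequences; it is not the
original procedure. Ties beyond that break by profile name order, so
classification is deterministic. Profiles serialise to a documented TSV,
and `learn_profiles()` can rebuild them from any labelled mapped cohort
via the conservation module.

## Pairwise comparisons

Identity and similarity are computed over the reference positions of the
ten segments where *both* sequences are mapped — the TM + Ω + S regions —
with similarity counting matches plus positive-scoring BLOSUM62
substitutions (the source does not define "similarity"; this is the
standard convention, and the matrix is configurable). Excluding positions
gapped in either sequence avoids penalising coverage differences twice.
Group matrices average all unordered within-group pairs on the diagonal
and all cross pairs off it; singleton groups get a missing diagonal.

## Operon support

Gene-context support follows the stated neighbourhood rule: up to three
genes on each side of the FNT gene on the same contig, filtered to the
same transcriptional strand, searched for partner-enzyme annotations by
case-insensitive keyword/gene-symbol matching (pfl, fdh, nirBD, asrABC
registries, user-extensible). The nearest match decides; equidistant ties
go downstream (in the FNT gene's transcription direction), making the
result order-independent. The original fallback — BLAST of unannotated
transcripts against known operon members — is out of scope here, as it
requires external databases.

## The synthetic cohort generator

The generator is the package's test substrate and defines its study
conditions. Default composition mirrors the reported prokaryotic cohort
(1723 classified sequences; YfdC-α largest at 361, NirC-β smallest at 79).
Per subfamily it builds a consensus: diagnostic positions take the first
allowed residue; family-wide near-invariant positions take their asserted
residue; remaining transmembrane positions keep the reference residue
with probability 0.35 and otherwise draw a hydrophobic residue from a
per-subfamily seeded stream; loop positions draw from {G,S,N,P,D,E}. The
0.35 retention keeps consensus-to-reference transmembrane similarity in
the range real subfamily members show (inter-subgroup identity lands at
~32–44 % on generated cohorts, against ~85 % within subfamilies), which
is what makes a sequence-level mapping proxy behave like the
structure-anchored original; with fully independent fills the synthetic
family would be far more divergent than the real one and mapping artefacts
would appear that real data does not produce.

Emission per sequence: constrained positions (diagnostics plus
near-invariants) emit their consensus residue with probability
`diagnostic_fidelity` (default 0.99) and otherwise a residue from outside
their allowed set — so the in-set frequency is the fidelity by
construction; unconstrained positions substitute with probability
`mutation_rate` (default 0.1), uniformly over the 19 alternatives. The
near-invariant positions are governed by fidelity rather than the
background rate because that is what "near-invariant" means: their
conservation must stay at ~99 %, not drift to 90 %. Loop and termini
lengths are drawn per region from a per-subfamily normal model (means
emulate the reported qualitative pattern: YfdC N-termini longest at
~45–50 residues, NirC-α with the shortest loop A and longest loop C, FocA
with a long loop E); indels are thereby confined to loops and termini,
mirroring the biological constraint the whole analysis exploits. Operon
placement selects round(`operon_fraction`·n) sequences (default 0.15)
from the subfamilies with a known partner class — YfdC has none, matching
the absence of genetic linkage reported for it — and the feature-table
generator realises each placement at the recorded signed gene distance on
the same strand.

All draws flow from one seeded stream (the caller's RNG state is saved
and restored), so a fixed seed gives byte-identical FASTA, ground truth
and feature tables. FASTA identifiers carry no label information; labels
live only in the ground-truth table.

What the generator does *not* emulate: tree-structured evolution (no
phylogenetic correlation between sequences), substitution-matrix-biased
mutation, eukaryotic FNTs, annotation noise in feature tables, or
fragmentary sequences beyond what the QC filters synthesise directly.
Passing tests on this substrate therefore demonstrate correct recovery of
known signal under idealised homology — they do not certify performance
on real, phylogenetically structured data.

## Validation sizes and numerical choices

The test suite exercises: emission-parameter recovery on 500 sequences
per subfamily (pooled in-set and background frequencies within 3 binomial
SDs, plus a per-position spot check at His-209); ≥ 95 % label recovery at
10 % mutation on 200 sequences per subfamily; exact operon-fraction
recovery on a 2000-gene cohort; 50-pair score equality against the
brute-force alignment oracle; and byte-identical reruns of the full
pipeline on a 48-sequence cohort. These sizes keep the default test run
in the low minutes on one core while leaving the binomial tolerances
tight; pooled (rather than per-position) frequency checks are used
because ~1,450 independent 3-SD tests would fail somewhere by chance in
almost every run even under a perfect generator.

Other numerical conventions: percentages to one decimal in tables;
report TSVs written with fixed 4-decimal formatting, LF newlines and no
quoting so that reruns are byte-comparable; the run manifest records
package version, parameters and input MD5 digests but no timestamps.

## Known limitations

* The mapping proxy is sequence-based; extremely diverged members that
  the original structure-guided procedure could still anchor may fall
  below the alignment floor here and be discarded as unalignable.
* The classifier inherits the diagnostic table's blind spots: a subfamily
  whose diagnostics are a near-subset of another's (YfdC-β vs YfdC-α) is
  separated only by the evidence-ranking rule, and sequences from outside
  the eight subfamilies are forced to "unclassified" rather than detected
  as novel.
* Pairwise matrices are quadratic in cohort size; the pipeline exposes a
  switch to skip them for very large runs rather than attempting the full
  2,000-sequence matrix by default.
* The bundled reference sequence is synthetic (see above); analyses that
  depend on reference residues *outside* the asserted set reflect that
  synthetic filler.
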