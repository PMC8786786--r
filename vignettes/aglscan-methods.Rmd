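---
title: "Methods: discovering PG-rich GPI-anchored disordered proteins with aglscan"
author: "aglscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering PG-rich GPI-anchored disordered proteins with aglscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aglscan)
```

## The problem

Small secreted intrinsically disordered proteins (IDPs) rich in proline and
glycine — in arbuscular mycorrhizal fungi usually called AGP-like proteins,
or AGLs — are nearly invisible to homology search. Their mature regions
evolve so fast that putative orthologues may share less than half their
coding-sequence identity, while the parts the cell machinery needs —
the N-terminal endoplasmic-reticulum (ER) signal peptide and the C-terminal
glycosylphosphatidylinositol (GPI) anchor signal — stay comparatively
conserved. What persists instead of sequence is *architecture*: an ER
signal, a short first exon with a single intron next to the signal-cleavage
site, a low-complexity mature region often built from tandem repeats with
strongly restricted codon usage, and a GPI ω-site near the C-terminus.

`aglscan` implements the computational side of a discovery workflow built
around that architecture:

1. **Candidate surfacing** — either six-frame ORF scanning with a
   composition screen (retain ORFs with > 20% P+G), or seeding from
   imported homology hits.
2. **Targeted read recovery** — k-mer baiting of raw reads against
   candidate coding sequences, to feed an external reassembly that can fix
   truncated or frameshifted contigs.
3. **Characterisation** — signal-region annotation, mature-protein
   composition/pI profiling, tandem-repeat detection with biophysical
   classification, and codon-usage tables over repeat regions.
4. **Classification** — a five-class scheme and an elimination rule that
   discards non-secreted candidates.

A synthetic-fixture generator produces genes with exactly this architecture
and exact ground truth; every non-trivial component is validated against it
or against an independent oracle.

## Sequence handling and ORF scanning

FASTA/FASTQ parsing and the genetic code are delegated to Biostrings; the
package adds record-level validation (unique ids, line-numbered parse
errors) and the conventions the rest of the pipeline relies on: residues
are uppercased, any codon containing `N` translates to `X`, and `X` counts
toward sequence length but never toward a composition percentage numerator.

ORFs are **stop-to-stop** maximal runs in all six frames, not ATG-to-stop,
because real candidates are frequently truncated assemblies whose predicted
proteins lack the initiator methionine; an ATG-anchored mode is available
behind a flag. The minimum ORF length defaults to 50 aa — the shortest
mature proteins of interest are around 100 aa, so 50 leaves a wide margin
for partials while suppressing noise ORFs. Frames on the minus strand are
numbered from the 5' end of the reverse complement. The PG screen is a
strict inequality (`> 20%`), so a peptide at exactly 20.0% is rejected.

## Composition, molecular weight, isoelectric point

Percentages are computed at full precision as `100 * count / length` and
displayed to one decimal. Molecular weight is the sum of average residue
masses plus one water; `X` is an error unless a substitute mass is given.

The isoelectric point bisects the Henderson–Hasselbalch net charge
(termini plus D, E, C, Y, H, K, R side chains) on pH ∈ [0, 14] to a
tolerance of 0.005. The default pKa set is the Bjellqvist convention used
by the common protein-analysis toolkits, with an EMBOSS-style set
selectable by name; both live in a documented constants table
(`PKA_SETS`). Published pI values for real proteins are reported to one
decimal without naming a pKa convention, so agreement across conventions
is only expected to about that precision; the package instead validates
its pI against a dense-grid root scan of the same charge model (±0.01 on
random peptides).

Display-style flags use the conventional inclusive thresholds: individual
residues at ≥ 15%, PGA (P+G+A) ≥ 40%, DE ≥ 8%, KR ≥ 8%. pI classes default
to acidic < 6.0, neutral 6.0–7.5, basic > 7.5; the cut points are
arguments, since "close to neutral" is a judgement call near 6.

## Signal regions: imported calls first, heuristics as fallback

External signal predictors are the authority: `import_signal_predictions()`
reads two TSV dialects (`id, cleavage_end, YES/NO` for ER;
`id, omega, YES/NO, score` for GPI) and annotations carry
`provenance = "imported"`. The built-in heuristics exist so the pipeline
can run unassisted, and are never silently mixed with imported calls —
every report row records provenance.

* **ER heuristic**: within the first 40 residues, require an 8-residue
  window with mean Kyte–Doolittle hydropathy ≥ 1.6 (the h-region), then
  return the first position in 15..35 after that window satisfying the
  (−3, −1) small-residue rule (both of A, G, S, C, T, V).
* **GPI heuristic**: require a hydrophobic tail (mean KD ≥ 1.0 over the
  final 12 residues) and a small residue (G, A, S, N, D, C) at 17–31
  residues from the C-terminus with a small residue at ω+2; among
  qualifying positions the one closest to 25-from-the-end wins, ties
  toward the C-terminus.

These are deliberately coarse approximations of the neural/HMM predictors
they stand in for; the synthetic generator draws its signal peptides from
curated templates on which the heuristics provably recover the planted
boundaries, so heuristic tests are exact rather than flaky.

The mature protein is everything between the ER cleavage site and ω−1
(the ω residue and the downstream propeptide are removed on anchor
attachment). All composition statistics of candidates refer to the mature
protein whenever stripping is possible.

## Tandem repeats

The detector's contract is what downstream analysis relies on: perfect
protein arrays are found at similarity 1.0 and reported once at their
smallest period; imperfect DNA arrays are found at relaxed thresholds
(conventionally 0.7, to absorb codon degeneracy).

The algorithm: candidate periods are the pairwise occurrence distances of
recurring k-mers (k = 3 for protein, 5 for DNA) with support ≥ 2; for each
period in ascending order, arrays grow left to right by appending adjacent
period-length units while each unit matches the running column-majority
consensus at identity ≥ the threshold (consensus ties resolve to the
first-seen residue). The similarity score `psim` is the mean over full
units of the fraction of positions matching the final consensus —
mutating *m* residues in one unit of an *N*-copy, length-*L* perfect array
lowers it by exactly *m/(N·L)*, which the tests assert. A trailing partial
unit extends the reported span but is not counted as a copy. Spans also
explained by a smaller qualifying period at at-least-equal psim are
suppressed, so `ABABABAB` is one region of unit 2 × 4 copies and
homopolymers report unit length 1. Unit comparison is positional:
substitutions are tolerated up to the threshold, but unit-internal indels
are not chased — the behaviours validated here (perfect protein arrays,
substitution-mutated DNA arrays) do not require indel tolerance, and the
k-mer seeding implies a detection floor: an array must be long enough
(roughly period + k within matching distance, observed twice) to be
seeded, so dinucleotide-scale accidents in random sequence are ignored.
Overlap filtering (off by default, matching the conventional setting)
greedily keeps the highest `copies × unit_length × psim` regions.

Repeat composition (P%, G%) is computed on the consensus unit, the level
at which published repeat compositions are quoted (e.g. APADGK → 16.7%
for both). A unit is zwitterionic when it contains at least one acidic
(D/E) and one basic (K/R) residue.

### Mechanical-property zones

Repeat compositions map to predicted mechanical behaviour in the (G%, P%)
plane: P/G-poor repeats tend to amyloid, P+G-rich ones to elastic
(elastin- or silk-like), with an "interchangeable" intermediate band. The
boundaries shipped with the package are two non-crossing piecewise-linear
curves (`inst/extdata/zones_default.json`), **calibrated** so that
well-characterised exemplar compositions classify as expected — a
14.3% G / 0% P repeat is amyloid, 16.7/16.7 intermediate, 20/20 and above
elastic — not read from any printed constant. Because both boundary curves
are non-increasing in G%, increasing P% or G% can never move a label
toward amyloid; this monotonicity is validated over a dense grid and
enforced (with a positive-width intermediate band) whenever a zone file is
loaded. The vertex file documents which axis is which, since composition
scatter plots in the literature are not always explicit about orientation.

## Codon usage

`codon_usage()` counts codons within a stated in-frame interval of a CDS
and reports per-amino-acid fractions. Repeat arrays that expanded by
recent DNA-level duplication show strongly restricted usage — often one
codon per amino acid — and the synthetic generator's "strict" codon bias
(one codon per amino acid, e.g. P → CCA, K → AAA, D → GAC) reproduces that
signature exactly, which the tests verify on planted repeat regions.

## k-mer read baiting

`build_bait_index()` stores every canonical k-mer (lexicographic minimum
of the k-mer and its reverse complement) of the bait sequences; a read is
selected when at least `n_min` of its canonical k-mers hit the index
(defaults k = 31, n = 1, the conventional baiting defaults). Strand
collapse is the right semantics because baits derive from coding
sequences while reads come from both strands; a tool that instead checks
both strands explicitly selects the same reads. Qualities are ignored at
baiting — the point is to pull matching raw reads into a
quality-aware external assembler. Pair policy defaults to "either mate",
since the selected pairs feed paired-end assembly; `both` and
`ignore-pairing` are available. Iterative two-round baiting is done by
running the CLI twice, not by bespoke logic.

## Global alignment and region-partitioned identity

The aligner is an affine-gap Needleman–Wunsch (C++ core) with a gap run
of length *L* costing `open + L·extend`; defaults are the conventional
full-length DNA comparison settings (match +5, mismatch −4, open 10,
extend 0.5) with terminal gaps free, appropriate for whole-gene
comparisons of unequal extent. Tie-breaking is deterministic (diagonal,
then vertical, then horizontal), so identical inputs always give
byte-identical alignments. Scores are validated against an exhaustive
enumeration of alignments on tiny inputs and an independently written
memoised recursion up to 12 nt.

`region_identity()` partitions alignment columns by regions given on the
ungapped coordinates of the first sequence (columns where that sequence
has a gap inherit the preceding region) and reports
`100 × identical / assigned columns`, gap columns included in the
denominator — the stricter convention. Viewer-derived identity
percentages in the literature can differ by convention, so published
per-region ranges are treated as *ordering* constraints (signal regions
more conserved than mature regions), which the synthetic orthologue tests
reproduce by construction. `frameshift_gaps()` reports gap runs inside
coding regions whose length is not a multiple of three — the lesions that
make putative orthologues encode different proteins.

## Classification and elimination

The five-class scheme: class 5, neither ER nor GPI signal; classes 3/4,
chimeric per an imported domain-hit table (3 for the configured
"insignificant" arabinogalactan-domain category, 4 otherwise); class 1,
PGA strictly above 40%; class 2, PGA in [15, 40]. The printed scheme
leaves (39.9, 40] ambiguous between classes 1 and 2; the package honours
the strict "> 40%" reading, so exactly 40.0 is class 2. An AGL call
additionally requires an ER signal and a mature length ≤ 200 aa.

Candidates without an ER signal cannot be secreted and are eliminated,
unless they are partial (no initiator Met, or truncated at a contig end)
and highly identical to an ER-bearing peer — the truncated-assembly case.
The identity threshold behind "highly identical" is not quantified in the
source workflow; the default of 90%, computed over the candidate's own
residues so a clean truncation scores 100%, is a documented choice.
Domain matching itself (e.g. against the fasciclin-like PF10342 family)
is out of scope; the pipeline consumes a hit table.

## The synthetic generator: what it emulates, what it does not

`make_agl_gene()` builds genes with the canonical architecture — ER-signal
exon plus three codons, one 80-nt GT..AG intron (echoing the short,
65–79 nt first exons of real genes), then the mature region (a glutamine
followed by the repeat array, back-translated under the restricted codon
bias) and the GPI signal. Defaults plant a clean class-1 candidate: 20-aa
ER signal, Q + 12 × APADGK mature region (73 aa, PGA ≈ 66%), 25-aa GPI
signal — sizes and composition in the range of real mature AGLs, with
whole-ORF PG just above the 20% screen, as for real candidates whose
signals dilute the mature-region PG content. Transcripts carry short
GC-only UTRs with an in-frame stop immediately upstream, so the
stop-to-stop ORF scan recovers exactly the encoded protein — a
deliberate convenience for exact truth comparison. Decoys are random
ORF-bearing transcripts with PG below 15%, re-sampled until no chance ORF
in any frame survives the 20% screen. Reads are error-configurable
substitution-only pairs at uniform coverage.

The generator does **not** emulate: expression-level variation, indel
sequencing errors, quality-score profiles, alternative splicing,
polymorphic repeat copy number, or compositional drift between signal
peptides of real species. Passing the end-to-end tests therefore shows
the pipeline's logic is correct under the stated architecture, not that
the heuristics match neural predictors on real proteomes — on real data
the imported-predictor path is the supported one.

All generator randomness flows from one mandatory seed per call; the same
spec and seed give byte-identical output.

## Numerical and testing choices

* Percentages are kept at full precision internally; rounding to one
  decimal happens only at display.
* pI bisection tolerance 0.005; test agreement with the grid oracle
  ±0.01.
* Repeat-consensus ties go to the first-seen residue; alignment
  tie-breaks prefer diagonal, then vertical, then horizontal — all
  deterministic.
* Degenerate inputs: empty FASTA records, proteins with `*`, inverted
  region annotations, crossing zone boundaries and out-of-frame
  codon-usage intervals are errors with informative messages; empty
  pipeline input yields an empty report, exit 0.
* Problem sizes in the test suite are chosen to be decisive but quick:
  200 × 300-nt sequences for the ORF oracle, 100 random peptides for the
  pI oracle, alignment oracles up to 12 nt, a 1000-read-pair baiting
  cohort (200 planted, 800 decoy), a 3 + 7 cohort for the end-to-end
  recall/precision check, and a 101 × 101 grid for zone monotonicity.
  The whole suite runs in well under a minute.

## Known limitations

* The repeat detector does not model unit-internal indels or nested
  repeat hierarchies; for heavily degenerate arrays a profile-based tool
  remains the reference.
* Published per-species candidate counts, pI values of real proteins, and
  repeat-region coordinates from the original assemblies require the
  original sequence data and are implementation-specific; they are not
  reproduction targets here and are replaced by the property suites and
  ordering constraints described above.
* The built-in signal heuristics are fallbacks, not predictors; their
  false-positive behaviour on arbitrary proteomes is uncharacterised.
* Zone boundaries are a calibration; users with their own reference set
  should supply their own vertex file.
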