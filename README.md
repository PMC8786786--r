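# aglscan

Discovery and characterisation of small, secreted, proline/glycine-rich
intrinsically disordered proteins (AGP-like proteins, "AGLs") from
transcript, genomic and protein sequences.

## The problem

AGLs — GPI-anchored cell-surface IDPs of arbuscular mycorrhizal fungi —
evolve so fast in their mature regions that homology search often fails
across species. What is conserved is their architecture: an N-terminal ER
signal peptide, a single intron adjacent to the signal-cleavage site, a
low-complexity mature region frequently built from tandem repeats with
restricted codon usage, and a C-terminal GPI-anchor signal cleaved at the
ω residue. `aglscan` finds and characterises candidates by that
architecture rather than by sequence similarity:

- **Six-frame ORF scanning** with a PG-content screen (retain ORFs with
  PG% > 20, strict) for candidate surfacing when homology fails.
- **k-mer read baiting** (canonical 31-mers, ≥ 1 hit) to pull matching raw
  reads for targeted reassembly by an external assembler.
- **Composition profiling** of mature proteins (per-residue %, molecular
  weight, isoelectric point by Henderson–Hasselbalch bisection under the
  Bjellqvist pKa set) with the standard display flags (single residues
  ≥ 15%, PGA ≥ 40%, DE ≥ 8%, KR ≥ 8%, pI class).
- **Signal-region handling**: imported predictor summaries are
  authoritative; built-in hydropathy/(−3,−1)-rule heuristics serve as a
  clearly flagged fallback.
- **Tandem-repeat detection**: k-mer–seeded periods grown against a
  column-majority consensus, scored by mean unit-to-consensus identity
  (`psim`; 1.0 for proteins, 0.7 for DNA by convention), with repeat P%/G%,
  a zwitterionic flag, and elastic/intermediate/amyloid zone
  classification in the (G%, P%) plane.
- **Codon-usage tables** over repeat regions of a CDS.
- **Global alignment** (affine Needleman–Wunsch, EMBOSS-style defaults,
  free terminal gaps) with region-partitioned identity and
  frameshift-gap reporting.
- **Five-class classification** (1: AGL, PGA > 40%; 2: PGA 15–40%; 3/4:
  chimeric by imported domain hits; 5: no ER or GPI signal) plus an
  elimination rule for non-secreted candidates.
- **Synthetic fixture generation** of genes/transcripts/proteins/reads
  with exact ground truth for validation.

## Worked example

Generate a synthetic cohort of 3 planted AGL transcripts and 7 decoys,
then run the pipeline with the truth signal annotations:

```r
library(aglscan)
co <- make_cohort(n_agl = 3, n_decoys = 7, seed = 42)
report <- run_pipeline(co$transcripts, signals = co$signals)
report[report$is_agl, c("id", "mature_len", "pga_pct", "pI",
                        "repeat_unit_length", "repeat_copies",
                        "repeat_zone", "class_label")]
#>               id mature_len pga_pct    pI repeat_unit_length repeat_copies
#> 1 agl1|+0|19-372         73   65.75 6.325                  6            12
#> 3 agl2|+0|19-372         73   65.75 6.325                  6            12
#> 5 agl3|+0|19-372         73   65.75 6.325                  6            12
#>    repeat_zone class_label
#> 1 intermediate           1
#> 3 intermediate           1
#> 5 intermediate           1
```

Exactly the three planted candidates are called AGL (class 1): each ORF
survives the PG screen, is stripped to a 73-aa mature protein of 65.8%
PGA, and carries the planted 12 × APADGK repeat array. Decoy ORFs and
reverse-frame ORFs of the planted genes are classified 2/5 or eliminated
as non-secreted.

Repeat detection and properties on a known repeat unit:

```r
r <- detect_repeats(strrep("GKAPAGGAAPGADA", 5), "protein", psim_min = 1.0)
r[, c("start", "end", "unit_length", "copies", "consensus", "psim")]
#>   start end unit_length copies      consensus psim
#> 1     1  70          14      5 GKAPAGGAAPGADA    1
repeat_properties(r)
#> P% 14.3  G% 28.6  zwitterionic TRUE  zone intermediate
```

The five-copy array of the 14-residue unit is reported once, at its
smallest period, with perfect unit-to-consensus similarity; the unit has
one basic (K) and one acidic (D) residue (zwitterionic) and its P/G
composition places it in the interchangeable elastic/amyloid zone.

## Command line

A thin CLI over the same functions is installed at
`exec/aglscan` (find it with
`system.file("exec", "aglscan", package = "aglscan")`):

```sh
aglscan orfscan --min-aa 50 --pg-min 20 transcripts.fasta -o orfs.fasta
aglscan bait --k 31 --n 1 --baits baits.fasta reads_1.fastq reads_2.fastq -o baited
aglscan repeats --alphabet protein --psim 1.0 proteins.fasta -o repeats.tsv
aglscan codon-usage --region 277:504 cds.fasta -o usage.tsv
aglscan region-id --regions regions.tsv a.fasta b.fasta -o report.tsv
aglscan classify transcripts.fasta --signals-er er.tsv --signals-gpi gpi.tsv -o candidates
aglscan simulate --seed 1 --n-agl 3 --n-decoys 7 -o synth_out
```

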