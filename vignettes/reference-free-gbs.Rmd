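---
title: "Reference-free SNP calling for GBS libraries: methods and design"
author: "gbscallr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free SNP calling for GBS libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbscallr)
```

## The problem

Genotyping-by-sequencing (GBS) reduces a genome to the set of restriction
fragments released by a one- or two-enzyme digest, sequences those fragments
as a multiplexed, barcoded, paired-end library, and discovers and genotypes
SNPs in one pass.  For many crops and wild species no reference genome is
available, so the reads themselves must supply the coordinate system.
`gbscallr` implements that reference-free workflow end to end:

1. **Parse, trim, demultiplex.**  R1 reads begin with a 6–10 bp in-line
   barcode followed by the rare-cutter site remnant; R2 reads begin with the
   common-cutter remnant.  Reads are assigned to genotypes, cut down to
   insert sequence, quality-trimmed, and split into per-genotype files.
2. **Build a Mock Reference.**  Mate pairs that overlap are merged into
   full-fragment reads; long fragments are represented by stitching the
   mates around a 20-A spacer.  Greedy identity clustering collapses these
   reads into a non-redundant set of centroid sequences that stands in for
   a genome.
3. **Map and pile up.**  All genotypes' read pairs are mapped back to the
   centroids under pair-proper, unique-hit semantics and summarised as
   per-position base-call depths; externally produced `samtools mpileup`
   text is accepted through the same interface.
4. **Call SNPs and genotypes.**  Per-genotype A/C/G/T depths at every
   candidate position form the population *master matrix*, which is pared
   down by an independence filter, a bi-allelic strength filter, depth-based
   genotype assignment, and population-level culls.

A synthetic-data module simulates the whole experiment with truth tables,
so every stage is testable without external downloads.

## Stage 1: parsing rules

A read pair is retained when the R1 prefix matches a known barcode within
Hamming distance 1 (evaluated longest-barcode-first; a distance tie among
equal-length barcodes is ambiguous and discards the read) *and* the
rare-cutter remnant follows the barcode exactly.  The barcode table itself
is validated at load: no two same-length barcodes may sit within Hamming
distance 1, otherwise one-mismatch assignment would be ambiguous by
construction.

Barcode and remnant are removed from R1 (the remnant removal is
configurable; removing it keeps positions comparable across genotypes), and
the common-cutter remnant is removed from the R2 5' end when present within
one mismatch.

**3' truncation.**  When a fragment is shorter than the read, the read
continues through the far cut-site remnant into the sequencing adapter.
The package truncates at an in-line signature: for R1 the
reverse-complement of the common-cutter remnant followed by the first 12
adapter bases; for R2 the reverse-complement of (barcode + rare remnant),
which is exactly the sequence that follows the insert on that strand (the
barcode is known at this point because the pair has been assigned).  Two
non-obvious choices matter here:

* the full-signature search tolerates one mismatch (`sig_max_mm`), and
* a read whose 3' end stops *inside* the signature is truncated at the
  longest suffix equal to a signature prefix (exact below 10 bases, one
  mismatch allowed at 10 or more).

Both exist because exact matching measurably corrupts the Mock Reference:
a sequencing error inside the signature leaves an adapter tail on the read,
tail-bearing reads are *longer* than clean ones, and the length-descending
clustering order then preferentially picks exactly those reads as centroid
founders.  The result is chimeric centroids (a short fragment appearing
twice, once per arm of a spurious stitch), which make downstream mapping
ambiguous and silently lose SNPs.  Mismatch-tolerant, end-aware adapter
matching is also what dedicated trimmers do.  The cost is bounded: a false
partial-suffix hit can shave at most a few genuine terminal bases off a
read, which only thins coverage at fragment ends.

Pairs in which either mate is a strict majority of N bases are discarded.
Quality trimming then mirrors the classic trimmer parameter string
`LEADING:30 SLIDINGWINDOW:4:30 TRAILING:30 MINLEN:32`: leading and trailing
bases below Q30 are removed, the read is cut at the start of the first
4-base window with mean quality below 30 (scanning 5' to 3'), and reads
shorter than 32 bases are dropped.  Pairs losing one mate become
singletons.  Only Phred+33 input is accepted; other encodings are rejected
at load.

## Stage 2: merging, stitching, clustering

**Merging.**  R2 is reverse-complemented into R1 orientation and the
longest 3'(R1)–5'(rc R2) overlap of at least 10 bp is accepted if its
mismatch fraction is at most `max_mismatch_frac` (default 0.1 — the
tolerance inside overlaps is not prescribed anywhere authoritative, so it
is exposed as a parameter).  At mismatching overlap columns the
higher-quality base wins and keeps its quality.  Merged reads shorter than
32 bp are discarded.

**Stitching.**  Pairs the merger leaves untouched are joined as
`R1 + A×20 + reverse-complement(R2)`, with the junction quality set to
Phred 40 ("high-quality" is not quantified anywhere; Q40 marks the bases
as synthetic-but-trusted).  Mates shorter than 32 bp discard the pair.
The mapper later refuses alignments that span a 20-A junction, so the
synthetic spacer can never generate evidence.

**Identity.**  Pairwise identity is matches / alignment columns of an
ends-free (semi-global) optimal alignment: internal gap columns count as
mismatch columns, terminal (free) gap columns are excluded.  This
reproduces the two calibration points that motivate the default threshold:
two 32-mers differing at two positions score 30/32 = 0.9375 (so they
co-cluster at 0.93), and a single internal insertion in a 100-mer scores
100/101.

**Clustering.**  Greedy first-fit: reads are processed in length-descending
order (ties broken lexicographically, which makes runs reproducible), each
read joins the first centroid reaching the identity threshold, otherwise it
founds a new centroid whose sequence is the read itself.  No consensus
polishing is done — polishing would silently shift downstream coordinates.
For speed the implementation dereplicates identical reads first (the
greedy result is provably unchanged), prefilters candidate centroids by a
shared 8-mer count bound derived from the threshold (with a 1.5× slack
factor for gaps), and evaluates the exact alignment in a band around the
main diagonal.  The band excludes pathological shifted alignments between
unrelated sequences; for the near-global alignments clustering cares about
it is exact.

Clustering runs within each selected genotype first and, when more than one
genotype is selected, again across the pooled genotype centroids.
Genotypes are selected by parsed-read abundance
(`select_mockref_genotypes()`).  The result carries both FASTA outputs: the
single concatenated genome and the per-centroid clusters file, in identical
order, with 1-based closed offset intervals that invert exactly.

## Stage 3: mapping and pileups

The built-in mapper indexes the centroids with exact 20-mers and extends
each candidate (reference, diagonal, strand) by full-length comparison,
keeping the locus with the fewest mismatches under a per-read ceiling
(`max_edit_frac`, default 0.07 — chosen to mirror the 93 % clustering
identity so any read that helped build a centroid can map back to it).  A
read with two or more distinct best-scoring loci is unmapped: this is the
single-best-hit reading of "no secondary/supplementary alignments".  A pair
is kept only when both mates map uniquely to the same centroid in opposite
orientations with a plausible, non-inverted insert.  The extension is
ungapped (substitution-only): GBS reads map back to centroids built from
the same reads, where indels would only arise from rare sequencing
artifacts, and such reads are better unmapped than force-fitted.  Pileup
construction still walks full M/I/D CIGARs, so records from external
aligners (or constructed ones) carry indel evidence through the same code
path, and the mpileup text reader covers the external route.

Pileups count bases with quality at least `min_base_q` (default 0; the
depth filters downstream do the heavy lifting).  Bases covered by both
mates of one pair are counted **once**, the higher-quality mate winning —
overlapping mates are one molecule, and double-counting would bias the
depth-based genotype caller exactly where fragments are short.

The mpileup text reader implements the classic dialect (`.`/`,` reference
matches, case-folded substitutions, `^` + mapping quality, `$`, `+n`/`-n`
indel runs, `*` deletion placeholders, `<`/`>` reference skips) and
cross-checks the resolved symbol count against the depth column, failing
with the offending line number.

## Stage 4: the master matrix and SNP calling

Per genotype, covered positions without indel evidence become count rows;
positions with *any* depth on a non-reference base are candidate SNPs
(deliberately threshold-free — the population-level filters do the
culling).  The master matrix is the union of all candidates over the
population, with each cell holding the genotype's full A/C/G/T depth
4-tuple even where that genotype was not itself polymorphic.  A position
with indel evidence in any genotype is excluded population-wide (the
workflow is SNP-exclusive; a locus that is an indel in one accession is not
a clean SNP in any).  Conflicting reference bases across genotypes are a
hard error.

Calling proceeds in a fixed order:

1. **Allele ranking.**  Bases are ranked primary→quaternary by
   population-summed depth; ties break by the fixed order A<C<G<T for
   reproducibility.  Rows whose secondary allele has zero population depth
   are dropped (monomorphic within the population).
2. **Independence filter.**  The secondary allele must be seen at depth ≥ 3
   in at least 3 distinct genotypes (both configurable).  The phrase
   "independent instances … across at least three genotypes" admits a
   pooled reading; the per-genotype reading is implemented as the default
   because independence across genotypes is the point of the filter, and
   the pooled alternative is available via `indep_pooled`.
3. **altStrength.**  The position is strongly bi-allelic iff
   2°depth / (2°+3°+4° depth) strictly exceeds 0.90.
4. **Genotype assignment** per genotype from its primary/secondary depths
   (p, s): heterozygote iff both ≥ 3 and min/max strictly exceeds 0.1;
   homozygote iff the other allele has 0 reads and depth ≥ 11, or exactly
   1 read and depth ≥ 48; everything else is missing data.  The strict
   vs. non-strict choices follow the rule text exactly ("must exceed" vs
   "≥"); the exhaustive-grid acceptance test pins all 3,721 cells of
   (p, s) ∈ [0, 60]² against an independently written rule table.
5. **Population culls.**  Keep SNPs with ≥ 75 % of genotypes scored and
   average depth strictly between 4 and 200.  Average depth is the mean
   total (4-base) depth over **all** genotypes, including zero-coverage
   ones — that is what makes the low-depth cull meaningful (a flag
   restricts it to covered genotypes).

The final matrix carries ten population-summary columns (reference id and
position, reference base, average depth, primary and secondary allele,
percent genotyped, and the three genotype-class counts — the class counts
recount exactly from the per-genotype calls) followed by one column per
genotype in the form `state|p/s` with `-` marking missing; `P`/`H`/`S`
label the called states (the cell grammar before the `|` is a package
convention; only the `-` missing marker is fixed by convention elsewhere).

No minor-allele-frequency filter exists anywhere in the workflow, by
design: in diverse germplasm collections a rare allele is a finding, not
noise, and the independence filter already guards against artifacts.

## Downstream tools

`to_numeric_matrix()` recodes calls 0 / 0.5 / 1 / NA for distance and
ordination work in R; `to_hapmap()` and `to_plink_transposed()` write the
standard interchange tables (heterozygotes are emitted primary-then-
secondary base; TFAM placeholders are the PLINK missing conventions).
`gower_similarity()` implements the modified Gower identity-by-state score:
per co-genotyped locus 1 for identical states, 0.5 for het vs. homozygote,
0 for opposite homozygotes, with missing calls removing their locus from
both sums; no co-genotyped loci is an explicit error rather than zero.
`replicate_report()` pairs that score with the exact-match fraction, the
two numbers used to recognise biological replicates.

## The synthetic-data module

`simulate_gbs()` emulates the library design the parser expects: random
fragment cores of 120–400 bp (spanning both the merge and the stitch
regime for 150 bp reads), flanked on the reads by the PstI/MspI-style
remnants, barcodes of length 6–10 with pairwise same-length Hamming
distance ≥ 3, adapter read-through on short fragments, Poisson(depth) read
pairs per genotype and fragment, and uniform per-base substitution errors
(default 0.2 %, the order of magnitude quoted for Illumina platforms).
Planted SNPs are bi-allelic; genotype states are drawn i.i.d. with priors
0.45 / 0.35 / 0.20 for reference homozygote / heterozygote / alternate
homozygote — a diverse outcrossing population rather than a biparental
cross.  Heterozygous alleles are drawn per read *pair* (each pair is one
molecule, so mates always agree), and SNP positions are restricted to the
read-covered ends of long fragments so that truth and observable data
coincide.  Replicate columns re-sequence a genotype from the same truth
with independent reads.  Everything is a deterministic function of the
seed.

What the generator does **not** model: PCR duplicates, quality-score decay
along the read, indel errors, repeat families, or paralogy.  Passing the
end-to-end tests therefore demonstrates the machinery is correct under
clean assumptions, not that real polyploid data will be as forgiving —
repeats and paralogs in particular are exactly what the uniqueness rule
and the altStrength filter exist to absorb, and their false-call rates on
real data cannot be estimated from this simulator.

## Validation scales and numerical choices

The packaged checks run at these sizes (chosen to exercise every code path
at desk scale):

* planted-SNP recovery: 24 genotypes × 300 fragments × 150 SNPs at 40×
  depth, 0.2 % error, with a matched null run (0 planted SNPs) that must
  yield zero called SNPs;
* replicate similarity: 12 genotypes × 120 fragments × 80 SNPs at 40× with
  one re-sequenced genotype, expecting Gower ≥ 0.99;
* merge/stitch: 1,000 fragments of 120–400 bp, exact reconstruction below
  2·read_len − 10 and exact junction placement above;
* clustering: 25 mutually dissimilar fragments, one centroid each, with
  centroid counts non-decreasing in the threshold.

Tie-breaks are all deterministic (lexicographic read order, A<C<G<T allele
order, first-mate-wins at equal quality, diagonal-preferring alignment
traceback), so a fixed seed reproduces every output byte for byte.
Degenerate inputs — empty read sets, empty barcode tables, zero-coverage
cells, monomorphic rows, no co-genotyped loci — are either well-defined
empty results or explicit errors, never silent NA propagation.

## Known limitations

* The native mapper is substitution-only; reads with true indels relative
  to their centroid go unmapped rather than gapped.  Use an external
  aligner plus `read_pileup()` when indel-tolerant mapping matters.
* Centroids are founding reads, not consensi: a centroid can carry its
  founder's sequencing errors.  Such positions surface as candidates and
  are then removed by the independence filter (population depth of the
  "variant" stays near zero), at the cost of a slightly inflated candidate
  list.
* Identity is computed under a banded alignment during clustering;
  sequences whose best alignment is strongly shifted can be scored below
  their unbanded identity.  This only matters for inputs very unlike GBS
  read sets.
* The replicate-similarity module reports Gower and exact-match fractions;
  Pearson correlations on the numeric matrix are left to the user's
  statistical environment.
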