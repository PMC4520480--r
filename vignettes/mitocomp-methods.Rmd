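---
title: "Comparative mitogenome statistics with mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome statistics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## Scope and model

Insect mitochondrial genomes are small circular molecules carrying a nearly
invariant census of 37 genes — 13 protein-coding genes (PCGs), 22 tRNAs, 2
rRNAs — plus an A+T-rich control region (CR). Comparative mitogenomics
papers characterize new genomes with a standard battery: gene order against
the ancestral insect arrangement, a census of gene junctions (overlaps,
intergenic spacers, abutting pairs), start/stop codon usage including
partial stops, strand- and codon-position-resolved nucleotide composition
with AT/GC skews, codon usage, and concatenated supermatrices for
phylogenetic inference. `mitocomp` implements that battery as a reusable,
tested pipeline, plus a seeded simulator of annotated mitogenomes so every
stage can be verified at desk scale without downloads.

Key conventions, fixed throughout:

* **Coordinates.** Internal coordinates are 0-based half-open on the
  J-strand (the majority strand as deposited). All file I/O uses the
  GenBank dialect: 1-based inclusive, `complement()` for the minority
  N-strand, two-segment `join()` for features crossing the circular
  origin. A feature wrapping the origin is stored unwrapped
  (`end > genome length`), which makes circular junction arithmetic a
  single subtraction.
* **Skews.** AT-skew = (A − T)/(A + T) and GC-skew = (G − C)/(G + C),
  computed on the strand stated. A zero denominator yields `NA` (JSON
  `null`), never an error.
* **Sense-strand rule.** Every gene-class composition row (PCG sets, tRNA,
  rRNAs, codon positions) is computed on the *sense strand* of each gene,
  concatenated. This is the only convention that reproduces the published
  sign structure — J-strand PCGs with negative GC-skew, N-strand PCGs with
  positive GC-skew — and it makes the whole profile invariant to how the
  genome was deposited.
* **Genetic code.** The invertebrate mitochondrial code (translation table
  5, from `Biostrings`), not configurable: AGA/AGG encode serine, the only
  stops are TAA/TAG.

## Junctions

Features are sorted by start; each adjacent pair contributes one junction
with gap = `next_start − prev_end`. Negative gaps are overlaps, positive
gaps spacers, zero abutting. Complete circular records close the chain
(n junctions for n features), which gives the conservation identity

  Σ gene lengths − Σ overlaps + Σ spacers = genome length.

Near-complete records — the common case when the control region resists
sequencing — are treated as linear: no junction is invented across the
missing region, matching how such genomes are described in the literature.
A feature nested inside its neighbour is reported as an overlap of the
nested feature's full length, loudly, rather than crashing: real
annotations contain such artifacts. CR-flanking junctions are excluded by
default because the CR boundary is an annotation convention more than a
biological junction; `include_cr = TRUE` restores them.

## Start/stop codon classification

The start codon is the first full codon after the `codon_start` offset;
ATN is canonical, everything else (e.g. the TCG of COX1 and TTG of ND1
common across flies) non-canonical. The stop is read from the 3' end of
the annotated span: length ≡ 0 (mod 3) with terminal TAA/TAG is complete;
a trailing T (mod 1) or TA (mod 2) is a partial stop, completed to TAA by
post-transcriptional polyadenylation. Any other terminus is *anomalous*:
a warning and a QC row, never an exception, because stop-codon anomalies
are exactly what annotation QC needs to surface. `validate_orf()` counts
internal stops after excluding the terminal (full or partial) stop.

Composition bookkeeping for partial stops is ambiguous in the literature,
so the choice is documented prominently: partial stop bases are included
in whole-PCG composition rows (they are genomic sequence) but excluded
from codon-position rows, because position labels are undefined for an
incomplete codon. This can shift third-position percentages by ≲0.1
relative to tools that drop or pad them.

## Supermatrices

`concatenate_blocks()` assembles four schemes: PCG123 (all codon
positions), PCG12 (third positions removed), and their +RNA variants. The
canonical concatenation order — PCGs, then tRNAs, then rRNAs, each in
ancestral-order rank — is fixed and documented; the source data do not
state an order, and changing it only relabels charset coordinates.
Partition counts follow from the construction: one charset per codon
position per PCG plus one per RNA gene (63 for PCG123RNA, 50 for
PCG12RNA, 39/26 without RNA). Hand-removal of ambiguous RNA columns is
not implementable verbatim; a reproducible gap-fraction filter
(`mask_ambiguous_columns()`, default off at threshold 1.0) stands in for
it, which is why published RNA-inclusive matrix widths are consistency
anchors, not bit-exact targets. Exporters write aligned FASTA, relaxed
PHYLIP, a NEXUS `sets` block, RAxML-style partition lines
(`DNA, ND2_pos1 = 1-1023\3`) and a PartitionFinder configuration stub.

## The simulator: a stated world

`sim_params()` encodes a muscoid-like mitogenome, and its defaults are
fixed commitments, not tuning knobs:

* 37 genes + CR in the ancestral insect order (23 J / 14 N genes);
* per-class sense-strand composition targets (A+T, AT-skew, GC-skew):
  PCG-J 74.9% / −0.13 / −0.09, PCG-N 78.5% / −0.20 / +0.28, tRNA 77.5%,
  rRNA 81%, CR 89.5% — the muscoid range; converted to base probabilities
  by p(A) = AT·(1+skew)/2 etc.;
* junctions: ATP8/ATP6 overlap 7 bp, trnW/trnC overlap 8 bp, the 27-bp
  TA-repeat spacer `GATATAAATTATATATATATATATATA` between trnS1 and trnE,
  the conserved 18-bp trnE/trnF spacer; all other pairs abut;
* start codons ATN except COX1 (TCG) and ND1 (TTG); stops TAA except the
  partial T of COX2 and ND5; gene lengths in the realistic insect range,
  with length mod 3 encoding the stop class.

PCGs are emitted codon-by-codon with in-frame TAA/TAG rejected, so every
ORF is clean by construction; start/stop codons and junction contents are
imposed exactly, and a bounded repair pass re-draws any free base whose
overlap-induced context created an in-frame stop. Codon-wise rejection
slightly depresses realized A+T below target (stops are AT-rich), which
is why the documented recovery tolerance for PCG classes is ±1.5
percentage points rather than the binomial band used for the iid classes.
All randomness flows through R's Mersenne-Twister from a single required
seed; fixed seed and parameters give byte-identical genomes.

What a green simulator-based test establishes: the analysis stages invert
the generator exactly (junctions, codon calls, ORF cleanliness,
composition within sampling error) on genomes with the stated structure.
What it does not establish: behaviour on real annotation dialects beyond
those the parsers model, rate heterogeneity, repeats, or any phylogenetic
signal — the generator makes single genomes, not alignments on trees.

## Numerical choices and degenerate inputs

* Percentages are computed at full precision; display rounding is 1
  decimal for percentages and 2 for skews.
* Ambiguity codes are preserved verbatim, counted, and excluded from all
  composition denominators.
* Empty sequences error; zero-feature records parse cleanly; records
  missing whole region classes simply omit those profile rows with a
  warning (as published tables leave CR cells blank for near-complete
  genomes).
* The convergence property for realized skews is checked at 10× lengths
  by averaging three replicates for AT-skew (single-replicate binomial sd
  is ≈0.01, exactly at the tolerance) and a 4-sd binomial band for
  GC-skew, whose denominator in these A+T-rich classes is ~5× smaller.
* Cross-species codon-position summaries pool base counts over strands
  and species before forming percentages; published per-position means
  mix strand classes in an unstated way, so pooled counts (the
  denominator-weighted convention) are used here.

## Limitations

GenBank parsing covers the location forms used by animal mitogenome
records (single spans, complement, two-segment origin-spanning joins);
exotic multi-segment joins are rejected rather than guessed. Leucine and
serine tRNA labels lacking a codon-family hint cannot be disambiguated
and map to `"unknown"`. Breakpoint counting uses the unsigned
adjacent-pair definition — sufficient for "same order as ancestral or
not", not a rearrangement-distance estimator. Alignment itself, model
selection and tree inference are out of scope; the package stops at the
matrices and partition files those tools consume.
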