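---
title: "mitocomp: methods, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitocomp: methods, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## The problem

Insect mitogenomes are circular ~15–18 kb chromosomes carrying 37 genes
(13 protein-coding, 22 tRNA, 2 rRNA) plus an AT-rich control region, in
an arrangement so conserved that departures from it are phylogenetically
informative. Lineages with parasitic life cycles — strepsipterans being
an extreme case — accumulate gene-order rearrangements, strong AT bias,
shortened genes and occasionally outright frame damage, while maternally
co-inherited endosymbionts such as *Wolbachia* can strip a species'
mitochondrial diversity by hitchhiking. `mitocomp` packages the analyses
these observations call for: signed circular gene-order comparison,
composition and codon-usage statistics, reading-frame integrity scans,
and intraspecific SNP/diversity summaries, together with a synthetic
genome generator that makes every stage testable without downloads.

## Gene orders as signed circular permutations

A `GeneOrder` is an ordered sequence of `(symbol, strand)` pairs with
unique canonical symbols. Circular orders compare equal under rotation
but **never** reflection: the major strand fixes the chromosome's
orientation, so flipping the whole molecule is not an isometry of the
data.

The comparison primitive is the *backbone*: a maximum-length common
subsequence of the reference and query restricted to shared symbols,
where a match requires symbol **and** strand to agree, maximized over
rotations of the circular query. Fixing the reference linearization is
exact here: any cyclic common subsequence can be read as a linear
subsequence of the fixed reference starting after the reference's cut,
and the matching rotation of the query realizes the same linearization.
Ties among equally long backbones are broken deterministically —
prefer the backbone containing `cox1`, then the lexicographically
smallest symbol string — for reproducibility; when several maxima exist
the event *count* is unaffected, only which of two interchangeable genes
is named "moved" can differ.

Per-gene events follow from the backbone:

* **transposition** — shared gene off the backbone, same strand;
* **inversion** — off the signed backbone, opposite strand, but joins
  the backbone when its strand mismatch alone is waived (flipped in
  place);
* **inverse transposition** — opposite strand and relocated.

The unit of counting is the moved gene, not the minimal block-edit
scenario: three genes moved as a block count as three transpositions.
That convention reproduces published per-gene transposition counts and
makes the count equal to `shared − |backbone|` (minus in-place flips),
which is exactly what the exhaustive oracle `brute_force_min_removal`
computes by enumeration on ≤ 12-gene instances. The control region may
anchor rotation but is never counted as an event. Partial genomes are
compared on shared genes only, with exclusions listed.

One deliberate deviation from the written contract: the minimal removal
count equals moved genes **plus in-place inversions** (a strand
mismatch prevents signed identity just as a relocation does); the
contract's alternative phrasing double-counted inverse transpositions,
which are already moved genes. The property suite verifies the
implemented identity on hundreds of random signed orders.

## Composition

AT skew = (A−T)/(A+T), GC skew = (G−C)/(G+C), computed on the major
strand as deposited. Ambiguity characters (anything outside ACGT) are
excluded from numerator and denominator and tallied (`n_excluded`) —
the simplest auditable rule. A zero denominator yields a *missing*
skew, never 0, because "no AT bases" and "perfectly balanced" are
different facts. Sliding-window profiles report per-window content
minus the whole-sequence mean; defaults are window 500 bp, step 100 bp,
circular wrap on — the published circular-track figures do not state
their parameters, so these defaults are documented and configurable
rather than claimed.

## Codon usage

The genetic code defaults to NCBI translation table 5 (invertebrate
mitochondrial), in which TGA is tryptophan and AGA/AGG are serine;
switching to table 2 reassigns AGA/AGG to stops and the test suite
covers the switch. Start codons in `{ATN, GTG, TTG, GTT}` are classed
canonical; anything else (e.g. an annotated CAA start) is flagged, not
rejected. A CDS whose length is not a multiple of 3 is taken to end in
an incomplete stop (`T`/`TA`) completed by mRNA polyadenylation; only
complete in-frame codons are counted, and no codons are fabricated.
RSCU is observed count × degeneracy / family total; within every
observed family the values sum to the degeneracy (mean 1), codons of
unobserved families are missing (`NA`), and stop codons belong to no
family.

## Frameshift hypotheses

`detect_internal_stops` scans the annotated frame; the terminal codon —
the last complete codon when length ≡ 0 (mod 3), the trailing `T`/`TA`
otherwise — is never reported. Given internal stops,
`frameshift_hypotheses` asks whether one indel explains them: the
*deletion* hypothesis collects every position where re-inserting some
nucleotide restores a stop-free frame through the terminus; the
*insertion* hypothesis symmetrically deletes one nucleotide. Only ±1
events are considered. The implementation is O(L) (prefix/suffix stop
tables over the three frames plus a bridge-codon check); its candidate
sets are proven equal to a brute-force re-insertion oracle on hundreds
of random CDSs, including the boundary case where removing the final
nucleotide converts the offending stop into the repaired terminal.

A candidate set is reported as a set/interval, never a point: within a
repeat, neighbouring positions are mathematically equivalent. A point
estimate requires an outgroup — `refine_with_homolog` globally aligns
each repaired translation against a full-length ortholog protein
(BLOSUM62, gap opening 10, extension 1, all configurable) and keeps the
best-scoring positions; a unique best becomes `refined_position`, ties
retain the narrowed interval, and a best score below 30% of the homolog
self-score returns the report unchanged with a warning flag. Whether a
damaged gene is rescued by translational frameshifting or expressed as
a truncated product is not a question sequence analysis can settle; the
report states the truncated-product length and takes no position.

## Variants, SNPs and diversity

Conspecific variants are aligned center-star against the longest
sequence (match +1, mismatch −1, gap −2, linear penalty) — for
near-identical conspecific mitogenomes this is effectively exact, and
pre-aligned equal-length input is accepted verbatim. Inputs below 70%
identity to the center are refused as probably not conspecific.
Identity is computed over columns where both sequences have an
unambiguous base, so a half-masked low-coverage variant is not falsely
refused.

A SNP is a column with ≥ 2 distinct bases among ACGT; gaps and `N` are
missing data, never alleles, and a variant may simply have no call at a
SNP (the low-coverage case). Positions are reported on the first
input's ungapped coordinates. π is the mean over **all** sequence pairs
of the per-site difference proportion with pairwise deletion of missing
columns; consequently duplicating a variant *does* change π (the
convention is documented and tested) while the SNP count does not.
Because the published fold-difference figures (33.1×/14.7×) are not
derivable from the published per-gene table by any ratio we can define,
`fold_difference` reports both defined ratios — SNP density and π —
labelled, and asserts no single "the" fold difference.

## The synthetic world

`generate_template` states its world once: 16,255 bp (a strepsipteran-
scale genome), AT fraction 0.84 (strepsipteran bias; use ~0.72 for a
fruit-fly-like genome), genes contiguous in the ancestral order with
typical insect gene lengths (nad5 1,719 nt, cox1 1,536 nt, tRNAs 65 nt),
control region absorbing the remainder between `rrnS` and `trnI`. PCGs
are built codon-wise: canonical start, non-stop body codons sampled at
the target AT bias, complete TAA stop. The realized AT fraction is
checked within ±0.02 of target.

What it emulates: gene content and order, strandedness, AT bias,
open reading frames, sparse intraspecific SNPs (transition-biased 2:1),
a low-coverage variant masked to `N`, and a −1 frameshift deletion whose
repair hypothesis is valid by construction. What it does **not**
emulate: codon-position-specific skews, tRNA secondary structure,
overlapping genes, repeats in the control region, sequencing error, or
read-level data. A green planted-truth test therefore establishes that
the analysis recovers what was planted under ideal annotation — not
that annotation or assembly errors are survivable.

Two construction details matter for exactness. Planted transpositions
forbid destinations that recreate an original adjacency or land within
two genes of the origin; and because several random moves can still
create a backbone tie in which a bystander gene substitutes for a
planted one, destinations are re-drawn until the classifier round-trips
the exact planted event set — making manifest closure a property of the
generator, not of luck. Every generator takes a mandatory seed, records
it in the manifest, and reproduces byte-identical output for the same
seed.

## Numerical and formatting conventions

Coordinates are 1-based inclusive everywhere, GenBank-style; a feature
with start > end wraps the circular origin and is flagged. Gene-order
text files use the bit-exact one-line dialect `trnI + , trnQ - , …`.
The sparse SNP-matrix dialect fills the reference row, leaves
identical cells blank and writes missing calls as `.`; `read_snp_matrix`
inverts it exactly. Equal-start annotation ties sort by (end, symbol).
Unmappable or duplicate features in a GenBank record are retained in an
`unclassified` slot and reported, not fatal — partial reference records
must stay usable.

## Known limitations

* The backbone is a maximum-subsequence criterion; it counts moved
  genes, not rearrangement *operations* (a tandem-duplication/random-
  loss scenario is out of scope by design).
* Center-star alignment is adequate for conspecific variants; it is not
  a general MSA and the 70% identity refusal enforces that scope.
* Frameshift hypotheses consider ±1 events only; two compensating
  indels, or ±2 events, are invisible.
* The GenBank parser reads the feature subset mitogenome records use
  (CDS/tRNA/rRNA/D-loop, complement/join locations); it is not a
  general-purpose flat-file parser.
* RSCU on a single short gene is noisy; the package pools per genome by
  default and leaves per-gene pooling to the caller.
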