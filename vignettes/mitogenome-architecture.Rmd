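---
title: "Annotation refinement and architecture analysis of insect mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation refinement and architecture analysis of insect mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
library(dplyr)
```

# Scope and data model

Insect mitochondrial genomes are closed circles of 15–20 kb carrying a
near-invariant inventory: 13 protein-coding genes (PCGs), 22 tRNAs, two
rRNAs, and one large non-coding element, the A+T-rich (control) region.
`mitoarch` analyses the *architecture* of such a genome — gene boundaries,
overlaps and spacers, strand composition, codon usage, gene order, and
control-region repeat structure — starting from a nucleotide sequence plus a
gene feature table.

The central container is the `mito_genome`: an identifier, an optional
majority-strand sequence, and a feature tibble with 1-based **inclusive**
coordinates, strand coded `J` (majority) / `N` (minority), and optional
start/stop-codon and anticodon metadata. Coordinates are kept 1-based
inclusive throughout because that is how published mitogenome annotation
tables print them; conversions to half-open intervals happen only inside
arithmetic helpers. A feature with `end < start` wraps the circular origin;
the linearization origin is fixed at the first base of `trnI`, the
convention of published insect annotation tables, and `relinearize()`
rotates records annotated from any other origin. Features may exist without
a sequence (**coordinate-only mode**): every architecture statistic —
spacer and overlap totals, gene order, codon totals — is computable from a
printed annotation table alone, which is what makes the package's desk
checks possible without any sequence download.

`N` residues are tolerated in sequences but excluded from all composition
denominators, so percentages remain comparable across assemblies of
differing completeness.

# PCG boundary determination

Boundaries are refined under the invertebrate mitochondrial genetic code
(translation table 5: AGA/AGG = Ser, UGA = Trp, AUA = Met; the only stops
are UAA/UAG). The 5' end of a gene is the **first legitimate in-frame start
codon** in the search window that is not located inside a strictly upstream
same-strand gene; the legitimate set is `{ATA, ATT, ATC, ATG, GTG, TTG,
GTT}` — ATN plus GTG, TTG and the unconventional GTT, retained exactly as
used in hepialid mitogenome annotation practice. `cox1`, whose initiation
is notoriously ambiguous in Lepidoptera, is handled by a per-gene override
that additionally accepts CGA; the override mechanism deliberately does not
legitimise CGA globally.

The 3' end is the first in-frame UAA/UAG downstream. When that stop lies —
even partially — within a downstream gene on the same strand, the gene is
instead terminated immediately before the downstream gene's first base,
provided the 1- or 2-base remainder reads `T` or `TA`: a **truncated stop
codon**, completed to UAA by post-transcriptional polyadenylation after the
polycistronic transcript is cleaved at tRNA secondary structures. Two
boundary cases deserve note, and both are deliberate design choices:

* a full stop ending exactly at the downstream gene's first base minus one
  (i.e. abutting it) is *not* truncated — truncation applies only to stops
  overlapping the downstream gene;
* when the remainder does not spell `T`/`TA` (or is a whole codon), no
  truncation is possible and the overlapping full stop stands. This is
  exactly how the canonical 7-bp `atp8`/`atp6` overlap arises: `atp8`'s
  in-frame TAA lies inside `atp6`, yet the 2-base remainder before `atp6`
  does not read TA, so `atp8` keeps its complete stop.

Truncation is only ever evaluated against downstream genes on the **same
strand**; minority-strand genes are processed on the reverse complement
with coordinates mapped back afterwards.

The search-window width is a free parameter (`window`, default 60 bp,
centred on the hinted start). Published methods do not state how wide such
a window should be; 60 bp comfortably covers the uncertainty of
homology-derived hints while staying well below typical gene spacing.
rRNA boundaries are not computed: `rrnL` is taken to extend between its
flanking tRNAs and `rrnS`'s 3' end abuts `trnV`; the `rrnS` 5' end (in
practice placed by cross-species alignment) is accepted from input.

Codon totals follow the bookkeeping `(length − stop_length)/3` per gene
with `stop_length` 3, 2, 1 for `TAA|TAG`, `TA-`, `T--`; `count_codons()`
therefore needs only coordinates and stop tokens, no sequence.

# Composition, skews and codon usage

Strand asymmetry uses the standard statistics

$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C},$$

computed on whatever region is asked for; undefined denominators yield
`NaN`, never a silent zero. Reverse-complementing a sequence negates both
skews exactly, which the tests exploit as an algebraic oracle.

`composition_summary()` reproduces the customary per-region table: whole
genome (majority strand), PCGs, the three codon positions, tRNAs, each
rRNA, and the A+T-rich region. For the PCG rows the **sense** sequences
(minority-strand genes reverse-complemented) are concatenated in annotation
order and stop codons are excluded; whether published tables complement
minority-strand genes before compositing is rarely stated, so this choice
is explicit and configurable by supplying your own sequence set to
`base_composition()`.

Codon usage is tallied over the 62 sense codons of table 5. Relative
synonymous codon usage is

$$\mathrm{RSCU}(c) = \frac{n_c \cdot k}{\sum_{c' \in \mathrm{fam}(c)} n_{c'}},$$

the observed count relative to expectation under uniform usage within the
codon's synonymous family of size $k$. Families follow the mitochondrial
presentation with Leu and Ser each split in two — Leu(UUR)/Leu(CUN),
Ser(UCN)/Ser(AGN) — because the classical six-fold grouping would change
every Leu/Ser RSCU value. Within each populated family RSCU sums to the
family size; zero-count families report `NaN`.

# Overlaps, spacers and the conservation identity

Adjacent features in circular order are compared by the signed gap
`start(next) − end(prev) − 1`: positive gaps are intergenic spacers,
negative gaps overlaps, with the circle closed through the origin. The
control region must be present as a feature so its interior is never
counted as spacer; the spacer total is then the genome's noncoding content
*excluding* the A+T-rich region. Overlaps are evaluated between
consecutive features only — nested features are an annotation error, not a
biological configuration of these genomes.

Every complete record must satisfy the conservation identity

$$\sum \mathrm{feature\ lengths} + \sum \mathrm{spacers}
  - \sum \mathrm{overlaps} = \mathrm{genome\ length},$$

exposed as `architecture_checksum()` and asserted across both bundled
annotation tables and all generator output.

# Gene order and rearrangement classification

`extract_gene_order()` reduces a record to its circular sequence of
(gene, strand) pairs; equality is rotation-invariant. Two reference orders
are built in: the ancestral insect arrangement (that of *Drosophila
yakuba*, with `trnI-trnQ-trnM` between the control region and `nad2`) and
the arrangement shared by all ditrysian Lepidoptera sequenced to date,
which differs only by the translocation of `trnM`.

Rearrangements are classified by the standard three-way taxonomy: a gene
with unchanged neighbour context but flipped strand is a **local
inversion**; changed context with retained strand is a **translocation**;
both changed is a **remote inversion**. Because moving one gene also
disturbs its neighbours' contexts, events are attributed by a
**minimal-mover** rule: the smallest set of genes whose removal makes the
two circular orders identical, found by exhaustive search over
growing subset sizes of the context-changed genes (depth capped at 4 —
published insect rearrangements involve one to three movers). Ties between
equally small sets prefer tRNA movers, the empirically common movers in
insect mitogenomes. How to attribute events when two blocks move
symmetrically is not formalised anywhere; the minimal-mover rule is this
package's documented choice, verified against brute-force single-gene
removals on small orders.

# Control-region tandem repeats

`find_tandem_repeats()` is a bespoke period scan, not a re-implementation
of any external repeat finder's scoring. For each candidate unit length
$u$ (default 10–300 bp, bracketing the >50 bp "macrorepeat" units of
lepidopteran control regions):

1. the region is compared against itself shifted by $u$; a pair of adjacent
   unit windows agreeing within the Hamming tolerance (default 10% of $u$)
   seeds an array, with the seed phase refined to the window of minimum
   mismatch within one unit;
2. the array grows copy by copy against the running per-column **majority
   consensus** (full copies vote; partials do not), with a slightly looser
   per-copy tolerance (twice the seed tolerance) so one noisy copy cannot
   split an array;
3. partial head/tail copies are added by maximising
   $\mathrm{matches} - \lambda\,\mathrm{mismatches}$ with
   $\lambda = 0.6/\mathrm{tolerance}$ (= 6 by default): an extension
   segment must exceed ~85% local identity to be kept, so unrelated
   A+T-biased flank (~40% identity) is rejected while a genuine partial
   copy carrying an isolated substitution is absorbed; ties favour the
   shorter extension;
4. margins whose penalised score is negative are trimmed, so a seed that
   started a few bases inside the flank cannot drag the boundary outward.

Copy number is the fractional span/unit reported to one decimal — eight
full copies plus a 57-bp partial of a 113-bp unit report 8.5, four full
107-bp copies plus a 101-bp partial report 4.9. Calls whose consensus unit
is itself periodic (a harmonic of a shorter period, or a homopolymer run)
are suppressed: such arrays belong to their fundamental period, which is
reported if it lies within the scanned range and silently ignored
otherwise. Overlapping survivors collapse to the highest penalised score,
then the smallest unit, so a perfect array is reported at its fundamental
period rather than a multiple. The default `min_copies` of 2.5 keeps
chance dinucleotide-scale structure out of reports on real control
regions.

Motif search (`find_motif()`) is plain Hamming matching reporting all,
possibly overlapping, hits — used for the replication-origin-associated
`ATAGA` element and the `ATACTAA` spacer motif with its one-mismatch
variants. `find_poly_t()` reports maximal `T` runs; the default minimum of
16 bp comes from the 16–22 bp poly-T element conserved in ditrysian
control regions.

# tRNA stem accounting

Cloverleaf structures are **input**, not predicted — in practice they come
from covariance-model predictors plus manual curation, which is out of
scope to reproduce. The interchange format is a three-line record: header,
sequence, and a dot-bracket line with commas delimiting the arms
(acceptor 5' half, DHU, anticodon, optional variable region, TψC,
acceptor 3' half). Pairs opening and closing within one internal segment
belong to that stem; pairs spanning the outer segments form the acceptor
stem; an all-dot DHU segment flags the DHU-arm-replaced-by-loop
configuration of `trnS(AGN)` common to many arthropods.

`classify_pairs()` partitions stem pairs into Watson–Crick (`A:U`, `G:C`),
G–U wobble, and mismatches, the latter tallied by unordered identity in
the RNA alphabet (`A-C` ≡ `C-A`). Classification is invariant to pair
order and to swapping the 5'/3' members of a pair. Note that
*complementing* both members is **not** an invariance of this partition —
the complement of a G–U wobble is a C–A mismatch — so no such property is
asserted. The anticodon is read 5'→3' as the central triplet of the
anticodon loop.

# The synthetic genome generator

`simulate_mitogenome()` exists so that every stage of the pipeline can be
validated against a known truth table. Its defaults *are* the study
conditions the analysis targets: the ancestral gene order; per-gene length
targets matching a hepialid-like genome (PCG lengths compatible with their
stop tokens, tRNAs of 60–73 bp, rRNAs of 1335/779 bp); whole-genome A+T
near 0.81 with a slight A skew (+0.011) and strong C skew (−0.19); the
7-bp `atp8`/`atp6` overlap; eight PCGs ending in truncated stops that abut
their downstream genes; a 49-bp spacer plan; and a control region with
eight full copies plus a 57-bp partial of a random 113-bp unit between
200-bp non-repetitive flanks at A+T 0.90.

Construction details that matter for interpreting test results:

* **PCGs are genuine ORFs**: sense codons are sampled from per-codon
  weights (default: product of the skewed base probabilities, normalised
  over the 62 sense codons), so generated coding sequence has no internal
  stops in frame and its RSCU estimates converge on the spec's weights —
  the rank-correlation recovery property checked in the tests.
* **The PCG/PCG overlap is constructed, not accidental**: the upstream
  gene's tail is resampled until it simultaneously hosts the downstream
  start codon, keeps every upstream codon sense, leaves no truncatable
  `T`/`TA` remainder (which would make the boundary ambiguous), and
  contains no spurious legitimate start in the downstream reading frame.
* **Start ambiguity is scrubbed**: after assembly, any legitimate start
  triplet inside a PCG's upstream search window — necessarily in spacer or
  placeholder tRNA/rRNA sequence — is mutated away (planted anticodons are
  preserved), so `annotate_pcgs()` recovers every truth boundary exactly.
  This is a property of the generator, not of the annotator: on real
  genomes an upstream in-frame legitimate codon within the window is
  genuinely ambiguous and the documented recovery guarantee is
  conditional on its absence.
* **Noise is substitution-only** in the control-region repeats, keeping
  planted unit lengths exact for copy-number validation; the flank bases
  touching the array are chosen not to continue it, so planted spans are
  exact too.
* **tRNA/rRNA sequences are placeholders**: A+T-biased random sequence
  carrying a planted central anticodon, with no attempt at foldability.
  They exercise coordinates, order, overlap and spacer logic only.

What passing tests therefore show: the pipeline's bookkeeping, boundary
rules, statistics and detectors are correct on data with the assumed
structure. What they do not show: robustness to assembly error, indels in
repeat arrays, genuinely ambiguous starts, or tRNA structural variation —
real-data phenomena the generator deliberately does not emulate.

# Numerical choices and problem sizes

Percentages are reported to full precision and compared at tolerance 0.01
(two-decimal table formatting); copy numbers to one decimal; RSCU family
sums to machine precision. Degenerate inputs are errors, not warnings:
empty sequences, coding lengths not divisible by 3 (named per gene),
coordinates outside the genome, duplicate genes in an order. The test
suite runs the generator at full genome scale (~16 kb) because generation
and annotation are fast; boundary-recovery properties use 20+ independent
seeds, repeat-detector round-trips 20 planted (unit, copies, partial,
noise) combinations, and the rearrangement minimal-mover check exhaustive
search on 7-gene orders.

# Known limitations

* The minimal-mover search is exact only up to its depth cap (4 movers);
  heavily shuffled genomes error out rather than guess.
* The repeat detector reports arrays at one period each; genuinely nested
  repeat structures (repeats within repeat units) surface only at their
  fundamental period.
* GenBank reading supports the single-record flat files distributed for
  mitogenomes (simple and `complement()` locations, two-segment
  origin-spanning `join()`); it is not a general GenBank parser.
* Start-codon determination trusts the hint windows; it does not do
  homology search, and genes whose true start lies outside the window are
  reported as per-gene failures rather than guessed.
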