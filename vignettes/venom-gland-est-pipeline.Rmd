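---
title: "Methods: a venom-gland EST pipeline on synthetic libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a venom-gland EST pipeline on synthetic libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

venomest re-implements, as a tested library, the analysis workflow used for
classic single-pass venom-gland EST studies: clean raw reads, cluster them
by pairwise overlap into contigs and singletons ("unisequences"), annotate
each unisequence against a labeled reference collection, and mine the
results for SNPs, indels, microsatellites, transposable elements (TEs),
TE-host chimeras and long inverted repeats (IRs). Because the original
data of such studies are archival trace sets and the original tool chain
(Phred, CAP3, BLAST against 2008-era databases, RepBase 14.08, QualitySNP)
is not reproducible bit-for-bit, the package pairs the pipeline with a
synthetic library generator that emulates the statistical structure of a
three-snake venom-gland cDNA library and records complete ground truth, so
that every stage is testable end to end without downloads.

## Alignment model and E-value statistics

All similarity steps share one local-alignment engine: Smith-Waterman with
affine gaps (a gap of length $L$ costs `gap_open` $+ L \cdot$
`gap_extend`), exact dynamic programming, no heuristic seeding for the
alignment itself. The default nucleotide scores are BLASTN-like: match
$+1$, mismatch $-3$, gap open $-5$, gap extend $-2$. `N` never counts as a
match. Beyond the single best alignment the engine reports further local
alignments that do not overlap already-reported query intervals
(Waterman-Eggert style, by query masking and re-running the DP), which is
what vector screening and multi-copy TE annotation need.

Hit significance uses Karlin-Altschul statistics,
$E = K m n e^{-\lambda S}$, with $m$ the query length, $n$ the total
database length (no edge corrections; the cutoffs in play are coarse).
$\lambda$ is calibrated at scheme construction as the unique positive root
of $\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ (solved to $10^{-12}$ by
`uniroot`; a non-negative expected score is an error). $K$ is a stored
constant, default $0.71$ — the standard ungapped value for $+1/-3$ — and
both $\lambda$ and $K$ can be overridden. Applying ungapped statistics to
gapped scores is an approximation; for the thresholds used here
(annotation at $E \le 10^{-5}$, TE detection at $E \le 10^{-10}$) true
hits sit many orders of magnitude below the cutoff and random hits many
above, so the approximation never decides a call in practice.

Internally all coordinates are 0-based half-open; the BLAST-style 12-column
TSV report converts to 1-based inclusive.

## The synthetic library

`generator_config()` defaults encode the study conditions the pipeline is
exercised under:

* **Composition.** 30% of reads derive from annotatable (reference-
  represented) transcripts; toxin reads are 23% of all reads, so toxins are
  roughly three quarters of hits. The toxin-class mixture is
  metalloproteinases 0.81, BPP/CNP precursors 0.088, PLA2 0.056, serine
  proteinases 0.019, C-type lectins 0.015, other toxins 0.012.
* **Length.** The post-cleaning target length is truncated normal on
  $[100, 848]$ bp with location 573 and scale 150, chosen so the truncated
  mean is 562 bp.
* **Library structure.** Three plates (sequencing batches) assigned
  uniformly; reads are 5' single-pass with a small geometric 5' offset
  (rate 0.03), and the deposition strand is randomised so assembly must
  handle both orientations.
* **Decorations.** Half the reads carry a 5' vector prefix (25-80 bp cut
  from a synthetic 600-bp vector); 85% carry a 25-bp 3' polyA tail whose
  PHRED quality decays linearly (start 28, slope $-1$ per base), which is
  what gives the quality trimmer real work. Core bases are
  $\mathcal{N}(35, 3)$ clipped to $[25, 45]$.
* **Errors.** Substitution miscalls at 0.5% per base (the paper gives no
  rate; this is a typical capillary figure). Miscalled bases get low PHRED
  scores ($\sim\mathcal{N}(12,3)$, clipped below 20) — an idealised,
  perfectly calibrated base caller. This idealisation matters: it is why
  the quality gate in the SNP caller removes essentially all error support.
  Real Phred scores are well but not perfectly calibrated, so real-data SNP
  precision would be somewhat lower at high depth.
* **Planted features.** By default a small registry of SNPs (minor-allele
  frequency 0.5, on abundant metalloproteinase templates, within the
  well-covered 5' 500 bp), indels, microsatellite arrays, TE insertions
  (two chimera-eligible fusions, one small insertion, one TE-dominated
  transcript kept rare) and two inverted repeats, one of them with the
  132-nt-arm / 183-nt-spacer architecture. Every plant is recorded with
  exact template coordinates in the ground truth.

Templates are i.i.d. random DNA. The generator therefore does **not**
emulate codon usage, shared domains between paralogous toxin genes, UTR
composition bias, or chromatogram-level error structure. Passing tests
show the pipeline's logic is correct under the configured composition,
coverage and error model; they do not show that, e.g., assembly would
separate real SVMP paralogs at 95% identity, which is exactly the regime
where real EST assemblies are hard. One realistic pathology *is* retained:
two default templates share a BovB segment, and reads bridging the shared
repeat co-assemble — the classic repeat-induced misassembly — and a
TE-bearing no-hit transcript gains a reference hit through the repeat,
slightly inflating the hit fraction (by about 0.2 percentage points at the
default rarity).

## Cleaning

Stages run vector → quality → polyA/polyT → slippage, then the strict
$<100$ bp discard. Vector removal comes first so contaminant bases cannot
distort the quality windows. Rules, all configurable via
`cleaning_params()`:

* **Vector:** any read interval aligning to a vector record at score
  $\ge 20$ (either strand) is excised; non-contiguous remainders keep the
  longest fragment; fully-excised reads are `discarded_all_vector`. The
  threshold is set so a 25-bp exact match is decisive while chance matches
  (expected best score $\approx 10$ at this scale) never trigger.
* **Quality:** keep the longest contiguous segment in which *every*
  20-base sliding window has mean PHRED $\ge 16$; reads shorter than one
  window are judged as a single whole-read window; an empty result is
  allowed.
* **polyA/polyT:** remove a terminal run of $\ge 10$ A's (3') or T's (5')
  allowing at most 1 interior non-matching base; the run must begin and
  end on a matching base; interior runs are untouched. Template-terminal
  A's adjacent to a tail are indistinguishable from it and are trimmed —
  an inherent, documented ambiguity (cleaned reads are never longer than
  the configured clean length, occasionally a few bases shorter).
* **Slippage:** a read is discarded if any 50-base window is dominated
  ($\ge 80\%$, boundary inclusive) by one nucleotide, or if it carries an
  exact 2-periodic (dinucleotide-unit) run covering that fraction of a
  window. "Slippage signal" has no published definition in this lineage
  of pipelines; this dominance rule is an explicit stand-in.

Cleaning only ever removes bases (every output read is a contiguous
interval of its input) and is idempotent.

## Assembly

Pairwise overlaps are accepted at $\ge 100$ alignment columns and
$\ge 95\%$ identity **over the overlap alignment** (the inclusive reading
of the threshold, applied to the local alignment, not to whole-read
identity). Clusters are the transitive closure (union-find) of accepted
overlaps; candidate pairs come from a shared canonical-16-mer prefilter
(content-subsampled so both mates sample identical k-mers), and pairs
already connected are skipped without alignment, which cannot change the
closure. Reads are sorted by id on entry, so the partition and all
downstream output are independent of input order.

Each cluster is assembled greedily: the seed is an endpoint of the
best-scoring accepted overlap, members join in Prim order over the overlap
graph, and each is placed by its best local alignment to the growing
backbone (read overhangs extend the backbone; internal clipped tails are
dropped; read insertions relative to the backbone occupy fractional layout
columns). Members that cannot be placed at the overlap thresholds seed a
new sub-contig rather than being force-merged. The consensus takes, per
padded column, the quality-weighted majority symbol — ties resolve by base
order A, C, G, T with the pad last — and pad-majority columns are dropped,
so an insertion survives exactly when a quality-weighted majority of
covering reads supports it. This is a deliberately simple assembler, not a
CAP3 re-implementation; reproducing a specific historical contig/singleton
split is a non-goal.

## Annotation and abundance

Each unisequence is searched (both strands) against every reference
record, with a shared-14-mer prefilter to skip records that cannot hit; a
unisequence is a **hit** if any alignment reaches $E \le 10^{-5}$, with
$n$ = total reference length. The class label is the best hit's label
(best-hit annotation, as in the original practice). The hit region is
`utr_only` when the subject interval is disjoint from the reference CDS,
`coding` otherwise; coding hits get a reading frame by mapping the aligned
interval into CDS codon coordinates (strand, phase of query position 0,
and a per-position query-to-subject map that is NA inside gaps).

Abundance is counted in **ESTs** (reads): a contig contributes its member
count. Both denominators are reported — percentages of all ESTs and of
toxin ESTs — because the two conventions answer different questions and
the source literature uses both.

## Variant and repeat mining

**SNPs.** A contig layout column is a SNP only if the contig has $\ge 3$
reads; at least two alleles each have $\ge 2$ supporting reads with base
quality $\ge 20$; the supporting reads jointly span $\ge 2$ plates; and
each supporting read is pad-free for 5 columns on either side. The plate
rule is the printed artifact control (independent libraries sequenced on
separate plates); QualitySNP's internal haplotype heuristics are replaced
by these explicit support rules. Indels are maximal runs of adjacent
pad-bearing columns where both the padded and unpadded allele meet the
same support rules. Synonymy classification substitutes each allele into
its codon via the annotation frame (standard genetic code) and is
symmetric in allele order; positions outside the CDS are `noncoding`,
positions that do not map cleanly are `frame_unknown`.

**Microsatellites.** Exact maximal tandem arrays of primitive 1-6-mers,
thresholds 12/7/5/4/4/4 copies (the external tool's parameters are not
published; these are stated defaults), canonical (lexicographically
smallest) motif rotation, fractional trailing copies included, nested
reports suppressed in favour of the smaller period. TE exclusion removes
arrays on any TE-annotated unisequence (sequence-level, following the
source wording).

**TEs and chimeras.** TE annotations must pass four gates: $E \le
10^{-10}$, alignment $\ge 50$ bp, identity $> 80\%$ (strict), and coverage
$\ge 10\%$ of the *unisequence* length (the "10% of their lengths" phrase
is ambiguous between unisequence and element; unisequence is the default,
configurable). A unisequence is chimera-eligible when total TE coverage
lies strictly inside (10%, 90%); its TE intervals are masked with N and
the remainder re-queried against the host references; the call is chimeric
when the best host hit covers $\ge 50\%$ of the **unmasked** length at
$\ge 70\%$ identity. The unmasked denominator is a deliberate choice: at
90% TE coverage only 10% of the sequence remains, so the whole-length
reading of "50% of the sequence" would be unsatisfiable. The re-query is
nucleotide-level (the original remote tBLASTX is out of scope), with the
identity threshold applied at nucleotide level.

**Inverted repeats.** The sequence is compared against its own reverse
complement; gap-free arm pairs live on anti-diagonals of that comparison.
Per anti-diagonal the scanner reports the valid window — endpoints
matching, arm $\ge 30$ bp ("long" IR; no published length exists),
mismatch fraction $\le 10\%$ inclusive — that maximises the
match/mismatch score, preferring the shorter window on ties. Maximising
*length* under the mismatch budget is ill-posed: the budget grows with
length, so a perfect palindrome always gets absorbed into a longer noisy
window; score maximisation returns the planted arms exactly. Arm pairs
must clear a self-alignment E-value of $10^{-5}$ (search space = sequence
length squared) and are selected greedily by score with non-overlapping
arms. The automated mismatch rule replaces the original visual inspection
of self-BLASTN output. The generator, for its part, plants IRs whose
junction bases cannot extend the palindrome, so ground-truth coordinates
are exact and the Figure-style 132/183 architecture round-trips to the
base.

## Evaluation harness

Calls are mapped back to template coordinates by locally aligning each
unisequence to the majority template of its member reads; a call matches a
planted feature of the same type on the same template within a tolerance
(0 for SNPs, $\pm 5$ bases for interval features). Sensitivity is
matched/planted, precision matched/called (undefined on zero calls).
Chimera truth is defined by template-level TE coverage, calls by
unisequence-level coverage; partially covered templates can legitimately
disagree at the 10% boundary, which is why the exact-match checks use
interior coverages.

## Problem sizes and runtime choices

The composition study runs the full clean-assemble-annotate path on 5,000
reads (the study-scale library; about 1.5 minutes on one core). Feature-
recovery experiments use 150-400 reads with coverage set by their stated
conditions (6-8x over the polymorphic templates, error-free where the
condition says error-free). Property tests run the exhaustive alignment
oracle on sequences up to 12 nt and the quadratic IR oracle on sequences
of a few hundred bases; the scanners themselves handle multi-kilobase
transcripts directly.

## Known limitations

* Random-DNA templates: no paralog structure, so assembly and best-hit
  annotation are easier than on real toxin families.
* Ungapped E-value statistics applied to gapped scores (coarse cutoffs
  only).
* The assembler is greedy single-pass with one consensus round; it splits
  rather than resolves conflicting layouts and does not handle deep
  repeat-induced joins.
* Miscall quality is idealised low, making quality-gated SNP precision
  optimistic relative to real trace data.
* The chimera host re-query is nucleotide-level; remote protein-level
  search is out of scope.
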