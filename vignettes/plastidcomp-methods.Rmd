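---
title: "Methods: comparative plastome analysis with plastidcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastidcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`plastidcomp` analyses sets of complete chloroplast genomes: the
quadripartite LSC/IRb/SSC/IRa architecture and its junctions, perfect
microsatellites (SSRs), alignment-based divergence statistics, and
pairwise dN/dS on shared protein-coding genes. A synthetic plastome
generator with exact event logs provides ground truth for every stage, so
the whole pipeline is testable without downloads. This vignette explains
the models and the choices behind them; the README shows a worked run.

# Coordinates and the circular contract

Plastomes are circular. All user-facing coordinates are 1-based inclusive;
an interval that crosses the origin is always represented by splitting it
into two linear pieces (never by coordinates outside `[1, L]`). Interval
arithmetic on the circle (`end < start` means a wrap) is confined to a
small helper layer that everything else shares.

# Quadripartite structure detection

The inverted repeats are found as the **maximal-length pair of disjoint
exact reverse-complement repeats** on the circle, seeded with 31-mers on
the doubled sequence: a maximal exact inverted match of length *m*
contains exactly *m* − 31 + 1 consecutive seed hits on one anti-diagonal,
so maximal matches are maximal runs of consecutive seeds per diagonal and
no character-level extension step is needed. 31-mers are effectively
collision-free at plastome scale (~160 kb), and real plastome IR copies
are near-identical, so exactness costs nothing while keeping detection
deterministic and directly comparable to a quadratic oracle (the test
suite checks equality against an anti-diagonal scan of the full match
matrix on small genomes).

Of the two single-copy arcs between the repeat copies, the longer is LSC
and the shorter SSC. Junction coordinates follow the convention that
JLB/JSB/JSA are the **first base of the downstream region** and JLA is the
last base of IRa, i.e. after canonical rotation `JLB = LSC + 1`,
`JSB = LSC + IR + 1`, `JSA = LSC + IR + SSC + 1`, `JLA = genome length`.

**Canonical form.** The genome is rotated so LSC starts at base 1 with
region order LSC, IRb, SSC, IRa. Both strands satisfy that layout, so a
tie-break is needed; we pick the strand whose canonical rotation is
lexicographically smaller. The rule is arbitrary but deterministic,
idempotent, and invariant under rotation and strand flip of the input —
inputs that differ only by rotation/flip always canonicalize to the same
sequence. No attempt is made to standardize SSC flip isomers beyond this.

Junction context reports, for each junction edge (between coordinate
J − 1 and J), the nearest gene on each side: distance 0 with an overlap
length when the gene covers the adjacent base (the overlap is the number
of gene bases on the reported side), otherwise the gap in bp.

# SSR scanning

A locus is a **maximal perfect tandem run** of a primitive 1–6 bp motif
whose copy number meets the per-unit-length threshold. Default thresholds
are 8/4/4/3/3/3 copies for mono- through hexanucleotides, the common
MISA-style configuration for plastome surveys. Detection builds, for each
unit length *u*, the circular match vector `cmp[i] = (seq[i] == seq[i+u])`;
maximal runs of `TRUE` are exactly the maximal tandem spans. The locus
starts at the leftmost base of the run and covers `floor(span/u)` complete
units; a trailing partial unit never extends it. Requiring the motif to be
primitive (not itself periodic) implements the smallest-primitive-unit
rule: a poly-A run is one mononucleotide locus, never also an "AA" locus.
Only perfect repeats are reported; compound/interrupted microsatellites
are out of scope.

Motifs are canonicalized to the lexicographically smallest string among
all cyclic rotations of the motif and of its reverse complement, so e.g.
`TA`, `AT`, and their complements are one type.

Classification assigns each locus by its **midpoint**: the structural
region is the partition span containing the midpoint, and the functional
region is `gene` if the midpoint lies in an exon, `intron` in a derived
intron, else `intergenic`, with precedence gene > intron > intergenic when
annotations overlap. The midpoint rule is a deterministic, symmetric
choice for loci straddling a boundary. Densities are pooled counts per kb
of pooled region length, reported to 2 decimals.

# Alignment divergence statistics

The package consumes a whole-genome multiple alignment produced
externally (e.g. MAFFT); it never computes alignments itself.

**Gap policy.** For site classification, pi and theta, the package follows
the complete-deletion convention: a column counts only if **no** sequence
has `-` or `N` there (`N` is treated as a gap to avoid inflating
diversity). A column is *variable* with ≥ 2 distinct bases and
*parsimony-informative* when ≥ 2 distinct bases each occur in ≥ 2
sequences.

**Diversity.** pi is the mean proportion of differing sites over all
sequence pairs; Watterson's theta is `S / (a_n · L)` with `a_n` the
(n−1)-th harmonic number, `S` the segregating gap-free columns and `L` the
gap-free columns used. Sliding windows (default 600 columns, step 200,
the common plastome setting) are defined on **alignment columns**, with
complete deletion applied per window; a trailing shorter window is kept
and flagged.

**Hypervariable regions.** Windows with positive pi are accumulated in
decreasing-pi order (ties by coordinate); overlapping windows merge, and
accumulation stops once `k` distinct regions exist (default 10). Each
region carries its peak window pi and the names of the reference features
it overlaps. This greedy rule needs no tuning threshold and provably
returns the `k` highest disjoint peaks; when fewer exist, all are
returned with a warning.

**Pairwise indels and substitutions.** For a pair of rows, columns gapped
in both are dropped; each maximal remaining gap run in either row counts
as **one indel event** regardless of length (so a gap run interrupted only
by shared gaps still counts once), and substitutions are columns where
both rows carry unambiguous bases that differ.

**Per-region variability** uses a different column accounting, on
purpose: for each gene (over its exons), intron and spacer of the
reference annotation, the percentage of variable columns is computed over
the full column span of the region **including** columns where some taxa
are gapped, with `-` counted as a state. A region deleted in some taxa
therefore approaches 100% variability, which is the biologically intended
reading (fragment loss is divergence), while the genome-wide site classes
above deliberately exclude such columns.

# dN/dS estimation

Shared protein-coding genes — annotated, non-pseudo, in-frame, internally
stop-free and of equal CDS length in every genome — are stripped of their
terminal stop codon and concatenated in alphabetical gene order (pairwise
counts are order-invariant; the fixed order makes output reproducible).
Genes failing any check are excluded with a logged reason. Because the
package does not align, genes whose CDS lengths differ between genomes
are excluded rather than codon-aligned; on annotation-preserving inputs
(no indels in genes) this loses nothing.

Rates use the Nei–Gojobori (1986) pathway method: per codon, each
position contributes the fraction of its three possible changes that are
synonymous (changes to stop codons count as nonsynonymous), averaged over
the two sequences, giving S and N sites with S + N equal to the
nucleotide length. Codons differing at 2–3 positions are resolved by
averaging synonymous/nonsynonymous steps over all orders of fixing the
differing positions, excluding pathways through stop codons (if all are
blocked, all pathways are counted as a degenerate fallback). Proportions
pS = Sd/S and pN = Nd/N are Jukes–Cantor corrected,
`d = −(3/4)·ln(1 − 4p/3)`; p ≥ 3/4 is flagged saturated. omega = dN/dS is
`NA` when dS = 0. NG86 is deliberately the estimator here — it is fully
verifiable against exhaustive pathway enumeration — rather than
yn00-style estimators that additionally model transition/transversion
bias and codon usage; omegas from the two families agree in direction and
magnitude but not digit-for-digit.

Extreme-value filters (defaults dN > 0.5, dS > 5, dS < 0.0005) guard
against saturation and ortholog misassignment; filtered pairs are flagged
and kept in the table but excluded from summaries. An identical pair
(dS = dN = 0) reports omega `NA` and is not treated as an extreme value.
The genetic code defaults to the standard table; the bacterial/plastid
table is selectable (identical amino-acid assignments, so results only
differ for organisms using other codes).

# The synthetic generator

`generate_plastome()` builds LSC + IRb + SSC + revcomp(IRb) with
region-specific GC (defaults 0.335/0.239/0.395 for LSC/SSC/IR and region
lengths 86,459/1,834/34,101 bp, emulating slipper-orchid-like plastomes
with expanded IRs and a minute SSC), plants genes (proper CDS with start
and stop, optional introns, strand-aware; IRb genes mirrored into IRa on
the opposite strand) and SSR loci at recorded coordinates. Two
construction details make ground truth *exact* rather than approximate:
flanking bases of every planted SSR are set so the run cannot extend by
even one base, and the four junction-adjacent bases are resampled so the
planted IR pair is not extendable by chance. Background sequence is then
repaired (single-base edits, stop-codon-safe inside planted CDS, mirrored
into IRa through reassembly) until the scanner finds nothing but the
planted loci. The repair loop reuses `find_ssrs()`; this does not make
recovery tests circular because `find_ssrs()` is independently proven
equal to an exhaustive enumeration oracle on random sequences in the test
suite.

`evolve()` produces independent descendants (a star phylogeny):
per-site Bernoulli substitutions (uniform among the three alternatives,
optional per-span rate multipliers for hotspots), indel events with
geometric lengths. With IR homogenization on, substitutions in IRb are
mirrored as complementary changes in IRa and indels are confined to
single-copy regions, so descendant IR copies remain exact reverse
complements. The truth alignment is built by event bookkeeping — one
column per ancestor base plus a column block per insertion — never by
re-alignment, and the event log replays exactly onto the ancestor.

**What the generator does not emulate.** A star phylogeny has no shared
internal branches, so parsimony-informative sites are rare (shared
derived states arise only by coincidence) — real data with tree structure
has many; codon-level selection is absent from whole-genome evolution (a
separate helper, `simulate_codon_descendants()`, applies a configurable
synonymous acceptance bias for dN/dS testing); indel lengths are
geometric, without the long structural deletions real spacers show; and
background composition is i.i.d. within regions. Passing tests therefore
demonstrate correctness of the *computations*, not realism of any
biological conclusion.

# Numerical and degenerate-input choices

* GC content excludes ambiguity codes from numerator and denominator;
  zero-length or all-ambiguous intervals are errors.
* Detection with fewer than 2 sequences, alignments with no gap-free
  column, and codon pairs with no comparable codon raise errors rather
  than returning silent zeros.
* Window/step of 600/200 columns, minimum IR length 1000 bp, SSR
  thresholds 8/4/4/3/3/3 and the dN/dS filters above are the defaults a
  plastome survey would use; all are arguments.
* Ties: equal-length best IR pairs break by smallest JLB then smallest
  rotation offset; equal-pi hypervariable peaks break by coordinate;
  equal-length single-copy arcs label the arc following the first repeat
  copy as LSC.
* Fully periodic circles (e.g. a poly-A genome) yield one SSR locus
  capped at the genome length; palindromic self-matches are excluded from
  IR candidacy by the disjointness requirement.

# Problem sizes used by the tests and acceptance script

The test suite validates against oracles at the sizes where the oracles
are exact and fast: quadratic IR oracle on ~3–5 kb circles, exhaustive
SSR enumeration on 10 kb sequences (50 replicates), full pathway
enumeration over all sense-codon pairs, event-log bookkeeping on 20 kb
ancestors (10 replicates), and a 3-sigma binomial envelope for diversity
on 200 kb genomes (5 replicates). The acceptance script runs the full
pipeline once at realistic scale: a 156,495 bp synthetic plastome, eight
descendants for diversity statistics (with region multipliers 1.0/2.0/0.26
for LSC/SSC/IR around a 0.5%-per-lineage baseline, emulating the
conserved-IR pattern), three descendants with indels for pairwise counts,
and a nine-taxon selection-biased codon set for dN/dS.
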