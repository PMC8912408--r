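---
title: "Plastome structure analysis with plastshift: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome structure analysis with plastshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastshift)
```

## The problem

Angiosperm plastid genomes (plastomes) are circular molecules with a
quadripartite architecture: a large and a small single-copy region (LSC,
SSC) separated by two identical inverted-repeat copies (IRb, IRa). Most
structural diversity between close relatives comes from movements of the
four region junctions — J_LB (LSC/IRb), J_SB (IRb/SSC), J_SA (SSC/IRa) and
J_LA (IRa/LSC) — which duplicate genes into the repeat or release them into
single copy, create truncated pseudogene copies at the boundaries, and can
leave behind "hidden" non-coding insertions in intergenic spacers. Two
further recurrent phenomena matter for comparative work: short (roughly
3–62 bp) inversions flanked by complementary repeats, which form hairpins
and flip orientation within and between species, and junction
misassemblies, which read mapping reveals as localized coverage drops.

plastshift implements this comparative workflow end to end: exact IR
detection and partitioning, junction localization and classification,
spacer-insertion screening, in-silico PCR surveys, junction coverage QC,
small-inversion detection and correction in alignments, and supermatrix
site statistics (variable and parsimony-informative counts, Fitch
parsimony with consistency/homoplasy indices, site concordance factors and
per-branch putative synapomorphies). A synthetic-plastome generator with
ground-truth records makes every stage testable without any external data.

## Inverted-repeat detection

The IR pair is defined as the maximal-length pair of disjoint, *exactly*
reverse-complementary substrings on the circle, at least `min_ir_length`
(default 1000) bases long. Exactness is deliberate: the two repeat copies
of a single assembly are identical by construction, and an exact definition
makes maximality well defined (extending either copy by one base breaks
complementarity). The search seeds on 16-mers shared between the sequence
and its reverse complement, groups seed pairs by anti-diagonal, and extends
each seed base by base; the circle is handled by scanning doubled
coordinates with the span capped at the genome length. Chance inverted
repeats in random sequence are far below the 1000 bp floor (tens of bases
at plastome sizes), so a genome with no hit is reported as IR-lacking
rather than forced into a quadripartite frame.

The partition is expressed on a canonical rotation: the LSC (the longer
single-copy gap) starts at position 0 and region order is LSC, IRb, SSC,
IRa, matching the junction names above. The orientation (whether the
reverse complement is reported) is chosen so that the intact ycf1 copy
sits adjacent to IRa — the convention implied by the classical truncated
pseudo-ycf1 at J_SB — with the lexicographically smaller LSC sequence as a
tie-break for unannotated genomes. Equal-length repeat candidates are
broken by smallest start coordinate. Internally all coordinates are
0-based half-open; every report converts to 1-based inclusive.

## Junctions, spacer insertions, and in-silico PCR

A junction's position is the first base of its downstream region; that
convention removes the ±1 ambiguity from distance reports. Classification
is `within:<gene>` when the position falls in an exon, `within-intron:<gene>`
between the exons of one feature, and `between:<A>,<B>` otherwise; a
feature that merely abuts a junction has distance 0 and does not overlap
it. Payload genes (trnH, psbA and fragments thereof captured into the
repeat by J_LA shifts) are listed for J_LB and J_LA and must be
mirror-symmetric between the two IR copies.

Insertion screening compares an observed spacer length against a baseline:
either an explicit number or a reference panel of spacer sequences (the
median panel length is the baseline). The call threshold `min_excess`
defaults to 200 bp — well above indel noise between close relatives and
well below the published hidden insertions (roughly 0.8–1.2 kb). With a
panel, the insertion is localized as the longest query segment unaligned
to the baseline spacer in a global alignment; with a bare number no
localization is possible and only the length excess is reported. Payload
fragments are recovered by local alignment (match +1, mismatch −1, gap −2)
in both orientations and reported at ≥ 70% identity over ≥ 50 bp; the
published reports give no thresholds for "significant similarity", so
these floors are explicit and configurable.

In-silico PCR enumerates every primer site on both strands with at most
`max_mismatch` (default 1) mismatches and none in the 3′-terminal five
bases — the anchor rule that makes real PCR specific — then reports every
convergent pair within `max_product` (default 5000) on the circle. An
empty result is meaningful: the classical survey pair fails exactly when
trnH sits in divergent orientation at the IRa/LSC boundary.

Junction depth QC uses medians, not means, for robustness to mapping
spikes. A junction is flagged `drop-suspect` when the median of the
100 bp window centred on it falls below `drop_threshold` (default 0.3)
times the median of two flanking windows (default 500 bp each); an
all-zero neighbourhood is reported as `zero-coverage` rather than passed
or failed.

## Small inversions

In an alignment, a hairpin inversion appears as a short block in which a
minority of taxa carry the reverse complement of the consensus. The
detector builds a strict-majority consensus over non-gap states (ties
broken alphabetically, for determinism), clusters each taxon's mismatch
columns (gap ≤ 6 columns — interior positions of a true inverted block can
match the consensus by palindromic chance, and such match runs must not
split a block), and evaluates candidate intervals obtained by trimming up
to two stray mismatches from the cluster ends and padding up to two
columns outward. Because any centre-symmetric sub-interval of an inverted
block also re-orients perfectly, neither the shortest nor the longest
acceptable interval is the right answer; candidates are ranked by an
alignment-style score (matches − mismatches of the re-oriented block
against the consensus), which both under- and over-shooting the true
boundary reduce. A reported block must gain at least `min_gain` (20)
identity points upon reverse complementation, reach `min_rc_identity`
(80%), and contain at least two mismatching columns (three for blocks of
five or more): a lone substitution is formally indistinguishable from a
perfect 3-bp inversion and is never called. Correction reverse-complements
the carrier's ungapped characters in place, leaving gap columns where they
are; the operation is an involution.

Genomic (between-genome) inversions are detected inside a gene-anchored
window: orientation is decided by global alignment of the query window
against the reference in both orientations, and the reversed segment is
localized by trimming the common prefix and suffix. The flanking
complementary repeat (the hairpin stem) is measured as the maximal k such
that the k bases left of the interval equal the reverse complement of the
k bases to its right.

## Supermatrix statistics

Columns with gaps in at least half of the rows are removed before
analysis ("less than half" is retained, exactly half is not). Site
classification excludes gaps, N and ambiguity codes from state counting:
constant means at most one distinct state, parsimony-informative means at
least two states each seen at least twice, singleton is the remainder of
the variable sites.

Parsimony lengths come from the Fitch state-set pass with unordered
equal-cost states; missing data (gap, N) is the full state set and
ambiguity codes are their IUPAC subsets. The per-site minimum is the
number of distinct observed single states minus one, CI is
Σmin/Σlength and HI = 1 − CI. Whether published homoplasy indices include
parsimony-uninformative sites is generally unstated, so both conventions
are available (`include_invariant`); the default excludes invariant sites.
Invariant data yields CI = 1 with an explicit `degenerate` flag instead of
an error. Multifurcating nodes are handled by sequential state-set
combination, which is exact for the trifurcating "root" of an unrooted
binary tree; genuinely polytomous trees are scored as one arbitrary binary
resolution.

Site concordance factors follow the published definition: for an internal
branch, quartets draw one leaf from each of the four surrounding subtrees;
a site is decisive for a quartet when the four leaves show exactly two
states, twice each, so it supports one of the three quartet topologies;
sCF is the mean over quartets of the fraction of decisive sites supporting
the tree's own topology, and sDF1/sDF2 are the two alternatives (so the
three always sum to 100 when decisive sites exist). A missing state at any
quartet leaf makes the site non-decisive for that quartet. All quartets
are enumerated when the universe is no larger than `n_quartets`; otherwise
sampling is without replacement (up to a universe of 10^6, with
replacement beyond) and reproducible from the seed. Putative
synapomorphies for a branch are counted strictly: columns where all
non-missing taxa on one side share one state, all non-missing taxa on the
other share a different state, and both sides have at least two
non-missing taxa. That is one defensible operational reading of
"putative synapomorphy", and reports label it as such.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. A stylized gene
layout places about thirty named genes at canonical positions — ycf2 just
inside J_LB, ndhB with its intron, trnV(GAC) and rrn16 in the repeat, the
intact ycf1 spanning J_SA with its reverse-complemented truncation ending
at J_SB, psbA and trnH at the classical LSC start, and the compact
trnD–trnY–trnE cluster mid-LSC — so every junction class and event of
interest is constructible. Default dimensions are a typical Apioideae
plastome: 92 kb LSC, 17.5 kb SSC, 18 kb IR, 37.4% GC; a `mini` template
with the same topology supports fast property tests on ~30 kb genomes.
Background sequence is i.i.d. with configurable GC — sufficient for
structural tests, with no attempt at realistic composition, codon
structure, or indel evolution.

Events are applied in order while maintaining exact IR symmetry:
`ev_jlb_expand(k)` duplicates the captured LSC tail at the far J_LA end;
`ev_jlb_contract(k)` releases the head of IRb into single copy and
truncates the mirrored genes at J_LA into pseudogene fragments (a cut
inside ycf2 reproduces the classical truncated-ycf2 junction type);
`ev_spacer_insertion()` inserts a payload into both repeat copies at the
mirrored positions, optionally embedding a psbA fragment, trnH, or a
5′-truncated trnV; `ev_genomic_inversion()` writes an exact complementary
flank pair around a gene-anchored segment and reverse-complements it
(`apply = FALSE` produces the matching reference genome of a pair under
the same seed). The generator also breaks chance complementarity across
the single-copy regions and at planted boundaries, so planted region
lengths and intervals are recovered *exactly* rather than up to chance
extensions — the property closure tests rely on this. A `census_target`
pads the LSC with additional real plastid gene names so the final census
matches a requested gene complement. Everything is a deterministic
function of the spec: identical specs give byte-identical GenBank output.

The alignment simulator evolves sites independently under a single-rate
symmetric model (Poisson substitutions per branch per site); an
`infinite_sites` mode gives each variable column exactly one mutation on
one branch, producing strictly homoplasy-free data for CI/HI calibration.
Planted small inversions are guaranteed detectable: block ends mismatch
the consensus after re-orientation, the columns just outside do not form a
chance stem pair, and blocks are not predominantly palindromic. These are
exactly the properties a real hairpin-flanked inversion has (the stem lies
outside the re-oriented loop), but they mean the detector's measured
operating characteristics apply to well-formed inversions, not to
arbitrarily ambiguous ones. Depth profiles are overdispersed
negative-binomial draws (uniform Poisson noise under-flags realistic
mapping dips), with 100–300 bp dips scaled by `drop_factor` at chosen
junctions.

## What passing tests do and do not show

The test suite validates every stage against independent oracles:
brute-force longest-inverted-repeat scans, exhaustive Fitch minimization
over internal labelings, naive primer-placement scans, direct recounts of
site classes and GC, an independent GenBank parser, and the generator's
own truth records. Problem sizes are chosen for sharp, fast checks:
full ~141–150 kb genomes for the reference-dimension recovery paths,
~30 kb `mini` genomes for bulk properties (100 random repeat specs,
screening across seeds), 40-taxon alignments of 6000 columns with 20
planted inversions per replicate at a realistic plastome divergence
(~0.1–0.15 expected substitutions per column across the tree) for the
detector's operating characteristics, and 100 replicate depth profiles for
the QC rates. Synthetic genomes do not model annotation error, composition
bias, repeat-mediated misassembly, or alignment uncertainty; passing tests
therefore demonstrate algorithmic correctness under the stated models, not
robustness to curation problems in real submissions — those must still be
inspected, which is exactly what the junction QC and screening reports are
for.

## Worked example

```{r example, eval = FALSE}
library(plastshift)

# a full-size synthetic plastome with a junction-shift insertion
spec <- plastome_spec(seed = 7,
                      events = list(ev_jla_shift_with_insertion(length = 1100)))
g <- generate_plastome(spec)

part <- detect_inverted_repeat(g$plastome)
tidy(part)
region_stats(g$plastome, part)
count_genes(g$plastome)

prof <- locate_junctions(g$plastome, part)
tidy(prof)
classify_junction(prof, "J_LB")

dep <- simulate_depth_profile(g$plastome, part, mean_depth = 60,
                              drop_sites = "J_LB", drop_factor = 0.05,
                              seed = 1)
junction_depth_qc(prof, dep)
autoplot(part)
```
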