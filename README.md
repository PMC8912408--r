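# plastshift

Comparative structural analysis of plastid genomes (plastomes) in R.

Angiosperm plastomes are circular quadripartite molecules: a large and a
small single-copy region (LSC, SSC) separated by two identical
inverted-repeat copies (IRa, IRb). Between close relatives, most
structural change is the "ebb and flow" of the four region junctions —
J_LB (LSC/IRb), J_SB (IRb/SSC), J_SA (SSC/IRa), J_LA (IRa/LSC). Junction
shifts duplicate genes into the repeat or release them, leave truncated
pseudogene copies (ψycf1, ψpsbA, ψycf2) at the boundaries, and can hide
kilobase-scale non-coding insertions in intergenic spacers such as
trnV(GAC)–rrn16. Alongside these, short hairpin-flanked inversions
(~3–62 bp) flip orientation between taxa and inflate homoplasy unless
re-oriented before phylogenetic analysis, and junction misassemblies show
up as localized drops in read coverage.

plastshift implements this workflow for people studying plastome
evolution (Apiaceae and beyond):

- **Quadripartite partition** — exact maximal inverted-repeat detection on
  the circle (`detect_inverted_repeat()`), canonical LSC→IRb→SSC→IRa
  rotation, region lengths and GC (`region_stats()`), gene census
  (`count_genes()`).
- **Junction analysis** — localization and classification relative to
  annotation (`locate_junctions()`, `classify_junction()`: `within:<gene>`,
  `within-intron:<gene>`, `between:<A>,<B>`, with captured payload genes),
  spacer-insertion screening with payload-fragment recovery
  (`screen_spacer_insertion()`), in-silico PCR with a 3′-anchor rule
  (`insilico_pcr()`), and coverage-drop QC at junctions
  (`junction_depth_qc()`).
- **Inversions** — detection and involutive correction of small inversions
  in alignments (`detect_small_inversions()`,
  `apply_inversion_correction()`), complementary-flank measurement
  (`find_flanking_ir()`), and anchored between-genome inversion calls
  (`detect_genomic_inversion()`).
- **Supermatrix statistics** — gap masking, concatenation with partition
  tables, site classification (variable / parsimony-informative /
  singleton), Fitch parsimony length with CI = Σmin/Σlength and
  HI = 1 − CI (`fitch_length()`), site concordance factors with
  sCF + sDF1 + sDF2 = 100 (`site_concordance()`), and strict per-branch
  putative-synapomorphy counts.
- **Synthetic data with ground truth** — a deterministic plastome
  generator (`plastome_spec()`, `generate_plastome()`) with junction-shift,
  insertion and inversion events, an alignment simulator with planted
  inversions and a homoplasy-free mode, and overdispersed depth profiles
  (`simulate_depth_profile()`), so every stage is testable offline.

Reports are tibbles; result objects have `tidy()`/`glance()` methods and
`autoplot()` figures. GenBank flat files, aligned FASTA, newick and TSV
depth tables are read and written (`read_genbank()`, `write_genbank()`,
`read_fasta_alignment()`, `read_depth_table()`). A thin command-line
wrapper ships at `inst/scripts/plastshift`
(`plastshift regions|junctions|screen|pcr|depthqc|inversions|flankir|matrix|scf|synth|report`).

## Worked example

```r
library(plastshift)

# a full-size synthetic plastome carrying a classic junction-shift
# insertion (psbA fragment + trnH payload) in the trnV(GAC)-rrn16 spacer
spec <- plastome_spec(seed = 7,
                      events = list(ev_jla_shift_with_insertion(length = 1100)))
g <- generate_plastome(spec)

part <- detect_inverted_repeat(g$plastome)
part
#> <quadripartite_partition> synthetic: LSC 92,000 | IRb 19,100 | SSC 17,500 | IRa 19,100 bp
tidy(part)
#> # A tibble: 4 x 5
#>   identifier region  start    end length
#>   <chr>      <chr>   <int>  <int>  <int>
#> 1 synthetic  LSC         1  92000  92000
#> 2 synthetic  IRb     92001 111100  19100
#> 3 synthetic  SSC    111101 128600  17500
#> 4 synthetic  IRa    128601 147700  19100
```

The repeat grew by 1100 bp over the 18 kb default: the inserted payload
sits in both IR copies. Junctions and coverage QC:

```r
prof <- locate_junctions(g$plastome, part)
classify_junction(prof, "J_LB")
#> # A tibble: 1 x 3
#>   junction class              payload_genes
#> 1 J_LB     between:rpl23,ycf2 <chr [2]>        # psbA fragment + trnH captured in the IR

dep <- simulate_depth_profile(g$plastome, part, mean_depth = 60,
                              drop_sites = "J_LB", drop_factor = 0.05, seed = 1)
junction_depth_qc(prof, dep)[, c("junction", "left_median", "inner_median",
                                 "right_median", "flag")]
#>   junction left_median inner_median right_median flag
#> 1 J_LB              56            3         55   drop-suspect
#> 2 J_SB              58           59         60.5 pass
#> 3 J_SA              59           59         60   pass
#> 4 J_LA              59           59         58.5 pass
```

The simulated assembly problem at J_LB (median 3× against ~56× flanks) is
flagged; clean junctions pass.

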