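# Published plastome characteristics of eleven Tordylieae representatives
# (region lengths in bp and gene censuses), used as generator parameters:
# the pipeline must recover every number by computation from the emitted
# genome.
reference_plastomes <- function() {
  tibble::tribble(
    ~taxon,                        ~size,   ~lsc,  ~ssc,  ~ir,   ~total, ~protein, ~pseudo, ~trna, ~rrna,
    "Dasispermum suffruticosum",   144902L, 91681L, 16931L, 18145L, 126L, 82L, 2L, 36L, 8L,
    "Ducrosia anethifolia",        141148L, 98931L, 17523L, 12347L, 122L, 79L, 2L, 35L, 8L,
    "Kalakia marginata",           142155L, 98758L, 17497L, 12950L, 122L, 79L, 2L, 35L, 8L,
    "Mandenovia komarovii",        149345L, 92332L, 17485L, 19764L, 127L, 82L, 2L, 37L, 8L,
    "Notobubon galbanum",          147466L, 93641L, 17443L, 18191L, 126L, 82L, 2L, 36L, 8L,
    "Pastinaca pimpinellifolia",   149758L, 92242L, 17654L, 19931L, 127L, 82L, 2L, 37L, 8L,
    "Symphyoloma graveolens",      149245L, 92159L, 17516L, 19785L, 127L, 82L, 2L, 37L, 8L,
    "Tordylium lanatum",           143402L, 94157L, 17521L, 15862L, 124L, 81L, 2L, 35L, 8L,
    "Tordylium maximum",           150103L, 91637L, 17676L, 20395L, 126L, 82L, 2L, 36L, 8L,
    "Tordylium pestalozzae",       141830L, 99355L, 17488L, 12493L, 122L, 79L, 1L, 35L, 8L,
    "Zosima korovinii",            141644L, 99620L, 17498L, 12263L, 122L, 79L, 2L, 35L, 8L
  )
}

# Build the generator spec realizing one reference row. The stylized layout
# starts with a long repeat (ycf2 wholly inside IRb); a boundary contraction
# then produces the observed repeat length: a cut inside ycf2 leaves the
# classical truncated ycf2 copy (second pseudogene besides pseudo-ycf1),
# while a cut in the ycf2-trnL spacer leaves pseudo-ycf1 alone.
reference_spec <- function(row, seed = 1L) {
  k <- if (row$pseudo >= 2L) 4000L else 7100L
  plastome_spec(
    seed = seed,
    lsc_length = row$lsc - k,
    ssc_length = row$ssc,
    ir_length = row$ir + k,
    template = "tordylieae",
    events = list(ev_jlb_contract(k)),
    census_target = list(protein = row$protein, trna = row$trna,
                         rrna = row$rrna),
    identifier = gsub(" ", "_", row$taxon))
}
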