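# L + R + S + revcomp(R) with boundary bases adjusted so the planted repeat
# is maximal exactly at the intended borders (otherwise chance
# complementarity across a single-copy region lengthens the true maximum)
make_circle <- function(lsc, ir, ssc, seed = 1) {
  withr::with_seed(seed, {
    L <- sample(c("A", "C", "G", "T"), lsc, TRUE)
    R <- paste(sample(c("A", "C", "G", "T"), ir, TRUE), collapse = "")
    S <- sample(c("A", "C", "G", "T"), ssc, TRUE)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (L[1] == comp[L[lsc]]) L[1] <- setdiff(c("A", "C", "G", "T"),
                                              comp[L[lsc]])[1]
    if (S[1] == comp[S[ssc]]) S[1] <- setdiff(c("A", "C", "G", "T"),
                                              comp[S[ssc]])[1]
    plastome("circle", paste0(paste(L, collapse = ""), R,
                              paste(S, collapse = ""), revcomp(R)))
  })
}

test_that("a constructed L + R + S + revcomp(R) circle is recovered exactly", {
  p <- make_circle(5000, 2000, 1200, seed = 3)
  part <- detect_inverted_repeat(p, min_ir_length = 1000)
  expect_identical(part$ir_length, 2000L)
  expect_identical(part$lsc_length, 5000L)
  expect_identical(part$ssc_length, 1200L)
  expect_identical(part$lsc_length + part$ssc_length + 2L * part$ir_length,
                   p$length)
})

test_that("generator boundaries make planted region lengths exact", {
  for (seed in c(1, 8, 21)) {
    g <- generate_plastome(mini_spec(seed = seed))
    part <- detect_inverted_repeat(g$plastome)
    expect_identical(part$lsc_length, g$truth$lsc_length)
    expect_identical(part$ssc_length, g$truth$ssc_length)
    expect_identical(part$ir_length, g$truth$ir_length)
  }
})

test_that("detected IR length equals the brute-force maximum", {
  for (seed in 1:2) {
    p <- make_circle(1600, 500, 400, seed = seed)
    part <- detect_inverted_repeat(p, min_ir_length = 300)
    expect_identical(part$ir_length,
                     as.integer(brute_longest_inverted_repeat(p$sequence)))
  }
})

test_that("random sequence without a planted repeat raises no-quadripartite", {
  p <- withr::with_seed(17, plastome("rand",
    paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")))
  expect_lt(brute_longest_inverted_repeat(p$sequence), 1000)
  expect_error(detect_inverted_repeat(p, min_ir_length = 1000),
               class = "ps_no_quadripartite_error")
})

test_that("a repeat pair covering the whole circle is degenerate", {
  R <- withr::with_seed(9, paste(sample(c("A", "C", "G", "T"), 2500, TRUE),
                                 collapse = ""))
  p <- plastome("deg", paste0(R, revcomp(R)))
  expect_error(detect_inverted_repeat(p, min_ir_length = 500),
               class = "ps_degenerate_structure_error")
})

test_that("detection is invariant to rotation and reverse complement", {
  g <- generate_plastome(mini_spec(seed = 12))
  p <- g$plastome
  ref <- detect_inverted_repeat(p)
  can_ref <- canonicalize_plastome(p, ref)
  for (off in c(137L, 14000L, 25000L)) {
    rot <- plastshift:::rotate_plastome(p, off)
    part <- detect_inverted_repeat(rot)
    expect_identical(part$lsc_length, ref$lsc_length)
    expect_identical(part$ssc_length, ref$ssc_length)
    expect_identical(part$ir_length, ref$ir_length)
    expect_identical(canonicalize_plastome(rot, part)$sequence,
                     can_ref$sequence)
  }
  flp <- plastshift:::flip_plastome(p)
  partf <- detect_inverted_repeat(flp)
  expect_identical(partf$lsc_length, ref$lsc_length)
  expect_identical(partf$ssc_length, ref$ssc_length)
  expect_identical(partf$ir_length, ref$ir_length)
  expect_identical(canonicalize_plastome(flp, partf)$sequence,
                   can_ref$sequence)
})

test_that("partition tiles the circle and tidy reports 1-based regions", {
  g <- generate_plastome(mini_spec(seed = 6))
  part <- detect_inverted_repeat(g$plastome)
  td <- tidy(part)
  expect_identical(sum(td$length), g$plastome$length)
  expect_identical(td$start[1], 1L)
  expect_identical(td$end[4], g$plastome$length)
  expect_identical(td$region, c("LSC", "IRb", "SSC", "IRa"))
  # IRa is the exact reverse complement of IRb on the canonical sequence
  can <- canonicalize_plastome(g$plastome, part)
  irb <- substr(can$sequence, td$start[2], td$end[2])
  ira <- substr(can$sequence, td$start[4], td$end[4])
  expect_identical(revcomp(irb), ira)
})

test_that("region GC matches an independent recount and boundary example", {
  gg <- paste(rep("GGCC", 1000), collapse = "")
  p <- make_circle(5000, 2000, 1200, seed = 4)
  part <- detect_inverted_repeat(p, 1000)
  rs <- region_stats(p, part)
  can <- canonicalize_plastome(p, part)
  td <- tidy(part)
  for (i in 1:4) {
    sub <- strsplit(substr(can$sequence, td$start[i], td$end[i]), "")[[1]]
    expect_equal(rs$gc[i], round(100 * mean(sub %in% c("G", "C")), 1))
  }
  expect_equal(rs$gc[rs$region == "overall"],
               round(100 * mean(strsplit(can$sequence, "")[[1]] %in%
                                  c("G", "C")), 1))
  # all-GC sequence reports 100.0
  pg <- plastome("gc", gg)
  expect_equal(plastshift:::gc_percent(pg$sequence), 100)
})

test_that("gene census counts features once and tracks pseudogenes", {
  p <- plastome("toy", paste(rep("ACGT", 100), collapse = ""),
                dplyr::bind_rows(
                  gene_feature("psbA", "protein", 0, 30),
                  gene_feature("ycf1", "protein", 40, 60, pseudo = TRUE),
                  gene_feature("trnH(GUG)", "trna", 70, 90),
                  gene_feature("rrn16", "rrna", 100, 150)))
  cg <- count_genes(p)
  expect_identical(cg$total_genes, 4L)
  expect_identical(cg$protein, 2L)
  expect_identical(cg$protein_pseudo, 1L)
  expect_identical(cg$trna, 1L)
  expect_identical(cg$rrna, 1L)
  # generator truth oracle, with census padding
  g <- generate_plastome(plastome_spec(seed = 2,
    census_target = list(protein = 82, trna = 37, rrna = 8)))
  cg2 <- count_genes(g$plastome)
  expect_identical(cg2$protein, 82L)
  expect_identical(cg2$trna, 37L)
  expect_identical(cg2$rrna, 8L)
  expect_identical(cg2$total_genes, 127L)
  expect_identical(cg2, g$truth$census)
  expect_error(count_genes(plastome("e", "ACGT")),
               class = "ps_validation_error")
})
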