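test_that("coordinate conversion between conventions is an involution", {
  starts <- c(1L, 10L, 900L)
  ends <- c(1L, 100L, 1000L)
  z <- to_zero_based(starts, ends)
  back <- to_one_based(z[, "start"], z[, "end"])
  expect_identical(back[, "start"], starts)
  expect_identical(back[, "end"], ends)
  expect_identical(to_zero_based(10, 100), cbind(start = 9L, end = 100L))
})

test_that("gene name normalization collapses tRNA notations", {
  expect_identical(normalize_gene_name(c("trnV(GAC)", "trnv-gac", "trnV_GAC")),
                   rep("trnV-GAC", 3))
  expect_identical(normalize_gene_name("psbA"), "psbA")
})

test_that("plastome construction validates sequence and features", {
  expect_error(plastome("x", ""), class = "ps_validation_error")
  expect_error(plastome("x", "ACGU"), class = "ps_validation_error")
  p <- plastome("x", "ACGTACGTAC",
                gene_feature("psbA", "protein", 2, 8, strand = "-"))
  expect_s3_class(p, "plastome")
  expect_identical(p$length, 10L)
  bad <- gene_feature("psbA", "protein", 2, 8)
  bad$kind <- "mystery"
  expect_error(plastome("x", "ACGTACGTAC", bad),
               class = "ps_classification_error")
})

test_that("GenBank reader converts coordinates and maps feature kinds", {
  f <- withr::local_tempfile(fileext = ".gb")
  seq1000 <- paste(rep("acgtacgtac", 100), collapse = "")
  writeLines(c(
    "LOCUS       TOY1                    1000 bp    DNA     circular PLN 01-JAN-2024",
    "ACCESSION   TOY1",
    "FEATURES             Location/Qualifiers",
    "     source          1..1000",
    "     CDS             10..100",
    "                     /gene=\"psbA\"",
    "ORIGIN",
    paste0("        1 ", seq1000),
    "//"), f)
  p <- read_genbank(f)
  expect_identical(p$length, 1000L)
  expect_identical(nrow(p$features), 1L)
  expect_identical(p$features$kind, "protein")
  expect_identical(p$features$intervals[[1]],
                   cbind(start = 9L, end = 100L))
})

test_that("GenBank reader flags origin-wrapping joins", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TOY2                    1000 bp    DNA     circular PLN 01-JAN-2024",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(900..1000,1..50)",
    "                     /gene=\"ycf1\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 100), collapse = "")),
    "//"), f)
  p <- read_genbank(f)
  expect_true(p$features$may_wrap_origin[1])
  expect_identical(nrow(p$features$intervals[[1]]), 2L)
  expect_identical(p$features$intervals[[1]][1, ], c(start = 899L, end = 1000L))
  expect_identical(p$features$intervals[[1]][2, ], c(start = 0L, end = 50L))
})

test_that("GenBank reader rejects malformed inputs with typed errors", {
  two <- withr::local_tempfile(fileext = ".gb")
  one <- c("LOCUS       A                         10 bp    DNA     circular PLN 01-JAN-2024",
           "ORIGIN", "        1 acgtacgtac", "//")
  writeLines(c(one, one), two)
  expect_error(read_genbank(two), class = "ps_ambiguity_error")
  empty <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       A                          0 bp    DNA     circular PLN 01-JAN-2024",
               "ORIGIN", "//"), empty)
  expect_error(read_genbank(empty), class = "ps_validation_error")
  junk <- withr::local_tempfile(fileext = ".gb")
  writeLines("this is not a flat file", junk)
  expect_error(read_genbank(junk), class = "ps_format_error")
  badloc <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       A                         10 bp    DNA     circular PLN 01-JAN-2024",
               "FEATURES             Location/Qualifiers",
               "     CDS             10..x2",
               "                     /gene=\"psbA\"",
               "ORIGIN", "        1 acgtacgtac", "//"), badloc)
  expect_error(read_genbank(badloc), class = "ps_format_error")
})

test_that("GenBank write/read round-trips synthetic plastomes exactly", {
  for (seed in c(2, 5)) {
    g <- generate_plastome(mini_spec(seed = seed,
      events = list(ev_jla_shift_with_insertion(length = 900))))
    f <- withr::local_tempfile(fileext = ".gb")
    write_genbank(g$plastome, f)
    p2 <- read_genbank(f)
    expect_identical(p2$sequence, g$plastome$sequence)
    expect_identical(p2$features$name, g$plastome$features$name)
    expect_identical(p2$features$kind, g$plastome$features$kind)
    expect_identical(p2$features$strand, g$plastome$features$strand)
    expect_identical(p2$features$pseudo, g$plastome$features$pseudo)
    expect_identical(p2$features$intervals, g$plastome$features$intervals)
  }
})

test_that("GenBank output agrees with an independent parser", {
  py <- Sys.which("python")
  skip_if(py == "", "python not available")
  g <- generate_plastome(mini_spec(seed = 3))
  f <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g$plastome, f)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from Bio import SeqIO",
    "rec = SeqIO.read(sys.argv[1], 'genbank')",
    "feats = [f for f in rec.features if f.type in ('CDS','tRNA','rRNA')]",
    "print(len(rec.seq), len(feats))",
    "for f in feats:",
    "    print(f.qualifiers['gene'][0], int(f.location.start), int(f.location.end), f.location.strand)"),
    script)
  out <- suppressWarnings(system2(py, c(script, f), stdout = TRUE))
  skip_if(length(out) == 0, "python parser produced no output")
  head_ <- as.integer(strsplit(out[1], " ")[[1]])
  expect_identical(head_[1], g$plastome$length)
  expect_identical(head_[2], nrow(g$plastome$features))
  parsed <- read.table(text = out[-1], col.names = c("gene", "start", "end", "strand"))
  fts <- g$plastome$features
  ours <- data.frame(
    name = fts$name,
    start = vapply(fts$intervals, function(iv) iv[1, 1], numeric(1)),
    end = vapply(fts$intervals, function(iv) iv[nrow(iv), 2], numeric(1)))
  ours <- ours[order(ours$start), ]
  theirs <- parsed[order(parsed$start), ]
  expect_identical(ours$name, as.character(theirs$gene))
  expect_identical(as.integer(ours$start), theirs$start)
  expect_identical(as.integer(ours$end), theirs$end)
})

test_that("FASTA alignment IO validates and round-trips", {
  rag <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), rag)
  expect_error(read_fasta_alignment(rag), class = "ps_ragged_alignment_error")
  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_fasta_alignment(dup), class = "ps_validation_error")
  two <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTAC"), two)
  aln <- read_fasta_alignment(two)
  expect_identical(dim(unclass(aln)), c(2L, 10L))
  sim <- simulate_alignment(ape::rtree(4), 20, seed = 11)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(sim$alignment, f)
  expect_identical(unclass(read_fasta_alignment(f)), unclass(sim$alignment))
})

test_that("depth tables fill missing positions and check bounds", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t5", "2\t5", "3\t5"), f)
  expect_identical(read_depth_table(f, 3)$depths, c(5L, 5L, 5L))
  writeLines(c("1\t5", "3\t5"), f)
  expect_identical(read_depth_table(f, 3)$depths, c(5L, 0L, 5L))
  writeLines(c("1\t5", "4\t5"), f)
  expect_error(read_depth_table(f, 3), class = "ps_bounds_error")
  # simulated profile round-trip
  g <- generate_plastome(mini_spec(seed = 4))
  part <- detect_inverted_repeat(g$plastome)
  d <- simulate_depth_profile(g$plastome, part, mean_depth = 40, seed = 2)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_depth_table(d, out)
  expect_identical(read_depth_table(out, g$plastome$length)$depths, d$depths)
})
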