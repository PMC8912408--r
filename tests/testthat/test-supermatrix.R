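test_that("gap-rich column masking removes exactly-half columns", {
  m <- matrix("A", 4, 3, dimnames = list(paste0("t", 1:4), NULL))
  m[1:2, 2] <- "-"      # gap fraction exactly 0.5 -> removed
  m[1, 3] <- "-"        # 0.25 -> kept
  res <- mask_gap_rich_columns(dna_alignment(m))
  expect_identical(res$mask, 2L)
  expect_identical(ncol(unclass(res$alignment)), 2L)
  # gap-free alignment is untouched
  res2 <- mask_gap_rich_columns(dna_alignment(matrix("C", 4, 5,
    dimnames = list(paste0("t", 1:4), NULL))))
  expect_identical(res2$mask, integer(0))
  # random gapped alignment equals a direct filter
  withr::with_seed(3, {
    m3 <- matrix(sample(c("A", "C", "G", "T", "-"), 40 * 8, TRUE,
                        prob = c(rep(0.2, 4), 0.2)), 8, 40,
                 dimnames = list(paste0("t", 1:8), NULL))
  })
  res3 <- mask_gap_rich_columns(dna_alignment(m3), 0.5)
  expect_identical(res3$mask, which(colMeans(m3 == "-") >= 0.5))
  allgap <- matrix("-", 4, 2, dimnames = list(paste0("t", 1:4), NULL))
  expect_error(mask_gap_rich_columns(dna_alignment(allgap)),
               class = "ps_empty_matrix_error")
})

test_that("concatenation appends blocks with a partition table", {
  a <- dna_alignment(setNames(rep("ACGTACGTAC", 4), paste0("t", 1:4)))
  b <- dna_alignment(setNames(rep("TTTTTTTTTT", 4), paste0("t", 1:4)))
  res <- concatenate_alignments(list(geneA = a, geneB = b))
  expect_identical(ncol(unclass(res$alignment)), 20L)
  expect_identical(res$partitions$start, c(1L, 11L))
  expect_identical(res$partitions$end, c(10L, 20L))
  # slicing by the partition table recovers each block
  sl <- unclass(res$alignment)[, res$partitions$start[2]:res$partitions$end[2]]
  expect_identical(sl, unclass(b)[paste0("t", 1:4), ])
  # missing taxon: strict errors, fill pads with gaps
  b2 <- dna_alignment(setNames(rep("TTTTTTTTTT", 3), paste0("t", 1:3)))
  expect_error(concatenate_alignments(list(a, b2), policy = "strict"),
               class = "ps_taxon_mismatch_error")
  filled <- concatenate_alignments(list(a, b2), policy = "fill")
  expect_identical(unname(unclass(filled$alignment)["t4", 11:20]),
                   rep("-", 10))
})

test_that("site classification follows the informative-site definition", {
  m <- rbind(A = strsplit("AAAA", "")[[1]], B = strsplit("AACA", "")[[1]],
             C = strsplit("ACCN", "")[[1]], D = strsplit("ATC-", "")[[1]])
  # col1 AAAA constant; col2 AACT-ish singleton; col3 ACCC informative?
  m2 <- matrix(c("A", "A", "A", "A",
                 "A", "A", "C", "T",
                 "A", "A", "C", "C",
                 "A", "N", "-", "A"), nrow = 4, byrow = FALSE,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  cs <- classify_sites(dna_alignment(m2))
  expect_identical(cs$constant, 2L)       # AAAA and A..A with missing
  expect_identical(cs$variable, 2L)
  expect_identical(cs$parsimony_informative, 1L)  # AACC
  expect_identical(cs$singleton, 1L)              # AACT
  expect_identical(cs$constant + cs$variable, cs$columns)
  # invariance to row and column shuffling + exhaustive recount
  withr::with_seed(9, {
    for (i in 1:5) {
      mm <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 12 * 60, TRUE,
                          prob = c(rep(0.22, 4), 0.08, 0.04)), 12, 60,
                   dimnames = list(paste0("t", 1:12), NULL))
      cs1 <- classify_sites(dna_alignment(mm))
      shuf <- mm[sample(12), sample(60)]
      rownames(shuf) <- rownames(mm)[1:12]
      cs2 <- classify_sites(dna_alignment(shuf))
      expect_identical(cs1$variable, cs2$variable)
      expect_identical(cs1$parsimony_informative, cs2$parsimony_informative)
      # direct recount
      counts <- apply(mm, 2, function(col) {
        tab <- table(col[col %in% c("A", "C", "G", "T")])
        c(var = length(tab) > 1, pi = length(tab) > 1 && sum(tab >= 2) >= 2)
      })
      expect_identical(cs1$variable, sum(counts["var", ]))
      expect_identical(cs1$parsimony_informative, sum(counts["pi", ]))
    }
  })
})

test_that("Fitch length matches the textbook case and brute force", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  aln <- dna_alignment(c(A = "A", B = "A", C = "T", D = "T"))
  fr <- fitch_length(tr, aln)
  expect_identical(fr$total_length, 1L)
  expect_identical(fr$per_site_length, 1L)
  expect_identical(fr$min_possible, 1L)
  # brute force over all internal labelings, with missing data
  withr::with_seed(21, {
    for (rep_i in 1:2) {
      tr6 <- ape::rtree(6)
      sim <- simulate_alignment(tr6, 40, seed = rep_i * 13)
      m <- unclass(sim$alignment)
      m[sample(length(m), 15)] <- sample(c("-", "N"), 15, TRUE)
      aln6 <- dna_alignment(m)
      mine <- fitch_length(tr6, aln6)
      expect_identical(mine$per_site_length, brute_fitch_lengths(tr6, m))
      # independent library cross-check
      pd <- phangorn::phyDat(m, type = "DNA")
      expect_identical(mine$total_length,
                       as.integer(phangorn::fitch(tr6, pd)))
      # re-rooting invariance
      tr6b <- ape::root(tr6, outgroup = tr6$tip.label[4],
                        resolve.root = TRUE)
      expect_identical(fitch_length(tr6b, aln6)$total_length,
                       mine$total_length)
    }
  })
  expect_error(fitch_length(tr, dna_alignment(c(A = "A", B = "A", X = "T",
                                                D = "T"))),
               class = "ps_taxon_error")
})

test_that("CI/HI conventions and the degenerate flag behave as documented", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  same <- dna_alignment(c(A = "ACGT", B = "ACGT", C = "ACGT", D = "ACGT"))
  fd <- fitch_length(tr, same)
  expect_identical(fd$ci, 1)
  expect_identical(fd$hi, 0)
  expect_true(fd$degenerate)
  # homoplasy-free simulation: HI exactly 0
  tr8 <- withr::with_seed(2, ape::rtree(8))
  sim <- simulate_alignment(tr8, 2000, mode = "infinite_sites", seed = 3)
  fr <- fitch_length(tr8, sim$alignment)
  expect_identical(fr$hi, 0)
  expect_false(fr$degenerate)
  # a site with two origins of the same state has length 2 > min 1
  aln <- dna_alignment(c(A = "G", B = "A", C = "G", D = "A"))
  f2 <- fitch_length(tr, aln)
  expect_identical(f2$per_site_length, 2L)
  expect_identical(f2$min_possible, 1L)
  expect_identical(f2$ci, 0.5)
  g2 <- glance(f2)
  expect_identical(g2$hi, 0.5)
  # both conventions computable
  fi <- fitch_length(tr, aln, include_invariant = TRUE)
  expect_identical(fi$ci, 0.5)
})

test_that("site concordance: trivial, exhaustive, reproducible, summing", {
  tr <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  # every informative site matches the AB|rest bipartition
  m <- matrix("A", 6, 30, dimnames = list(LETTERS[1:6], NULL))
  m[c("A", "B"), 1:10] <- "G"
  aln <- dna_alignment(m)
  b_ab <- pick_branch(tr, c("A", "B"))
  sc <- site_concordance(tr, aln, b_ab, n_quartets = 100, seed = 1)
  expect_equal(sc$scf, 100)
  expect_equal(sc$sdf1, 0)
  expect_equal(sc$sdf2, 0)
  # exhaustive enumeration is seed-independent
  tr8 <- withr::with_seed(31, ape::rtree(8, br = function(n) runif(n, 0.05, 0.2)))
  sim <- simulate_alignment(tr8, 1500, seed = 7)
  b <- internal_branches(tr8)$branch[2]
  s1 <- site_concordance(tr8, sim$alignment, b, n_quartets = 5000, seed = 1)
  s2 <- site_concordance(tr8, sim$alignment, b, n_quartets = 5000, seed = 77)
  expect_identical(s1$scf, s2$scf)
  # sampled run is seed-reproducible
  tr16 <- withr::with_seed(5, ape::rtree(16, br = function(n) runif(n, 0.05, 0.2)))
  sim16 <- simulate_alignment(tr16, 800, seed = 8)
  bb <- internal_branches(tr16)$branch[3]
  r1 <- site_concordance(tr16, sim16$alignment, bb, n_quartets = 50, seed = 4)
  r2 <- site_concordance(tr16, sim16$alignment, bb, n_quartets = 50, seed = 4)
  expect_identical(r1$scf, r2$scf)
  # sCF + sDF1 + sDF2 = 100 on every internal branch
  all_b <- site_concordance_all(tr8, sim$alignment, n_quartets = 100, seed = 2)
  expect_true(all(abs(all_b$scf + all_b$sdf1 + all_b$sdf2 - 100) < 0.1))
  expect_error(site_concordance(tr8, sim$alignment, 1e6), class = "ps_key_error")
})

test_that("a 50/50 conflicted branch shows depressed site concordance", {
  t1 <- ape::read.tree(text = "(((A,B),(C,D)),(E,(F,(G,H))));")
  # NNI alternative around the AB|CD-adjacent internal branch
  t2 <- ape::read.tree(text = "(((A,C),(B,D)),(E,(F,(G,H))));")
  t1$edge.length <- rep(0.08, nrow(t1$edge))
  t2$edge.length <- rep(0.08, nrow(t2$edge))
  s1 <- simulate_alignment(t1, 1500, seed = 21)
  s2 <- simulate_alignment(t2, 1500, seed = 22)
  mixed <- dna_alignment(cbind(unclass(s1$alignment),
                               unclass(s2$alignment)[rownames(unclass(s1$alignment)), ]))
  br <- internal_branches(t1)
  # the branch separating {A,B} x {C,D} neighbourhoods is conflicted
  scs <- site_concordance_all(t1, mixed, n_quartets = 200, seed = 3)
  expect_lt(min(scs$scf), 60)
  expect_gt(max(scs$scf), min(scs$scf))
  expect_true(all(abs(scs$scf + scs$sdf1 + scs$sdf2 - 100) < 0.1))
})

test_that("putative synapomorphies count strict bipartition-exact columns", {
  tr <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  m <- matrix("A", 6, 20, dimnames = list(LETTERS[1:6], NULL))
  br <- pick_branch(tr, c("A", "B"))      # AB | CDEF
  m[c("A", "B"), 1:3] <- "T"              # 3 exact columns
  m["A", 4] <- "T"                        # one deviant inside S -> not counted
  m[c("A", "B", "C"), 5] <- "T"           # deviant outside -> not counted
  m[c("A", "B"), 6] <- "T"; m["C", 6] <- "N"  # missing outside ok
  k <- count_branch_synapomorphies(tr, dna_alignment(m), br)
  expect_identical(k, 4L)
  pendant <- which(tr$edge[, 2] <= length(tr$tip.label))[1]
  expect_error(count_branch_synapomorphies(tr, dna_alignment(m), pendant),
               class = "ps_not_internal_error")
})
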