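# one generated genome per structural situation, reused across tests
jx_plain <- generate_plastome(mini_spec(seed = 3))
jx_ins <- generate_plastome(mini_spec(seed = 3,
  events = list(ev_jla_shift_with_insertion(length = 1100))))
jx_part <- detect_inverted_repeat(jx_ins$plastome, 500)
jx_can <- canonicalize_plastome(jx_ins$plastome, jx_part)

test_that("junction localization reports overlaps and distances", {
  part <- detect_inverted_repeat(jx_plain$plastome)
  prof <- locate_junctions(jx_plain$plastome, part)
  expect_identical(nrow(prof), 4L)
  expect_identical(prof$junction, c("J_LB", "J_SB", "J_SA", "J_LA"))
  jsa <- prof[prof$junction == "J_SA", ]
  expect_identical(jsa$overlap_feature, "ycf1")
  expect_identical(jsa$class, "within:ycf1")
  # intact ycf1 reaches 400 bp into IRa in the mini template
  expect_identical(jsa$right_distance, -400L)
  # the truncated ycf1 mirror ends exactly at J_SB: distance 0, no overlap
  jsb <- prof[prof$junction == "J_SB", ]
  expect_identical(jsb$left_distance, 0L)
  expect_true(is.na(jsb$overlap_feature))
  expect_error(locate_junctions(plastome("e", "ACGTACGT"), part),
               class = "ps_consistency_error")
})

test_that("junction classes follow boundary shifts into genes and introns", {
  g1 <- generate_plastome(mini_spec(seed = 11,
    events = list(ev_jlb_contract(600))))
  prof1 <- locate_junctions(g1$plastome,
                            detect_inverted_repeat(g1$plastome, 500))
  expect_identical(classify_junction(prof1, "J_LB")$class, "within:ycf2")
  # find a cut inside the ndhB intron from the realized layout
  ft <- jx_plain$plastome$features
  nb <- which(ft$name == "ndhB")[1]
  iv <- ft$intervals[[nb]]
  intron_mid <- as.integer((iv[1, 2] + iv[2, 1]) %/% 2)
  k <- intron_mid - jx_plain$truth$lsc_length
  g2 <- generate_plastome(mini_spec(seed = 3,
    events = list(ev_jlb_contract(k))))
  prof2 <- locate_junctions(g2$plastome,
                            detect_inverted_repeat(g2$plastome, 500))
  expect_identical(classify_junction(prof2, "J_LB")$class,
                   "within-intron:ndhB")
  expect_error(classify_junction(prof2, "J_XX"), class = "ps_key_error")
})

test_that("captured payload genes are mirror-consistent between J_LB and J_LA", {
  prof <- locate_junctions(jx_ins$plastome, jx_part)
  p_lb <- classify_junction(prof, "J_LB")$payload_genes[[1]]
  p_la <- classify_junction(prof, "J_LA")$payload_genes[[1]]
  expect_setequal(p_lb, c("psbA", "trnH-GUG"))
  expect_setequal(p_la, p_lb)
  # mirror offsets: each payload feature in IRb has a twin in IRa
  ff <- plastshift:::flat_features(jx_can)
  irb <- jx_part$irb; ira <- jx_part$ira
  n <- jx_can$length
  pay <- ff[plastshift:::gene_stem(ff$name) %in% c("psba", "trnh"), ]
  pay_irb <- pay[pay$start >= irb["start"] & pay$end <= irb["end"], ]
  for (i in seq_len(nrow(pay_irb))) {
    rel_s <- pay_irb$start[i] - irb["start"]; rel_e <- pay_irb$end[i] - irb["start"]
    twin_s <- ira["start"] + (jx_part$ir_length - rel_e)
    twin_e <- ira["start"] + (jx_part$ir_length - rel_s)
    twin <- pay[pay$start == twin_s & pay$end == twin_e, ]
    expect_identical(nrow(twin), 1L)
    expect_identical(twin$name, pay_irb$name[i])
    expect_false(twin$strand == pay_irb$strand[i])
  }
})

test_that("spacer screening recovers planted insertions and payload fragments", {
  pay <- c(psbA = extract_gene_sequence(jx_ins$plastome, "psbA"),
           trnH = extract_gene_sequence(jx_ins$plastome, "trnH"),
           trnV = extract_gene_sequence(jx_ins$plastome, "trnV-GAC"))
  part0 <- detect_inverted_repeat(jx_plain$plastome, 500)
  can0 <- canonicalize_plastome(jx_plain$plastome, part0)
  inst0 <- plastshift:::find_spacer_instances(can0, "trnV-GAC", "rrn16")
  base_seq <- plastshift:::plastome_subseq(can0, inst0$start[1],
                                           inst0$start[1] + inst0$len[1])
  rep <- screen_spacer_insertion(jx_ins$plastome, c("trnV-GAC", "rrn16"), pay,
                                 baseline = base_seq, partition = jx_part)
  expect_true(rep$insertion_present)
  expect_lte(abs(rep$insertion_length - jx_ins$truth$insertions$length), 10)
  frg <- rep$fragments[[1]]
  expect_setequal(plastshift:::gene_stem(frg$gene), c("psba", "trnh"))
  expect_true(all(frg$identity >= 70))
  # numeric-baseline route: length excess, no interval
  rep2 <- screen_spacer_insertion(jx_ins$plastome, c("trnV-GAC", "rrn16"),
                                  baseline = jx_ins$truth$insertions$baseline,
                                  partition = jx_part)
  expect_true(rep2$insertion_present)
  expect_identical(rep2$insertion_length,
                   rep2$observed_length - rep2$baseline_length)
  expect_true(is.na(rep2$insertion_start))
  # no event: absent, length 0
  rep0 <- screen_spacer_insertion(jx_plain$plastome, c("trnV-GAC", "rrn16"),
                                  baseline = base_seq, partition = part0)
  expect_false(rep0$insertion_present)
  expect_identical(rep0$insertion_length, 0L)
  expect_error(screen_spacer_insertion(jx_plain$plastome,
                                       c("trnV-GAC", "nadX"),
                                       baseline = 100, partition = part0),
               class = "ps_spacer_undefined_error")
})

test_that("planted insertion recovery holds across generator seeds", {
  for (seed in 1:12) {
    g0 <- generate_plastome(mini_spec(seed = seed))
    g1 <- generate_plastome(mini_spec(seed = seed,
      events = list(ev_jla_shift_with_insertion(length = 1100))))
    part0 <- detect_inverted_repeat(g0$plastome, 500)
    can0 <- canonicalize_plastome(g0$plastome, part0)
    inst0 <- plastshift:::find_spacer_instances(can0, "trnV-GAC", "rrn16")
    base_seq <- plastshift:::plastome_subseq(can0, inst0$start[1],
                                             inst0$start[1] + inst0$len[1])
    rep <- screen_spacer_insertion(g1$plastome, c("trnV-GAC", "rrn16"),
                                   baseline = base_seq)
    expect_true(rep$insertion_present)
    expect_lte(abs(rep$insertion_length - 1100), 10)
  }
})

test_that("in-silico PCR matches a naive site scan and honours the 3' anchor", {
  g <- generate_plastome(mini_spec(seed = 6, lsc = 9000, ssc = 3000, ir = 4500))
  p <- g$plastome
  fw <- substr(extract_gene_sequence(p, "rbcL"), 21, 40)
  s <- p$sequence
  for (primer in c(fw, revcomp(fw))) {
    mine <- plastshift:::primer_sites(strsplit(s, "")[[1]], nchar(s), primer,
                                      1L, "x")
    naive <- brute_primer_sites(s, primer, 1L)
    expect_identical(sort(mine$start), sort(naive$start))
  }
  # a 3'-anchor mismatch kills a site that a plain 1-mismatch scan allows
  site <- regexpr(fw, s, fixed = TRUE)[1]
  fw_anchor_mm <- fw
  substr(fw_anchor_mm, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                          substr(fw, 20, 20))[1]
  hits <- plastshift:::primer_sites(strsplit(s, "")[[1]], nchar(s),
                                    fw_anchor_mm, 1L, "x")
  expect_false((site - 1) %in% hits$start[hits$strand == "+"])
  expect_error(insilico_pcr(p, "ACGTNACGTACGTACGT", fw),
               class = "ps_primer_alphabet_error")
  expect_error(insilico_pcr(p, "ACGTACGT", fw),
               class = "ps_validation_error")
})

test_that("the survey primer pair amplifies only across the planted insertion", {
  fw <- substr(extract_gene_sequence(jx_can, "trnV-GAC"), 10, 28)
  rv <- substr(extract_gene_sequence(jx_can, "trnH"), 10, 28)
  amp <- insilico_pcr(jx_can, fw, rv, partition = jx_part)
  expect_gt(nrow(amp), 0)
  ins <- jx_ins$truth$insertions
  # at least one product spans the IRb payload copy
  expect_true(any(amp$product_length > 100 & amp$product_length < 3000))
  part0 <- detect_inverted_repeat(jx_plain$plastome, 500)
  can0 <- canonicalize_plastome(jx_plain$plastome, part0)
  amp0 <- insilico_pcr(can0, fw, rv, partition = part0)
  expect_identical(nrow(amp0), 0L)
})

test_that("junction depth QC flags dips and degenerate coverage", {
  prof <- locate_junctions(jx_can, jx_part)
  n <- jx_can$length
  uni <- depth_profile("u", rep(60L, n))
  qc <- junction_depth_qc(prof, uni)
  expect_true(all(qc$flag == "pass"))
  expect_true(all(qc$drop_ratio == 1))
  dip <- simulate_depth_profile(jx_can, jx_part, mean_depth = 60,
                                drop_sites = "J_LB", drop_factor = 0.05,
                                seed = 4)
  qc2 <- junction_depth_qc(prof, dip)
  expect_identical(qc2$flag[qc2$junction == "J_LB"], "drop-suspect")
  expect_true(all(qc2$flag[qc2$junction != "J_LB"] == "pass"))
  zero <- depth_profile("z", rep(0L, n))
  qc3 <- junction_depth_qc(prof, zero)
  expect_true(all(qc3$flag == "zero-coverage"))
  expect_true(all(is.na(qc3$drop_ratio)))
  expect_error(junction_depth_qc(prof, uni, window = 10000),
               class = "ps_window_too_large_error")
  expect_error(junction_depth_qc(prof, depth_profile("s", rep(1L, 10))),
               class = "ps_consistency_error")
})
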