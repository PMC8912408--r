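# Synthetic plastome / alignment / depth-profile generators with ground
# truth. The plastome generator lays out a stylized quadripartite genome
# (canonical rotation LSC, IRb, SSC, IRa) from a gene-layout template, then
# applies structural events (IR boundary shifts, spacer insertions, small and
# gene-cluster inversions) in order, maintaining exact IR symmetry and a
# truth record for every event.

# ---- gene layout templates ------------------------------------------------
# Each template lists ordered genes per region with lengths (bp), strand,
# gap weight (share of the region's spare space placed before the gene), and
# optional exon/intron part lengths. ycf1 is pinned: it spans J_SA with
# `ycf1_extent` bases inside IRa, and its reverse-complemented truncation
# (the classical pseudo-ycf1) fills the IRb tail at J_SB.

template_layout <- function(template = c("tordylieae", "mini")) {
  template <- match.arg(template)
  g <- function(name, kind, len, strand = "+", gap = 1, parts = NULL)
    tibble::tibble(name = name, kind = kind, len = len, strand = strand,
                   gap = gap, parts = list(parts))
  if (template == "tordylieae") {
    lsc <- dplyr::bind_rows(
      g("trnH-GUG", "trna", 75, "-", gap = 0.02),
      g("psbA", "protein", 1062, "-", gap = 0.05),
      g("matK", "protein", 1518, "+"),
      g("rps16", "protein", 813, "-"),
      g("trnQ-UUG", "trna", 72, "-"),
      g("atpA", "protein", 1524, "-"),
      g("rpoB", "protein", 3213, "-"),
      g("rpoC1", "protein", 2061, "-"),
      g("trnC-GCA", "trna", 71, "+"),
      g("psbM", "protein", 105, "-"),
      g("trnD-GUC", "trna", 74, "-"),
      g("trnY-GUA", "trna", 84, "-", gap = 0.01),
      g("trnE-UUC", "trna", 73, "-", gap = 0.01),
      g("psaA", "protein", 2253, "-"),
      g("psaB", "protein", 2205, "-"),
      g("rbcL", "protein", 1428, "+"),
      g("clpP", "protein", 591, "-"),
      g("psbB", "protein", 1527, "+"),
      g("rpoA", "protein", 1014, "-"),
      g("rpl16", "protein", 399, "-"),
      g("rps3", "protein", 657, "-"),
      g("rpl22", "protein", 500, "-"),
      g("rps19", "protein", 279, "-", gap = 0.2),
      g("rpl2", "protein", 1491, "-", gap = 0.2),
      g("rpl23", "protein", 282, "-", gap = 0.1)
    )
    irb <- dplyr::bind_rows(
      g("ycf2", "protein", 6834, "+", gap = 0.05),
      g("trnL-CAA", "trna", 81, "-"),
      g("ndhB", "protein", 2210, "-", parts = c(775, 679, 756)),
      g("rps7", "protein", 468, "-"),
      g("trnV-GAC", "trna", 72, "+"),
      g("rrn16", "rrna", 1491, "+"),
      g("trnI-GAU", "trna", 71, "+", gap = 0.3),
      g("trnA-UGC", "trna", 73, "+", gap = 0.3),
      g("rrn23", "rrna", 2810, "+", gap = 0.3),
      g("rrn4.5", "rrna", 103, "+", gap = 0.1),
      g("rrn5", "rrna", 121, "+", gap = 0.1),
      g("trnR-ACG", "trna", 74, "+", gap = 0.1),
      g("trnN-GUU", "trna", 72, "-", gap = 0.1)
    )
    ssc <- dplyr::bind_rows(
      g("ndhF", "protein", 2240, "-", gap = 0.2),
      g("rpl32", "protein", 161, "+"),
      g("ccsA", "protein", 960, "+"),
      g("ndhD", "protein", 1503, "-"),
      g("psaC", "protein", 246, "-"),
      g("ndhE", "protein", 306, "-"),
      g("ndhA", "protein", 1080, "-"),
      g("ndhH", "protein", 1182, "-"),
      g("rps15", "protein", 270, "-", gap = 0.3)
    )
    list(lsc = lsc, irb = irb, ssc = ssc,
         ycf1_len = 5600L, ycf1_extent = 1400L)
  } else {
    lsc <- dplyr::bind_rows(
      g("trnH-GUG", "trna", 70, "-", gap = 0.02),
      g("psbA", "protein", 300, "-", gap = 0.05),
      g("trnC-GCA", "trna", 71, "+"),
      g("psbM", "protein", 105, "-"),
      g("trnD-GUC", "trna", 74, "-"),
      g("trnY-GUA", "trna", 84, "-", gap = 0.01),
      g("trnE-UUC", "trna", 73, "-", gap = 0.01),
      g("rbcL", "protein", 400, "+"),
      g("rps19", "protein", 150, "-", gap = 0.2),
      g("rpl2", "protein", 300, "-", gap = 0.2),
      g("rpl23", "protein", 120, "-", gap = 0.1)
    )
    irb <- dplyr::bind_rows(
      g("ycf2", "protein", 800, "+", gap = 0.05),
      g("trnL-CAA", "trna", 71, "-"),
      g("ndhB", "protein", 650, "-", parts = c(250, 150, 250)),
      g("rps7", "protein", 200, "-"),
      g("trnV-GAC", "trna", 72, "+"),
      g("rrn16", "rrna", 600, "+"),
      g("rrn23", "rrna", 800, "+", gap = 0.3),
      g("rrn5", "rrna", 121, "+", gap = 0.1),
      g("trnN-GUU", "trna", 72, "-", gap = 0.1)
    )
    ssc <- dplyr::bind_rows(
      g("ndhF", "protein", 600, "-", gap = 0.2),
      g("ccsA", "protein", 300, "+"),
      g("ndhA", "protein", 350, "-"),
      g("rps15", "protein", 150, "-", gap = 0.3)
    )
    list(lsc = lsc, irb = irb, ssc = ssc,
         ycf1_len = 1200L, ycf1_extent = 400L)
  }
}

# real plastid gene names available as census padding
FILLER_PROTEINS <- c("atpB", "atpE", "atpF", "atpH", "atpI", "ndhC", "ndhJ",
                     "ndhK", "petA", "petB", "petD", "petG", "petL", "petN",
                     "psaI", "psaJ", "psbC", "psbD", "psbE", "psbF", "psbH",
                     "psbI", "psbJ", "psbK", "psbL", "psbN", "psbT", "psbZ",
                     "rpl14", "rpl20", "rpl33", "rpl36", "rps2", "rps4",
                     "rps8", "rps11", "rps12", "rps14", "rps18", "accD",
                     "cemA", "matK2", "ycf3", "ycf4", "infA", "clpP1")
FILLER_TRNAS <- c("trnF-GAA", "trnG-GCC", "trnG-UCC", "trnK-UUU", "trnL-UAA",
                  "trnL-UAG", "trnM-CAU", "trnfM-CAU", "trnP-UGG", "trnR-UCU",
                  "trnS-GCU", "trnS-GGA", "trnS-UGA", "trnT-GGU", "trnT-UGU",
                  "trnV-UAC", "trnW-CCA", "trnI-CAU", "trnQ-GUC", "trnA-GGC")

# ---- structural event constructors ----------------------------------------

#' Structural events for the synthetic plastome generator
#'
#' Constructors for the event list of [plastome_spec()]:
#' `ev_jlb_expand(k)` moves the LSC/IRb boundary `k` bases into the LSC
#' (capturing LSC genes into the repeat); `ev_jlb_contract(k)` releases the
#' first `k` bases of IRb into single copy (truncating the mirrored genes at
#' J_LA into pseudogene fragments); `ev_spacer_insertion()` inserts a payload
#' of the given length into the named spacer (both IR copies when the spacer
#' lies in the repeat), optionally embedding psbA-fragment / trnH /
#' trnV-pseudo payload genes; `ev_jla_shift_with_insertion()` is the classic
#' junction-shift signature (a psbA-fragment + trnH payload) in one call;
#' `ev_genomic_inversion()` reverse-complements a gene-anchored LSC segment
#' and writes exact complementary flanks of the given length around it.
#'
#' @param k Shift size in bases.
#' @param spacer Two flanking gene names.
#' @param length Insertion / inversion length in bases.
#' @param payload Character vector from
#'   `c("psbA-fragment", "trnH", "trnV-pseudo")` (or empty for a purely
#'   non-coding insertion).
#' @param flank Complementary flank length (<= 200).
#' @param anchors Anchor genes whose cluster the inversion must contain.
#' @return An event object for [plastome_spec()].
#' @name synthetic_events
NULL

#' @rdname synthetic_events
#' @export
ev_jlb_expand <- function(k) list(kind = "jlb_expand", k = as.integer(k))

#' @rdname synthetic_events
#' @export
ev_jlb_contract <- function(k) list(kind = "jlb_contract", k = as.integer(k))

#' @rdname synthetic_events
#' @export
ev_spacer_insertion <- function(spacer, length, payload = character()) {
  stopifnot(length(spacer) == 2L)
  bad <- setdiff(payload, c("psbA-fragment", "trnH", "trnV-pseudo", "none"))
  if (length(bad) > 0L)
    ps_abort(paste0("unknown payload parts: ", paste(bad, collapse = ", ")),
             "ps_validation_error")
  list(kind = "spacer_insertion", spacer = spacer, length = as.integer(length),
       payload = setdiff(payload, "none"))
}

#' @rdname synthetic_events
#' @export
ev_jla_shift_with_insertion <- function(spacer = c("trnV-GAC", "rrn16"),
                                        length = 1100L,
                                        payload = c("psbA-fragment", "trnH")) {
  ev <- ev_spacer_insertion(spacer, length, payload)
  ev$kind <- "jla_shift_with_insertion"
  ev
}

#' @rdname synthetic_events
#' @param apply Reverse-complement the segment (`TRUE`, the default). With
#'   `FALSE` the hairpin flanks are written but the segment is left in
#'   forward orientation, producing the matching reference genome of an
#'   inversion pair under the same seed.
#' @export
ev_genomic_inversion <- function(length = 489L, flank = 39L,
                                 anchors = c("trnD", "trnE"), apply = TRUE) {
  if (flank > 200L)
    ps_abort("flank length must be <= 200", "ps_validation_error")
  list(kind = "genomic_inversion", length = as.integer(length),
       flank = as.integer(flank), anchors = anchors, apply = isTRUE(apply))
}

#' Specify a synthetic plastome
#'
#' Defaults describe a typical Apioideae-style plastome: a 145-kb circle with
#' a 92-kb LSC, 17.5-kb SSC, 18-kb IR and 37.4% GC, carrying a stylized gene
#' complement in which ycf2 sits just inside J_LB, ndhB (with intron),
#' trnV(GAC) and rrn16 lie in the repeat, the intact ycf1 spans J_SA, its
#' truncated mirror ends at J_SB, and the trnD-trnY-trnE cluster sits
#' mid-LSC.
#'
#' @param seed Integer seed; the whole genome is a deterministic function of
#'   the spec.
#' @param lsc_length,ssc_length,ir_length Region lengths in bases (before
#'   events).
#' @param gc GC percent of the random background.
#' @param template `"tordylieae"` (full-size layout) or `"mini"`
#'   (scaled-down layout for small genomes).
#' @param events Ordered list of events (see [synthetic_events]).
#' @param census_target Optional named vector/list with any of `protein`,
#'   `trna`, `rrna`: the generator pads the LSC with additional real gene
#'   names so the final census matches.
#' @param identifier Genome id.
#' @return A `plastome_spec` list.
#' @export
plastome_spec <- function(seed = 1L, lsc_length = 92000L, ssc_length = 17500L,
                          ir_length = 18000L, gc = 37.4,
                          template = "tordylieae", events = list(),
                          census_target = NULL, identifier = "synthetic") {
  if (lsc_length <= ssc_length)
    ps_abort("lsc_length must exceed ssc_length", "ps_infeasible_spec_error")
  if (min(lsc_length, ssc_length, ir_length) <= 0L)
    ps_abort("region lengths must be positive", "ps_infeasible_spec_error")
  structure(list(seed = as.integer(seed), lsc_length = as.integer(lsc_length),
                 ssc_length = as.integer(ssc_length),
                 ir_length = as.integer(ir_length), gc = gc,
                 template = template, events = events,
                 census_target = census_target,
                 identifier = identifier),
            class = "plastome_spec")
}

random_dna <- function(n, gc) {
  if (n <= 0L) return(character(0))
  p_gc <- gc / 100
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2))
}

# place ordered template genes inside [0, room): returns flat part rows
place_genes <- function(tpl, room, region, id0) {
  total <- sum(tpl$len)
  spare <- room - total
  if (spare < 2L * nrow(tpl))
    ps_abort(sprintf("%s region too small for template (%d bp needed)",
                     region, total + 2L * nrow(tpl)),
             "ps_infeasible_spec_error")
  gaps <- floor(spare * tpl$gap / sum(tpl$gap))
  pos <- cumsum(gaps + dplyr::lag(tpl$len, default = 0L))
  rows <- list()
  for (i in seq_len(nrow(tpl))) {
    parts <- tpl$parts[[i]]
    id <- id0 + i
    if (is.null(parts)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = id, name = tpl$name[i], kind = tpl$kind[i], pseudo = FALSE,
        strand = tpl$strand[i], start = pos[i], end = pos[i] + tpl$len[i])
    } else {
      # exon / intron / exon ... alternating lengths
      offs <- cumsum(c(0L, parts))
      exon_idx <- seq(1L, length(parts), by = 2L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = id, name = tpl$name[i], kind = tpl$kind[i], pseudo = FALSE,
        strand = tpl$strand[i],
        start = pos[i] + offs[exon_idx], end = pos[i] + offs[exon_idx + 1L])
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a synthetic plastome with ground truth
#'
#' Deterministic for a given spec (same spec, same bytes). The truth record
#' carries the realized partition, census, per-event insertion and inversion
#' records, and baseline spacer lengths, and is what every pipeline stage is
#' tested against.
#'
#' @param spec A [plastome_spec()].
#' @return List with `plastome` (a [plastome()]) and `truth` (list:
#'   `lsc_length`, `ssc_length`, `ir_length`, `genome_length`, `census`,
#'   `insertions` tibble, `inversions` tibble, `spacer_baselines`).
#' @export
generate_plastome <- function(spec) {
  with_seed(spec$seed, {
    st <- build_initial_state(spec)
    st <- apply_census_padding(st, spec)
    for (ev in spec$events) st <- apply_event(st, ev, spec)
    finalize_genome(st, spec)
  })
}

build_initial_state <- function(spec, extra_lsc = NULL) {
  tpl <- template_layout(spec$template)
  llsc <- spec$lsc_length; lir <- spec$ir_length; lssc <- spec$ssc_length
  if (lir <= tpl$ycf1_extent + sum(tpl$irb$len) + 2L * nrow(tpl$irb))
    ps_abort("ir_length too small for template", "ps_infeasible_spec_error")
  lsc_tpl <- tpl$lsc
  if (!is.null(extra_lsc)) {
    # census padding genes interleaved mid-LSC (away from junction zones)
    at <- min(6L, nrow(lsc_tpl) - 3L)
    lsc_tpl <- dplyr::bind_rows(lsc_tpl[seq_len(at), ], extra_lsc,
                                lsc_tpl[(at + 1L):nrow(lsc_tpl), ])
  }
  f_lsc <- place_genes(lsc_tpl, llsc, "LSC", 0L)
  f_irb <- place_genes(tpl$irb, lir - tpl$ycf1_extent - 2L, "IR", 1000L)
  ycf1_ssc_part <- tpl$ycf1_len - tpl$ycf1_extent
  f_ssc <- place_genes(tpl$ssc, lssc - ycf1_ssc_part - 2L, "SSC", 2000L)
  # absolute coordinates
  irb_off <- llsc; ssc_off <- llsc + lir; ira_off <- llsc + lir + lssc
  n <- llsc + 2L * lir + lssc
  f_irb$start <- f_irb$start + irb_off; f_irb$end <- f_irb$end + irb_off
  f_ssc$start <- f_ssc$start + ssc_off; f_ssc$end <- f_ssc$end + ssc_off
  # intact ycf1 spanning J_SA; pseudo mirror filling the IRb tail at J_SB
  ycf1 <- tibble::tibble(id = 3001L, name = "ycf1", kind = "protein",
                         pseudo = FALSE, strand = "+",
                         start = ira_off - ycf1_ssc_part,
                         end = ira_off + tpl$ycf1_extent)
  ycf1_ps <- tibble::tibble(id = 3002L, name = "ycf1", kind = "protein",
                            pseudo = TRUE, strand = "-",
                            start = ssc_off - tpl$ycf1_extent, end = ssc_off)
  ft <- dplyr::bind_rows(f_lsc, f_irb, f_ssc, ycf1, ycf1_ps)
  ft <- dplyr::bind_rows(ft, mirror_ir_parts(f_irb, irb_off, lir, ira_off))
  sq <- c(random_dna(llsc, spec$gc), random_dna(lir, spec$gc),
          random_dna(lssc, spec$gc))
  irb_seq <- sq[(irb_off + 1L):(irb_off + lir)]
  sq <- c(sq, rev(c("A" = "T", "C" = "G", "G" = "C", "T" = "A")[irb_seq]))
  names(sq) <- NULL
  list(sq = sq, n = n, llsc = llsc, lir = lir, lssc = lssc, ft = ft,
       truth = list(insertions = list(), inversions = list(),
                    spacer_baselines = spacer_gaps(ft, f_irb)))
}

# IRa twins of IRb-resident feature parts (coordinates mirrored, strand
# flipped); ids offset so twins stay distinct features
mirror_ir_parts <- function(f_irb, irb_off, lir, ira_off) {
  if (nrow(f_irb) == 0L) return(NULL)
  rel_s <- f_irb$start - irb_off; rel_e <- f_irb$end - irb_off
  tibble::tibble(id = f_irb$id + 5000L, name = f_irb$name, kind = f_irb$kind,
                 pseudo = f_irb$pseudo,
                 strand = ifelse(f_irb$strand == "+", "-", "+"),
                 start = ira_off + (lir - rel_e), end = ira_off + (lir - rel_s))
}

spacer_gaps <- function(ft, f_irb) {
  ids <- unique(f_irb$id)
  ord <- f_irb[order(f_irb$start), ]
  firsts <- ord[!duplicated(ord$id), ]
  ends <- vapply(split(ord$end, ord$id)[as.character(firsts$id)], max, numeric(1))
  gaps <- firsts$start[-1L] - ends[-length(ends)]
  stats::setNames(as.integer(gaps),
                  paste(firsts$name[-nrow(firsts)], firsts$name[-1L], sep = "-"))
}

apply_census_padding <- function(st, spec) {
  if (is.null(spec$census_target)) return(st)
  tgt <- spec$census_target
  cur <- table(factor(st$ft$kind[!duplicated(st$ft$id)],
                      levels = c("protein", "trna", "rrna")))
  # padding must anticipate later events; run events on the unpadded state
  # first to learn the post-event census
  probe <- st
  for (ev in spec$events) probe <- apply_event(probe, ev, spec)
  post <- table(factor(probe$ft$kind[!duplicated(probe$ft$id)],
                       levels = c("protein", "trna", "rrna")))
  need_p <- if (!is.null(tgt$protein)) tgt$protein - post[["protein"]] else 0L
  need_t <- if (!is.null(tgt$trna)) tgt$trna - post[["trna"]] else 0L
  need_r <- if (!is.null(tgt$rrna)) tgt$rrna - post[["rrna"]] else 0L
  if (min(need_p, need_t, need_r) < 0L)
    ps_abort("census_target below the template's gene complement",
             "ps_infeasible_spec_error")
  if (need_p > length(FILLER_PROTEINS) || need_t > length(FILLER_TRNAS) ||
      need_r > 4L)
    ps_abort("census_target exceeds available filler gene names",
             "ps_infeasible_spec_error")
  extra <- dplyr::bind_rows(
    if (need_p > 0L) tibble::tibble(name = FILLER_PROTEINS[seq_len(need_p)],
                                    kind = "protein", len = 300L, strand = "+",
                                    gap = 1, parts = list(NULL)),
    if (need_t > 0L) tibble::tibble(name = FILLER_TRNAS[seq_len(need_t)],
                                    kind = "trna", len = 72L, strand = "+",
                                    gap = 1, parts = list(NULL)),
    if (need_r > 0L) tibble::tibble(name = paste0("rrn", seq_len(need_r)),
                                    kind = "rrna", len = 120L, strand = "+",
                                    gap = 1, parts = list(NULL)))
  if (is.null(extra) || nrow(extra) == 0L) return(st)
  # rebuild with padding (same seed-stream position: rebuild draws fresh
  # background, determinism preserved because the path is fixed by the spec)
  build_initial_state(spec, extra_lsc = extra)
}

apply_event <- function(st, ev, spec) {
  switch(ev$kind,
         jlb_expand = event_jlb_expand(st, ev),
         jlb_contract = event_jlb_contract(st, ev),
         spacer_insertion = event_spacer_insertion(st, ev, spec),
         jla_shift_with_insertion = event_spacer_insertion(st, ev, spec),
         genomic_inversion = event_genomic_inversion(st, ev, spec),
         ps_abort(paste0("unknown event kind: ", ev$kind),
                  "ps_validation_error"))
}

event_jlb_expand <- function(st, ev) {
  k <- ev$k
  if (k <= 0L || k >= st$llsc)
    ps_abort("jlb_expand size out of range", "ps_infeasible_spec_error")
  c0 <- st$llsc - k
  X <- st$sq[(c0 + 1L):st$llsc]
  n0 <- st$n
  st$sq <- c(st$sq, rev(c("A" = "T", "C" = "G", "G" = "C", "T" = "A")[X]))
  names(st$sq) <- NULL
  # mirrored copies of captured parts at the far (J_LA) end
  cap <- st$ft[st$ft$end > c0 & st$ft$start < st$llsc, ]
  if (nrow(cap) > 0L) {
    s2 <- pmax(cap$start, c0); e2 <- pmin(cap$end, st$llsc)
    partial <- !(cap$start >= c0 & cap$end <= st$llsc)
    # a part is a fragment when clipped, or when sibling parts escaped capture
    full_ids <- vapply(cap$id, function(i) {
      all(st$ft$start[st$ft$id == i] >= c0 & st$ft$end[st$ft$id == i] <= st$llsc)
    }, logical(1))
    mirr <- tibble::tibble(
      id = cap$id + 7000L, name = cap$name, kind = cap$kind,
      pseudo = cap$pseudo | partial | !full_ids,
      strand = ifelse(cap$strand == "+", "-", "+"),
      start = n0 + (st$llsc - e2), end = n0 + (st$llsc - s2))
    st$ft <- dplyr::bind_rows(st$ft, mirr)
  }
  st$n <- n0 + k
  st$llsc <- st$llsc - k
  st$lir <- st$lir + k
  st
}

event_jlb_contract <- function(st, ev) {
  k <- ev$k
  if (k <= 0L || k >= st$lir)
    ps_abort("jlb_contract size out of range", "ps_infeasible_spec_error")
  cut <- st$n - k                       # IRa tail [cut, n) is removed
  ft <- st$ft
  drop <- ft$start >= cut
  clip <- ft$start < cut & ft$end > cut
  ft$end[clip] <- cut
  ft$pseudo[clip] <- TRUE
  ft <- ft[!drop, ]
  # features that lost sibling parts become fragments too
  lost <- setdiff(st$ft$id[drop], ft$id)
  ft$pseudo[ft$id %in% st$ft$id[drop]] <- TRUE
  st$ft <- ft
  st$sq <- st$sq[seq_len(cut)]
  st$n <- cut
  st$llsc <- st$llsc + k
  st$lir <- st$lir - k
  st
}

event_spacer_insertion <- function(st, ev, spec) {
  comp <- c("A" = "T", "C" = "G", "G" = "C", "T" = "A")
  irb_lo <- st$llsc; irb_hi <- st$llsc + st$lir
  gap <- locate_truth_spacer(st, ev$spacer)
  in_ir <- gap$start >= irb_lo && gap$end <= irb_hi
  baseline <- gap$end - gap$start
  m <- gap$start + (gap$end - gap$start) %/% 2L
  payload <- build_payload(st, ev, spec)
  len <- length(payload$seq)
  if (in_ir) {
    m_rel <- m - irb_lo
    m2 <- (st$llsc + st$lir + st$lssc) + (st$lir - m_rel)  # IRa mirror point
    st <- insert_segment(st, m2, rev(unname(comp[payload$seq])),
                         mirror_payload_feats(payload$feats, len, m2))
    st <- insert_segment(st, m, payload$seq,
                         shift_payload_feats(payload$feats, m))
    st$lir <- st$lir + len
  } else {
    st <- insert_segment(st, m, payload$seq,
                         shift_payload_feats(payload$feats, m))
    if (gap$end <= st$llsc) st$llsc <- st$llsc + len
    else st$lssc <- st$lssc + len
  }
  st$truth$insertions[[length(st$truth$insertions) + 1L]] <- tibble::tibble(
    spacer = paste(normalize_gene_name(ev$spacer[1]),
                   normalize_gene_name(ev$spacer[2]), sep = "-"),
    baseline = as.integer(baseline), length = as.integer(len),
    start = as.integer(m), end = as.integer(m + len),
    payload = list(payload$genes), in_ir = in_ir)
  st
}

# the gap between the two named genes (nearest pairing, absolute coords);
# preferentially the IRb instance
locate_truth_spacer <- function(st, spacer) {
  ft <- st$ft
  ia <- which(gene_stem(ft$name) == gene_stem(spacer[1]))
  ib <- which(gene_stem(ft$name) == gene_stem(spacer[2]))
  if (length(ia) == 0L || length(ib) == 0L)
    ps_abort("spacer genes absent from synthetic layout", "ps_spacer_undefined_error")
  combos <- expand.grid(a = ia, b = ib)
  lo <- pmin(ft$end[combos$a], ft$end[combos$b])
  hi <- pmax(ft$start[combos$a], ft$start[combos$b])
  d <- hi - lo
  d[d < 0L] <- NA_integer_
  i <- which.min(d)
  list(start = lo[i], end = hi[i])
}

build_payload <- function(st, ev, spec) {
  parts <- list(); genes <- character(0); feats <- NULL; at <- 0L
  grab <- function(stem, take = NULL, from_end = FALSE) {
    idx <- which(gene_stem(st$ft$name) == stem & !st$ft$pseudo)
    if (length(idx) == 0L)
      ps_abort(paste0("payload source gene absent: ", stem),
               "ps_validation_error")
    i <- idx[which.min(st$ft$start[idx])]
    s <- st$sq[(st$ft$start[i] + 1L):st$ft$end[i]]
    if (!is.null(take)) {
      s <- if (from_end) s[(length(s) - take + 1L):length(s)] else s[seq_len(take)]
    }
    list(seq = s, name = st$ft$name[i], kind = st$ft$kind[i],
         strand = st$ft$strand[i])
  }
  for (pg in ev$payload) {
    piece <- switch(pg,
      "psbA-fragment" = { x <- grab("psba", take = 250L); x$pseudo <- TRUE; x },
      "trnH" = { x <- grab("trnh"); x$pseudo <- FALSE; x },
      "trnV-pseudo" = { x <- grab("trnv", take = 40L, from_end = TRUE)
                        x$pseudo <- TRUE; x })
    feats <- dplyr::bind_rows(feats, tibble::tibble(
      name = piece$name, kind = piece$kind, pseudo = piece$pseudo,
      strand = piece$strand, start = at, end = at + length(piece$seq)))
    genes <- c(genes, piece$name)
    parts[[length(parts) + 1L]] <- piece$seq
    at <- at + length(piece$seq) + 15L      # short random linker
    parts[[length(parts) + 1L]] <- random_dna(15L, spec$gc)
  }
  used <- sum(lengths(parts))
  if (used > ev$length)
    ps_abort("payload genes exceed requested insertion length",
             "ps_infeasible_spec_error")
  parts[[length(parts) + 1L]] <- random_dna(ev$length - used, spec$gc)
  list(seq = unlist(parts) %||% character(0), feats = feats, genes = genes)
}

shift_payload_feats <- function(feats, m) {
  if (is.null(feats) || nrow(feats) == 0L) return(NULL)
  feats$start <- feats$start + m; feats$end <- feats$end + m
  feats$id <- 9000L + seq_len(nrow(feats))
  feats
}

mirror_payload_feats <- function(feats, len, m2) {
  if (is.null(feats) || nrow(feats) == 0L) return(NULL)
  out <- tibble::tibble(
    id = 9500L + seq_len(nrow(feats)), name = feats$name, kind = feats$kind,
    pseudo = feats$pseudo, strand = ifelse(feats$strand == "+", "-", "+"),
    start = m2 + (len - feats$end), end = m2 + (len - feats$start))
  out
}

# insert `seg` (char vector) at boundary position m (0-based), shifting
# downstream features; `new_feats` are added as-is (already absolute)
insert_segment <- function(st, m, seg, new_feats = NULL) {
  len <- length(seg)
  st$sq <- append(st$sq, seg, after = m)
  ft <- st$ft
  ft$start[ft$start >= m] <- ft$start[ft$start >= m] + len
  ft$end[ft$end > m] <- ft$end[ft$end > m] + len
  if (!is.null(new_feats)) ft <- dplyr::bind_rows(ft, new_feats)
  st$ft <- ft
  st$n <- st$n + len
  st
}

event_genomic_inversion <- function(st, ev, spec) {
  comp <- c("A" = "T", "C" = "G", "G" = "C", "T" = "A")
  ft <- st$ft
  ia <- which(gene_stem(ft$name) == gene_stem(ev$anchors[1]))
  ib <- which(gene_stem(ft$name) == gene_stem(ev$anchors[2]))
  if (length(ia) == 0L || length(ib) == 0L)
    ps_abort("inversion anchor genes absent", "ps_infeasible_spec_error")
  lo <- min(ft$start[c(ia, ib)]); hi <- max(ft$end[c(ia, ib)])
  span <- hi - lo
  if (span > ev$length)
    ps_abort(sprintf("anchor cluster (%d bp) exceeds inversion length %d",
                     span, ev$length), "ps_infeasible_spec_error")
  pad <- ev$length - span
  s <- lo - pad %/% 2L
  e <- s + ev$length
  # the interval boundaries and flank zones must fall between features
  if (any(ft$start < s & ft$end > s - ev$flank) ||
      any(ft$start < e + ev$flank & ft$end > e))
    ps_abort("inversion boundary or flank would overlap a feature",
             "ps_infeasible_spec_error")
  # write complementary flanks
  flank_seq <- random_dna(ev$flank, spec$gc)
  st$sq[(s - ev$flank + 1L):s] <- flank_seq
  st$sq[(e + 1L):(e + ev$flank)] <- rev(unname(comp[flank_seq]))
  # ensure the flank does not extend further by chance
  outer_l <- s - ev$flank     # 0-based position of base just left of flank
  if (st$sq[outer_l] == comp[st$sq[e + ev$flank + 1L]])
    st$sq[outer_l] <- setdiff(c("A", "C", "G", "T"),
                              c(st$sq[outer_l],
                                comp[st$sq[e + ev$flank + 1L]]))[1L]
  seg <- st$sq[(s + 1L):e]
  # make the inversion boundary unambiguous: segment ends must differ under
  # reverse complement (the hairpin stem lies outside the segment)
  if (seg[1L] == comp[seg[length(seg)]]) {
    repl <- setdiff(c("A", "C", "G", "T"),
                    c(seg[1L], comp[seg[length(seg)]]))[1L]
    seg[1L] <- repl
  }
  st$sq[(s + 1L):e] <- seg     # boundary tweak in both orientations
  if (!ev$apply) return(st)
  st$sq[(s + 1L):e] <- rev(unname(comp[seg]))
  # flip wholly-contained features
  inside <- ft$start >= s & ft$end <= e
  ns <- s + e - ft$end[inside]
  ne <- s + e - ft$start[inside]
  ft$start[inside] <- ns; ft$end[inside] <- ne
  ft$strand[inside] <- ifelse(ft$strand[inside] == "+", "-", "+")
  st$ft <- ft
  st$truth$inversions[[length(st$truth$inversions) + 1L]] <- tibble::tibble(
    start = as.integer(s), end = as.integer(e),
    length = as.integer(e - s), flank = as.integer(ev$flank),
    affected = list(unique(ft$name[inside])))
  st
}

finalize_genome <- function(st, spec) {
  comp <- c("A" = "T", "C" = "G", "G" = "C", "T" = "A")
  # break chance complementarity across the single-copy regions so the
  # planted repeat is maximal exactly at the intended boundaries: the last
  # LSC base must not pair with the first LSC base (IR growth across J_LA /
  # J_LB), nor the first SSC base with the last SSC base (growth across
  # J_SB / J_SA)
  if (st$sq[st$llsc] == comp[st$sq[1L]])
    st$sq[1L] <- setdiff(c("A", "C", "G", "T"),
                         comp[st$sq[st$llsc]])[1L]
  ssc_first <- st$llsc + st$lir + 1L
  ssc_last <- st$llsc + st$lir + st$lssc
  if (st$sq[ssc_first] == comp[st$sq[ssc_last]])
    st$sq[ssc_first] <- setdiff(c("A", "C", "G", "T"),
                                comp[st$sq[ssc_last]])[1L]
  # IR symmetry is an internal invariant of every event; verify it
  irb <- st$sq[(st$llsc + 1L):(st$llsc + st$lir)]
  ira <- st$sq[(st$llsc + st$lir + st$lssc + 1L):st$n]
  stopifnot(identical(unname(rev(comp[irb])), unname(ira)))
  ft <- st$ft[order(st$ft$id, st$ft$start), ]
  feats <- purrr::map_dfr(split(seq_len(nrow(ft)), ft$id), function(ix) {
    rows <- ft[ix, ]
    gene_feature(rows$name[1L], rows$kind[1L],
                 start = rows$start, end = rows$end,
                 strand = rows$strand[1L],
                 pseudo = any(rows$pseudo))
  })
  ord <- order(vapply(feats$intervals, function(iv) iv[1L, 1L], numeric(1)))
  feats <- feats[ord, ]
  p <- plastome(spec$identifier, chars_seq(st$sq), feature_table(),
                source = "synthetic")
  p$features <- validate_features(feats, p$length)
  census <- count_genes(p)
  truth <- list(
    lsc_length = st$llsc, ssc_length = st$lssc, ir_length = st$lir,
    genome_length = st$n,
    census = census,
    insertions = dplyr::bind_rows(st$truth$insertions),
    inversions = dplyr::bind_rows(st$truth$inversions),
    spacer_baselines = st$truth$spacer_baselines,
    junctions = truth_junctions(st))
  list(plastome = p, truth = truth)
}

# expected junction classes from the generator's own layout
truth_junctions <- function(st) {
  jp <- c(J_LB = st$llsc, J_SB = st$llsc + st$lir,
          J_SA = st$llsc + st$lir + st$lssc, J_LA = 0L)
  ft <- st$ft
  vapply(jp, function(p) {
    if (p == 0L) p <- st$n  # J_LA boundary; no synthetic feature wraps it
    span_lo <- tapply(ft$start, ft$id, min)
    span_hi <- tapply(ft$end, ft$id, max)
    hit <- which(span_lo < p & p < span_hi)
    if (length(hit) > 0L) {
      id <- as.integer(names(span_lo)[hit[1L]])
      rows <- ft[ft$id == id, ]
      in_exon <- any(rows$start < p & p < rows$end)
      if (in_exon) paste0("within:", rows$name[1L])
      else paste0("within-intron:", rows$name[1L])
    } else {
      pl <- p; if (pl == st$n) pl <- 0L
      dl <- (pl - ft$end) %% st$n
      dr <- (ft$start - pl) %% st$n
      paste0("between:", ft$name[which.min(dl)], ",", ft$name[which.min(dr)])
    }
  }, character(1))
}

#' Extract a gene's sequence from a plastome
#'
#' Concatenates the feature's exon intervals and reverse complements minus
#' strand genes; the first (lowest-coordinate, non-pseudo if available) copy
#' is used.
#'
#' @param plastome A [plastome()].
#' @param gene Gene name (stem match, case-insensitive).
#' @return Character DNA string.
#' @export
extract_gene_sequence <- function(plastome, gene) {
  f <- plastome$features
  idx <- which(gene_stem(f$name) == gene_stem(gene))
  if (length(idx) == 0L)
    ps_abort(paste0("gene not found: ", gene), "ps_validation_error")
  if (any(!f$pseudo[idx])) idx <- idx[!f$pseudo[idx]]
  i <- idx[which.min(vapply(idx, function(j) f$intervals[[j]][1L, 1L], numeric(1)))]
  iv <- f$intervals[[i]]
  s <- paste(vapply(seq_len(nrow(iv)), function(j)
    plastome_subseq(plastome, iv[j, 1L], iv[j, 2L]), character(1)),
    collapse = "")
  if (f$strand[i] == "-") revcomp(s) else s
}

# ---- alignment simulation -------------------------------------------------

#' Simulate an alignment on a tree, optionally planting small inversions
#'
#' Sites evolve independently under a single-rate symmetric model: the root
#' sequence is uniform over A/C/G/T and each branch applies a Poisson number
#' of substitutions per site with mean equal to the branch length (each
#' substitution uniform over the three alternative bases). The
#' `infinite_sites` mode instead gives each of `n_variable` chosen columns
#' exactly one mutation on one branch (sampled proportionally to branch
#' length), producing strictly homoplasy-free data. Planted inversions
#' replace a carrier's block with its reverse complement; the generator
#' guarantees each planted block is detectable (ends mismatch under reverse
#' complement, bounded palindromicity), emulating hairpin-flanked inversions.
#'
#' @param tree `ape::phylo` with branch lengths (substitutions/site).
#' @param n_columns Number of alignment columns.
#' @param mode `"poisson"` or `"infinite_sites"`.
#' @param n_variable Number of variable columns for `infinite_sites` mode
#'   (default 10% of columns).
#' @param inversions Number of small inversions to plant (carriers drawn at
#'   random, one per inversion), or 0.
#' @param inversion_length_range Inversion lengths are drawn uniformly from
#'   this range (default 3-62 bases).
#' @param seed Integer seed.
#' @return List with `alignment` (a [dna_alignment()]) and `truth` (tibble of
#'   planted inversions: `start`, `end` 1-based inclusive, `carrier`).
#' @export
simulate_alignment <- function(tree, n_columns, mode = c("poisson", "infinite_sites"),
                               n_variable = NULL, inversions = 0L,
                               inversion_length_range = c(3L, 62L), seed = 1L) {
  mode <- match.arg(mode)
  if (n_columns < 1L) ps_abort("n_columns must be >= 1", "ps_validation_error")
  with_seed(seed, {
    m <- simulate_core(tree, n_columns, mode, n_variable)
    truth <- tibble::tibble(start = integer(), end = integer(),
                            carrier = character())
    if (inversions > 0L)
      res <- plant_inversions(m, inversions, inversion_length_range)
    else res <- list(m = m, truth = truth)
    list(alignment = dna_alignment(res$m), truth = res$truth)
  })
}

simulate_core <- function(tree, n_columns, mode, n_variable) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (is.null(tree$edge.length))
    ps_abort("tree must have branch lengths", "ps_validation_error")
  if (any(tree$edge.length < 0))
    ps_abort("branch lengths must be >= 0", "ps_validation_error")
  root <- ntip + 1L
  seqs <- matrix(NA_character_, nrow = ntip + nnode, ncol = n_columns)
  seqs[root, ] <- sample(c("A", "C", "G", "T"), n_columns, replace = TRUE)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  edge_order <- tr$edge
  el <- tr$edge.length
  if (mode == "poisson") {
    for (e in seq_len(nrow(edge_order))) {
      parent <- seqs[edge_order[e, 1L], ]
      k <- stats::rpois(n_columns, el[e])
      p_same <- 0.25 + 0.75 * (-1 / 3)^k
      stay <- stats::runif(n_columns) < p_same
      child <- parent
      hit <- which(!stay)
      if (length(hit) > 0L)
        child[hit] <- vapply(hit, function(j)
          sample(setdiff(c("A", "C", "G", "T"), parent[j]), 1L), character(1))
      seqs[edge_order[e, 2L], ] <- child
    }
  } else {
    for (e in seq_len(nrow(edge_order)))
      seqs[edge_order[e, 2L], ] <- seqs[edge_order[e, 1L], ]
    if (is.null(n_variable)) n_variable <- max(1L, round(n_columns * 0.1))
    n_variable <- min(n_variable, n_columns)
    cols <- sample.int(n_columns, n_variable)
    w <- tree$edge.length / sum(tree$edge.length)
    picked <- sample.int(nrow(tree$edge), n_variable, replace = TRUE, prob = w)
    adj <- tree_adjacency(tree)
    for (i in seq_along(cols)) {
      v <- tree$edge[picked[i], 2L]
      below <- c(v, reachable_leaves_all(adj, v, tree$edge[picked[i], 1L]))
      anc <- seqs[root, cols[i]]
      derived <- sample(setdiff(c("A", "C", "G", "T"), anc), 1L)
      seqs[below, cols[i]] <- derived
    }
  }
  out <- seqs[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# all nodes (internal + tips) reachable from `start` avoiding `blocked`
reachable_leaves_all <- function(adj, start, blocked) {
  seen <- logical(length(adj))
  seen[blocked] <- TRUE
  stack <- start
  nodes <- integer(0)
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    nodes <- c(nodes, v)
    stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
  }
  nodes
}

cons_at <- function(m, j) {
  tab <- sort(table(m[, j]), decreasing = TRUE)
  sort(names(tab)[tab == max(tab)])[1L]
}

plant_inversions <- function(m, n_inv, len_range) {
  ncol_ <- ncol(m)
  taxa <- rownames(m)
  placed <- tibble::tibble(start = integer(), end = integer(),
                           carrier = character())
  occupied <- logical(ncol_)
  comp <- c("A" = "T", "C" = "G", "G" = "C", "T" = "A")
  tries <- 0L
  while (nrow(placed) < n_inv && tries < n_inv * 400L) {
    tries <- tries + 1L
    len <- if (len_range[1] == len_range[2]) len_range[1]
           else sample(seq(len_range[1], len_range[2]), 1L)
    if (len + 4L > ncol_) next
    s <- sample.int(ncol_ - len - 5L, 1L) + 2L   # keep two columns margin
    cols <- s:(s + len - 1L)
    if (any(occupied[max(1L, s - 6L):min(ncol_, s + len + 5L)])) next
    carrier <- sample(taxa, 1L)
    block <- m[carrier, cols]
    inv <- rev(unname(comp[block]))
    cons <- apply(m[, cols, drop = FALSE], 2L, function(col) {
      tab <- sort(table(col), decreasing = TRUE)
      sort(names(tab)[tab == max(tab)])[1L]
    })
    # detectability: ends must mismatch the consensus after inversion, the
    # columns just outside must not form a chance complementary (stem-like)
    # pair that would blur the boundary, and the block must not be
    # predominantly palindromic
    if (inv[1L] == cons[1L] || inv[len] == cons[len]) next
    if (mean(inv == cons) > 0.5) next
    bad_outer <- FALSE
    for (d in 0:1) {
      out_l <- m[carrier, s - 1L - d]; out_r <- m[carrier, s + len + d]
      cons_l <- cons_at(m, s - 1L - d); cons_r <- cons_at(m, s + len + d)
      if (unname(comp[out_r]) == out_l || unname(comp[out_l]) == out_r ||
          unname(comp[out_r]) == cons_l || unname(comp[out_l]) == cons_r) {
        bad_outer <- TRUE; break
      }
    }
    if (bad_outer) next
    m[carrier, cols] <- inv
    occupied[cols] <- TRUE
    placed <- dplyr::bind_rows(placed, tibble::tibble(
      start = s, end = s + len - 1L, carrier = carrier))
  }
  if (nrow(placed) < n_inv)
    ps_abort("could not place all requested inversions", "ps_infeasible_spec_error")
  list(m = m, truth = placed[order(placed$start), ])
}

# ---- depth simulation -----------------------------------------------------

#' Simulate a per-base depth profile with optional junction dips
#'
#' Depths are overdispersed negative-binomial draws around `mean_depth`
#' (uniform Poisson noise under-flags real mapping dips). Each junction named
#' in `drop_sites` receives a 100-300 bp dip scaled by `drop_factor`.
#'
#' @param plastome A [plastome()].
#' @param partition Its [detect_inverted_repeat()] partition (junction
#'   positions are taken on the canonical rotation).
#' @param mean_depth Mean coverage (> 0).
#' @param drop_sites Character vector of junction ids to dip
#'   (subset of `J_LB`, `J_SB`, `J_SA`, `J_LA`).
#' @param drop_factor Multiplier in `[0, 1)` applied inside each dip.
#' @param dispersion Negative-binomial size parameter (default 20).
#' @param seed Integer seed.
#' @return A [depth_profile()] on the canonical rotation.
#' @export
simulate_depth_profile <- function(plastome, partition, mean_depth = 60,
                                   drop_sites = character(), drop_factor = 0.1,
                                   dispersion = 20, seed = 1L) {
  if (mean_depth <= 0) ps_abort("mean_depth must be > 0", "ps_validation_error")
  if (drop_factor < 0 || drop_factor >= 1)
    ps_abort("drop_factor must be in [0, 1)", "ps_validation_error")
  jp <- junction_positions(partition)
  bad <- setdiff(drop_sites, names(jp))
  if (length(bad) > 0L)
    ps_abort(paste0("unknown junction id(s): ", paste(bad, collapse = ", ")),
             "ps_key_error")
  n <- plastome$length
  with_seed(seed, {
    d <- stats::rnbinom(n, mu = mean_depth, size = dispersion)
    for (j in drop_sites) {
      w <- sample(100:300, 1L)
      p <- jp[[j]]
      idx <- circ1(seq(p - w %/% 2L + 1L, length.out = w), n)
      d[idx] <- round(d[idx] * drop_factor)
    }
    depth_profile(plastome$identifier, d)
  })
}
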