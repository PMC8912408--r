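# Small-inversion detection/correction in alignments and genomic inversion
# detection between annotated plastomes.

#' Detect small inversions in an alignment
#'
#' Small plastome inversions (typically 3-62 bp, hairpin-flanked) appear as
#' short blocks where a minority of taxa carry the reverse complement of the
#' consensus. The scan builds a strict-majority consensus over non-gap states
#' (ties broken alphabetically), clusters each taxon's mismatch columns into
#' maximal blocks, and reports a block when the reverse complement of the
#' carrier's ungapped block matches the consensus with an identity gain of at
#' least `min_gain` percentage points over the forward comparison. Calls from
#' different carriers on overlapping columns are merged.
#'
#' @param alignment A [dna_alignment()] with at least 4 rows.
#' @param min_len,max_len Inversion length bounds in columns (defaults 3, 100).
#' @param min_gain Required reverse-complement identity gain, percentage
#'   points (default 20).
#' @param max_cluster_gap Mismatch columns within this distance are clustered
#'   into one candidate block (default 6; interior positions of a true
#'   inverted block can match the consensus by palindromic chance, so small
#'   match runs must not split a block).
#' @param min_rc_identity Floor on the reverse-complement identity of a
#'   reported block, percent (default 80): a hairpin inversion restores
#'   near-perfect homology when re-oriented.
#' @return Object of class `small_inversion_set`: tibble with `start`, `end`
#'   (1-based inclusive alignment columns), `carriers` (list column),
#'   `identity_forward`, `identity_revcomp`.
#' @details A block needs at least two mismatching columns (three when the
#'   interval is 5 columns or longer): a lone substitution is
#'   indistinguishable from a perfect 3-bp inversion and is never called.
#'   Up to two stray mismatches (independent substitutions adjacent to a
#'   block) are trimmed from the cluster ends when that improves the
#'   reverse-complement fit.
#' @export
detect_small_inversions <- function(alignment, min_len = 3L, max_len = 100L,
                                    min_gain = 20, max_cluster_gap = 6L,
                                    min_rc_identity = 80) {
  m <- unclass(alignment)
  if (nrow(m) < 4L)
    ps_abort("small-inversion detection needs >= 4 taxa", "ps_insufficient_taxa_error")
  cons <- column_consensus(m)
  calls <- list()
  for (tx in rownames(m)) {
    row <- m[tx, ]
    mism <- which(row != cons & row %in% c("A", "C", "G", "T") &
                    cons %in% c("A", "C", "G", "T"))
    if (length(mism) < 2L) next
    # cluster mismatch positions
    brk <- which(diff(mism) > max_cluster_gap)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(mism))
    for (ci in seq_along(starts)) {
      if (ends[ci] - starts[ci] + 1L < 2L) next
      cluster <- mism[starts[ci]:ends[ci]]
      best <- best_inversion_interval(row, cons, cluster, min_len, max_len,
                                      min_gain, min_rc_identity)
      if (!is.null(best)) calls[[length(calls) + 1L]] <- c(best, taxon = tx)
    }
  }
  merged <- merge_inversion_calls(calls, nrow(m), m)
  structure(merged, class = c("small_inversion_set", class(tibble::tibble())))
}

column_consensus <- function(m) {
  apply(m, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) return("-")
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    sort(top)[1L]   # alphabetical tie-break
  })
}

# identity of the (ungapped) carrier block vs consensus, forward and revcomp
block_identities <- function(row, cons, i0, i1) {
  idx <- i0:i1
  keep <- row[idx] != "-"
  if (!any(keep)) return(c(fwd = NA_real_, rc = NA_real_))
  rb <- row[idx][keep]
  cb <- cons[idx][keep]
  rc <- revcomp_chars(rb)
  c(fwd = 100 * mean(rb == cb), rc = 100 * mean(rc == cb))
}

# Candidate intervals for one mismatch cluster: trim up to `trim` stray
# mismatches from either end, then pad up to `pad` columns outward. Any
# centre-symmetric sub-interval of a true inverted block also re-orients
# perfectly, so neither shortest nor longest selection is right: candidates
# are ranked by an alignment-style score of the re-oriented block against
# the consensus (match +1, mismatch -1), which shrinking below or growing
# beyond the true boundary both reduce (ties: fewer trims, then leftmost).
best_inversion_interval <- function(row, cons, cluster, min_len, max_len,
                                    min_gain, min_rc_identity,
                                    trim = 2L, pad = 2L) {
  ncol_ <- length(row)
  nm <- length(cluster)
  best <- NULL
  for (a in 0L:min(trim, nm - 2L)) for (b in 0L:min(trim, nm - 2L - a)) {
    i0 <- cluster[1L + a]; i1 <- cluster[nm - b]
    nm_kept <- nm - a - b
    for (e1 in 0L:pad) for (e2 in 0L:pad) {
      s <- max(1L, i0 - e1); e <- min(ncol_, i1 + e2)
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      if (len >= 5L && nm_kept < 3L) next
      id <- block_identities(row, cons, s, e)
      if (any(is.na(id))) next
      if (id["rc"] < min_rc_identity) next
      gain <- id["rc"] - id["fwd"]
      if (gain < min_gain) next
      score <- len * (2 * id[["rc"]] / 100 - 1)
      cand <- list(start = s, end = e, fwd = unname(id["fwd"]),
                   rc = unname(id["rc"]), gain = unname(gain),
                   score = score, trims = a + b)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score &&
             (cand$rc > best$rc ||
                (cand$rc == best$rc &&
                   (cand$trims < best$trims ||
                      (cand$trims == best$trims && cand$start < best$start))))))
        best <- cand
    }
  }
  if (!is.null(best)) { best$trims <- NULL; best$score <- NULL }
  best
}

merge_inversion_calls <- function(calls, n_taxa, m) {
  empty <- tibble::tibble(start = integer(), end = integer(),
                          carriers = list(), identity_forward = numeric(),
                          identity_revcomp = numeric())
  if (length(calls) == 0L) return(empty)
  df <- purrr::map_dfr(calls, function(cl)
    tibble::tibble(start = as.integer(cl$start), end = as.integer(cl$end),
                   taxon = cl$taxon, fwd = as.numeric(cl$fwd),
                   rc = as.numeric(cl$rc)))
  df <- df[order(df$start, df$end), ]
  groups <- list(); cur <- df[1L, , drop = FALSE]
  cur_start <- df$start[1L]; cur_end <- df$end[1L]
  for (i in seq_len(nrow(df))[-1L]) {
    if (df$start[i] <= cur_end) {
      cur <- rbind(cur, df[i, ]); cur_end <- max(cur_end, df$end[i])
      cur_start <- min(cur_start, df$start[i])
    } else {
      groups[[length(groups) + 1L]] <- list(s = cur_start, e = cur_end, d = cur)
      cur <- df[i, , drop = FALSE]; cur_start <- df$start[i]; cur_end <- df$end[i]
    }
  }
  groups[[length(groups) + 1L]] <- list(s = cur_start, e = cur_end, d = cur)
  out <- purrr::map_dfr(groups, function(g) {
    carriers <- sort(unique(g$d$taxon))
    # carrier taxa must be a strict minority of non-gap rows over the block
    nongap <- sum(apply(m[, g$s:g$e, drop = FALSE] != "-", 1L, any))
    if (length(carriers) * 2L >= nongap) return(NULL)
    tibble::tibble(start = g$s, end = g$e, carriers = list(carriers),
                   identity_forward = round(mean(g$d$fwd), 1),
                   identity_revcomp = round(mean(g$d$rc), 1))
  })
  if (is.null(out) || nrow(out) == 0L) empty else out
}

#' Reverse-complement inversion blocks to restore positional homology
#'
#' For each inversion and carrier taxon, the carrier's ungapped characters in
#' the interval are reverse complemented in place, leaving gap columns where
#' they are; all other rows are untouched. The operation is an involution.
#'
#' @param alignment A [dna_alignment()].
#' @param inversions A [detect_small_inversions()] result (intervals must be
#'   disjoint).
#' @return The corrected [dna_alignment()].
#' @export
apply_inversion_correction <- function(alignment, inversions) {
  m <- unclass(alignment)
  if (nrow(inversions) == 0L) return(alignment)
  iv <- inversions[order(inversions$start), ]
  if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)]))
    ps_abort("overlapping inversion intervals", "ps_overlap_error")
  for (i in seq_len(nrow(iv))) {
    cols <- iv$start[i]:iv$end[i]
    for (tx in iv$carriers[[i]]) {
      sub <- m[tx, cols]
      keep <- sub != "-"
      if (any(keep)) m[tx, cols[keep]] <- revcomp_chars(sub[keep])
    }
  }
  dna_alignment(m)
}

#' Maximal complementary flank length around a genome interval
#'
#' Returns the maximal `k <= max_flank` such that the `k` bases immediately
#' left of the interval equal the reverse complement of the `k` bases
#' immediately right (the hairpin stem flanking small inversions). Flanks are
#' read on the circle.
#'
#' @param genome A [plastome()].
#' @param start,end Interval as 0-based half-open genome coordinates.
#' @param max_flank Maximum flank length scanned (default 200).
#' @return Integer flank length (0 when the immediate flanks do not pair).
#' @export
find_flanking_ir <- function(genome, start, end, max_flank = 200L) {
  n <- genome$length
  if (end <= start || end - start > n)
    ps_abort("invalid interval", "ps_bounds_error")
  s <- seq_chars(genome$sequence)
  comp <- comp_chars(s)
  k <- 0L
  while (k < max_flank) {
    left <- s[circ1(start - k, n)]         # base at start-1-k (0-based)
    right <- comp[circ1(end + 1L + k, n)]  # comp of base at end+k
    if (left != right || left == "N") break
    k <- k + 1L
  }
  k
}

#' Detect a genomic inversion between two plastomes in an anchored window
#'
#' Extracts the window between two anchor genes in both genomes, decides the
#' orientation by global alignment of the query window against the reference
#' window in forward and reverse-complement orientation, and, when the
#' reverse orientation scores best, localizes the maximal reversed segment by
#' trimming the common prefix/suffix of the two windows. Affected features
#' are genes inside the interval whose strand differs between the genomes.
#'
#' @param query,reference [plastome()] objects sharing the anchor genes.
#' @param anchors Character vector of the two anchor gene names bounding the
#'   window (e.g. `c("trnC", "psbM")`).
#' @return A one-row tibble (`start`, `end` 1-based inclusive on the query;
#'   `length`; `flank_ir_length`; `affected_features` list column), or a
#'   zero-row tibble when the window aligns best in forward orientation.
#' @export
detect_genomic_inversion <- function(query, reference, anchors) {
  stopifnot(length(anchors) == 2L)
  wq <- anchored_window(query, anchors)
  wr <- anchored_window(reference, anchors)
  none <- tibble::tibble(start = integer(), end = integer(), length = integer(),
                         flank_ir_length = integer(), affected_features = list())
  if (wq$seq == wr$seq) return(none)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  score_fwd <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(wq$seq), Biostrings::DNAString(wr$seq),
    type = "global", substitutionMatrix = submat, gapOpening = 4,
    gapExtension = 0.5, scoreOnly = TRUE)
  score_rev <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(revcomp(wq$seq)), Biostrings::DNAString(wr$seq),
    type = "global", substitutionMatrix = submat, gapOpening = 4,
    gapExtension = 0.5, scoreOnly = TRUE)
  # the middle (prefix/suffix-trimmed) segment decides; whole-window score
  # can favour forward when the inversion is short relative to the window
  qc <- seq_chars(wq$seq); rc <- seq_chars(wr$seq)
  nq <- length(qc); nr <- length(rc)
  pre <- 0L
  while (pre < min(nq, nr) && qc[pre + 1L] == rc[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < min(nq, nr) - pre && qc[nq - suf] == rc[nr - suf]) suf <- suf + 1L
  mid_q <- if (pre + suf < nq) chars_seq(qc[(pre + 1L):(nq - suf)]) else ""
  mid_r <- if (pre + suf < nr) chars_seq(rc[(pre + 1L):(nr - suf)]) else ""
  if (nchar(mid_q) == 0L || nchar(mid_r) == 0L) return(none)
  mid_fwd <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(mid_q), Biostrings::DNAString(mid_r),
    type = "global", substitutionMatrix = submat, gapOpening = 4,
    gapExtension = 0.5, scoreOnly = TRUE)
  mid_rev <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(revcomp(mid_q)), Biostrings::DNAString(mid_r),
    type = "global", substitutionMatrix = submat, gapOpening = 4,
    gapExtension = 0.5, scoreOnly = TRUE)
  if (mid_rev <= mid_fwd && score_rev <= score_fwd) return(none)
  g_start <- wq$start + pre                 # 0-based genome coords (query)
  g_end <- wq$start + nq - suf
  flank <- find_flanking_ir(query, g_start, g_end)
  affected <- strand_flipped_features(query, reference, g_start, g_end)
  tibble::tibble(start = as.integer(g_start + 1L), end = as.integer(g_end),
                 length = as.integer(g_end - g_start),
                 flank_ir_length = as.integer(flank),
                 affected_features = list(affected))
}

anchored_window <- function(p, anchors) {
  ff <- flat_features(p)
  if (is.null(ff))
    ps_abort("anchored window requires annotation", "ps_anchor_error")
  ia <- which(gene_stem(ff$name) == gene_stem(anchors[1]))
  ib <- which(gene_stem(ff$name) == gene_stem(anchors[2]))
  if (length(ia) == 0L || length(ib) == 0L)
    ps_abort(paste0("anchor gene(s) absent: ",
                    paste(anchors[c(length(ia) == 0L, length(ib) == 0L)],
                          collapse = ", ")), "ps_anchor_error")
  # nearest pairing: window between end of the first anchor and start of the
  # second, in genome order
  combos <- expand.grid(a = ia, b = ib)
  n <- p$length
  d <- (ff$start[combos$b] - ff$end[combos$a]) %% n
  i <- which.min(d)
  a <- combos$a[i]; b <- combos$b[i]
  start <- ff$end[a] %% n
  len <- d[i]
  list(start = start, end = start + len,
       seq = plastome_subseq(p, start, start + len))
}

strand_flipped_features <- function(query, reference, g_start, g_end) {
  ffq <- flat_features(query)
  ffr <- flat_features(reference)
  if (is.null(ffq) || is.null(ffr)) return(character(0))
  inside <- ffq[ffq$start >= g_start & ffq$end <= g_end, ]
  flipped <- vapply(seq_len(nrow(inside)), function(i) {
    j <- which(gene_stem(ffr$name) == gene_stem(inside$name[i]))
    length(j) > 0L && all(ffr$strand[j] != inside$strand[i])
  }, logical(1))
  unique(inside$name[flipped])
}
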