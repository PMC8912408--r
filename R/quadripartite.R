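# Inverted-repeat detection on the circular plastome and Table-1-style
# statistics (region lengths, GC, gene census).

#' Detect the inverted-repeat pair and partition the plastome
#'
#' Finds the maximal-length pair of disjoint, exactly reverse-complementary
#' substrings of length >= `min_ir_length` on the circle (seed k-mers shared
#' between the sequence and its reverse complement, grouped by anti-diagonal,
#' then exact base-wise extension; maximality means one-base extension on
#' either side of either copy breaks exact reverse-complementarity). The two
#' single-copy gaps become LSC (longer) and SSC (shorter). The result is
#' expressed on the canonical rotation: LSC starts at 0 and region order is
#' LSC, IRb, SSC, IRa; orientation (possible reverse complement) is chosen so
#' that an intact ycf1 annotation sits adjacent to IRa, falling back to the
#' lexicographically smaller LSC sequence; equal-length repeat candidates are
#' broken by smallest start coordinate.
#'
#' @param plastome A [plastome()].
#' @param min_ir_length Minimum acceptable repeat length in bases (default
#'   1000, well above the longest inverted repeat expected by chance in a
#'   random sequence of plastome size).
#' @return Object of class `quadripartite_partition` with 0-based half-open
#'   region intervals on the canonical rotation, region lengths,
#'   `canonical_offset` (rotation applied to the input after any flip) and
#'   `flipped` (whether the reverse complement orientation was chosen).
#' @export
detect_inverted_repeat <- function(plastome, min_ir_length = 1000L) {
  n <- plastome$length
  min_ir_length <- as.integer(min_ir_length)
  if (n < 4L * min_ir_length)
    ps_abort(sprintf("genome of %d bp is shorter than 4 x min_ir_length", n),
             "ps_validation_error")
  hit <- find_max_inverted_repeat(plastome$sequence, min_ir_length)
  if (is.null(hit))
    ps_abort(sprintf("no inverted repeat of length >= %d found (IR-lacking genome?)",
                     min_ir_length), "ps_no_quadripartite_error")
  L <- hit$length
  p0 <- hit$start1; q0 <- hit$start2   # 0-based starts of the two copies
  gap_pq <- (q0 - (p0 + L)) %% n       # bases between copy1 end and copy2 start
  gap_qp <- (p0 - (q0 + L)) %% n
  if (gap_pq == 0L && gap_qp == 0L)
    ps_abort("inverted repeat pair covers the whole circle", "ps_degenerate_structure_error")
  build_partition(plastome, p0, q0, L, gap_pq, gap_qp)
}

# Exact maximal inverted-repeat pair search. Returns NULL or
# list(start1, start2, length) with 0-based starts, start1 <= start2.
find_max_inverted_repeat <- function(sequence, min_len) {
  s <- seq_chars(sequence)
  n <- length(s)
  k <- min(16L, min_len)
  code <- match(s, c("A", "C", "G", "T", "N")) - 1L
  rcode <- rev(c(3L, 2L, 1L, 0L, 4L)[code + 1L])
  hs <- kmer_hashes(code, k)    # circular k-mer hashes of S
  hr <- kmer_hashes(rcode, k)   # ... of revcomp(S)
  ia <- which(hs %in% hr)
  if (length(ia) == 0L) return(NULL)
  jr <- which(hr %in% hs)
  # low-complexity guard: drop hash values occurring too often on either side
  ca <- table(hs[ia]); cr <- table(hr[jr])
  ok_val <- intersect(names(ca)[ca <= 16L], names(cr)[cr <= 16L])
  ia <- ia[as.character(hs[ia]) %in% ok_val]
  jr <- jr[as.character(hr[jr]) %in% ok_val]
  if (length(ia) == 0L || length(jr) == 0L) return(NULL)
  pairs <- merge(data.frame(h = hs[ia], a = ia),
                 data.frame(h = hr[jr], j = jr))
  if (nrow(pairs) == 0L) return(NULL)
  pa <- pairs$a
  pb <- ((n + 1L - pairs$j - k) %% n) + 1L     # R-kmer -> S position
  diag_id <- (pa + pb) %% n
  comp <- comp_chars(s)
  best <- NULL
  for (d in unique(diag_id)) {
    idx <- which(diag_id == d)
    idx <- idx[order(pa[idx])]
    # several separate repeats can share an anti-diagonal; greedily extend
    # from unconsumed seeds
    consumed <- NULL
    if (length(idx) > 1L) consumed <- logical(n)
    for (t in idx) {
      if (!is.null(consumed) && consumed[pa[t]]) next
      ext <- extend_ir_seed(s, comp, n, pa[t], pb[t], k)
      if (is.null(ext)) next
      if (!is.null(consumed)) {
        consumed[circ1(seq(ext$a0 + 1L, length.out = ext$L), n)] <- TRUE
        consumed[circ1(seq(ext$b0 + 1L, length.out = ext$L), n)] <- TRUE
      }
      if (ext$L >= min_len) {
        cand <- normalize_ir_pair(ext$a0, ext$b0, ext$L, n)
        if (is.null(best) || cand$length > best$length ||
            (cand$length == best$length && cand$start1 < best$start1))
          best <- cand
      }
    }
  }
  best
}

# polynomial base-5 circular k-mer hashes (exact in doubles for k <= 16)
kmer_hashes <- function(code, k) {
  n <- length(code)
  d <- c(code, code[seq_len(k - 1L)])
  h <- numeric(n)
  for (t in 0L:(k - 1L)) h <- h * 5 + d[seq_len(n) + t]
  h
}

# extend an exact seed match S[a..a+k) == revcomp(S[b..b+k)) maximally.
# 1-based circular starts; returns 0-based starts. Extension is chunked so
# spurious seeds cost O(chunk), true repeats O(length).
extend_ir_seed <- function(s, comp, n, a, b, k, chunk = 512L) {
  sa <- s[circ1(seq(a, length.out = k), n)]
  sb <- comp[circ1(seq(b + k - 1L, by = -1L, length.out = k), n)]
  if (!all(sa == sb) || any(sa == "N")) return(NULL)
  grow <- function(emax, xpos, ypos) {
    e <- 0L
    while (e < emax) {
      m <- min(chunk, emax - e)
      xs <- s[circ1(xpos(e + 0L:(m - 1L)), n)]
      ys <- comp[circ1(ypos(e + 0L:(m - 1L)), n)]
      ok <- xs == ys & xs != "N"
      if (all(ok)) e <- e + m
      else return(e + which.min(ok) - 1L)
    }
    e
  }
  g1 <- (b - (a + k)) %% n   # gap between A-end and B-start
  g2 <- (a - (b + k)) %% n
  e1 <- grow(g1 %/% 2L, function(e) a + k + e, function(e) b - 1L - e)
  e2 <- grow(g2 %/% 2L, function(e) a - 1L - e, function(e) b + k + e)
  L <- k + e1 + e2
  list(a0 = (a - e2 - 1L) %% n, b0 = (b - e1 - 1L) %% n, L = L)
}

normalize_ir_pair <- function(a0, b0, L, n) {
  if (a0 <= b0) list(start1 = a0, start2 = b0, length = L)
  else list(start1 = b0, start2 = a0, length = L)
}

build_partition <- function(plastome, p0, q0, L, gap_pq, gap_qp) {
  n <- plastome$length
  # the gap following copy1 (p) is [p0+L, q0); the other is [q0+L, p0)
  if (gap_pq >= gap_qp) {
    lsc_start <- (p0 + L) %% n; lsc_len <- gap_pq
    ssc_start <- (q0 + L) %% n; ssc_len <- gap_qp
    ir_after_lsc <- q0
  } else {
    lsc_start <- (q0 + L) %% n; lsc_len <- gap_qp
    ssc_start <- (p0 + L) %% n; ssc_len <- gap_pq
    ir_after_lsc <- p0
  }
  # two candidate orientations: forward (rotate LSC to 0) or flipped
  fwd <- list(offset = lsc_start, flipped = FALSE)
  # after reverse complement, position x maps to n - 1 - x; LSC start becomes
  # n - (lsc_start + lsc_len)
  rev_off <- (n - (lsc_start + lsc_len)) %% n
  rev <- list(offset = rev_off, flipped = TRUE)
  choice <- choose_orientation(plastome, fwd, rev, lsc_len, ssc_len, L)
  can <- if (choice$flipped) flip_plastome(plastome) else plastome
  can <- rotate_plastome(can, choice$offset)
  structure(
    list(
      lsc = c(start = 0L, end = lsc_len),
      irb = c(start = lsc_len, end = lsc_len + L),
      ssc = c(start = lsc_len + L, end = lsc_len + L + ssc_len),
      ira = c(start = lsc_len + L + ssc_len, end = n),
      lsc_length = as.integer(lsc_len), ssc_length = as.integer(ssc_len),
      ir_length = as.integer(L), genome_length = n,
      canonical_offset = as.integer(choice$offset),
      flipped = choice$flipped,
      identifier = plastome$identifier
    ),
    class = "quadripartite_partition"
  )
}

choose_orientation <- function(plastome, fwd, rev, lsc_len, ssc_len, L) {
  n <- plastome$length
  score <- function(o) {
    can <- if (o$flipped) flip_plastome(plastome) else plastome
    can <- rotate_plastome(can, o$offset)
    f <- can$features
    intact <- which(gene_stem(f$name) == "ycf1" & !f$pseudo)
    if (length(intact) == 0L) return(NA_real_)
    j_sa <- lsc_len + L + ssc_len     # SSC/IRa junction position
    d <- min(vapply(intact, function(i) {
      iv <- f$intervals[[i]]
      mids <- (iv[, 1L] + interval_lengths(iv, n) / 2)
      min(abs(mids - j_sa))
    }, numeric(1)))
    d
  }
  sf <- score(fwd)
  if (!is.na(sf)) {
    sr <- score(rev)
    if (sf <= sr) return(fwd) else return(rev)
  }
  # no intact ycf1 annotation: lexicographically smaller LSC sequence
  lsc_of <- function(o) {
    can <- if (o$flipped) flip_plastome(plastome) else plastome
    can <- rotate_plastome(can, o$offset)
    substr(can$sequence, 1L, lsc_len)
  }
  if (lsc_of(fwd) <= lsc_of(rev)) fwd else rev
}

#' Canonicalize a plastome to its partition's rotation
#'
#' Applies the flip and rotation recorded in the partition so that sequence
#' position 0 is the LSC start and region order is LSC, IRb, SSC, IRa.
#'
#' @param plastome The [plastome()] the partition was derived from.
#' @param partition A [detect_inverted_repeat()] result for the same genome.
#' @return The canonicalized `plastome`.
#' @export
canonicalize_plastome <- function(plastome, partition) {
  check_partition_match(plastome, partition)
  p <- if (partition$flipped) flip_plastome(plastome) else plastome
  rotate_plastome(p, partition$canonical_offset)
}

check_partition_match <- function(plastome, partition) {
  if (plastome$length != partition$genome_length)
    ps_abort("partition does not match plastome length", "ps_consistency_error")
  invisible(TRUE)
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  cat(sprintf(
    "<quadripartite_partition> %s: LSC %s | IRb %s | SSC %s | IRa %s bp%s\n",
    x$identifier, format(x$lsc_length, big.mark = ","),
    format(x$ir_length, big.mark = ","), format(x$ssc_length, big.mark = ","),
    format(x$ir_length, big.mark = ","),
    if (x$flipped) " (reverse-complemented)" else ""))
  invisible(x)
}

#' Tidy a quadripartite partition
#'
#' @param x A `quadripartite_partition`.
#' @param ... Unused.
#' @return Tibble with one row per region (1-based inclusive coordinates on
#'   the canonical rotation).
#' @method tidy quadripartite_partition
#' @export
tidy.quadripartite_partition <- function(x, ...) {
  regions <- c("LSC", "IRb", "SSC", "IRa")
  iv <- rbind(x$lsc, x$irb, x$ssc, x$ira)
  tibble::tibble(
    identifier = x$identifier, region = regions,
    start = as.integer(iv[, 1L] + 1L), end = as.integer(iv[, 2L]),
    length = as.integer(iv[, 2L] - iv[, 1L])
  )
}

#' @method glance quadripartite_partition
#' @export
glance.quadripartite_partition <- function(x, ...) {
  tibble::tibble(identifier = x$identifier, size = x$genome_length,
                 lsc_length = x$lsc_length, ssc_length = x$ssc_length,
                 ir_length = x$ir_length,
                 canonical_offset = x$canonical_offset, flipped = x$flipped)
}

# ---- region statistics ----------------------------------------------------

gc_percent <- function(s) {
  ch <- seq_chars(s)
  acgt <- sum(ch %in% c("A", "C", "G", "T"))
  if (acgt == 0L) return(NA_real_)
  100 * sum(ch %in% c("G", "C")) / acgt
}

#' Region lengths and GC content
#'
#' GC is computed as (G+C)/(A+C+G+T) per region and overall (N excluded from
#' the denominator), reported to 0.1%.
#'
#' @param plastome A [plastome()].
#' @param partition Its [detect_inverted_repeat()] partition.
#' @return Tibble with one row per region plus an `overall` row: `region`,
#'   `length`, `gc` (percent, 1 decimal).
#' @export
region_stats <- function(plastome, partition) {
  check_partition_match(plastome, partition)
  can <- canonicalize_plastome(plastome, partition)
  iv <- rbind(partition$lsc, partition$irb, partition$ssc, partition$ira)
  regions <- c("LSC", "IRb", "SSC", "IRa")
  gc <- vapply(seq_len(4L), function(i)
    gc_percent(substr(can$sequence, iv[i, 1L] + 1L, iv[i, 2L])), numeric(1))
  tibble::tibble(
    identifier = plastome$identifier,
    region = c(regions, "overall"),
    length = c(as.integer(iv[, 2L] - iv[, 1L]), plastome$length),
    gc = round(c(gc, gc_percent(can$sequence)), 1)
  )
}

#' Gene census
#'
#' Counts each gene feature instance once (genes duplicated in the IR are two
#' features and count twice); pseudogenes count within their kind and are
#' additionally tallied in `protein_pseudo` when protein-coding.
#'
#' @param plastome A [plastome()] with a non-empty feature table.
#' @return One-row tibble: `total_genes`, `protein`, `protein_pseudo`,
#'   `trna`, `rrna`.
#' @export
count_genes <- function(plastome) {
  f <- plastome$features
  if (nrow(f) == 0L)
    ps_abort("plastome has no features to census", "ps_validation_error")
  tibble::tibble(
    identifier = plastome$identifier,
    total_genes = nrow(f),
    protein = sum(f$kind == "protein"),
    protein_pseudo = sum(f$kind == "protein" & f$pseudo),
    trna = sum(f$kind == "trna"),
    rrna = sum(f$kind == "rrna")
  )
}
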