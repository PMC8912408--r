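# IR junction localization/classification, spacer insertion screening,
# in-silico PCR, and junction depth QC.
#
# Junction convention: a junction's position is the first base of the
# downstream region, 0-based on the canonical rotation, so
# J_LB = LSC/IRb boundary, J_SB = IRb/SSC, J_SA = SSC/IRa, J_LA = IRa/LSC
# (position 0). Overlap extents are reported as negative distances.

junction_positions <- function(partition) {
  c(J_LB = unname(partition$irb["start"]),
    J_SB = unname(partition$ssc["start"]),
    J_SA = unname(partition$ira["start"]),
    J_LA = 0L)
}

# flatten canonical features to per-part rows with linear [start,end) on the
# canonical rotation (wrap parts split)
flat_features <- function(can) {
  n <- can$length
  f <- can$features
  if (nrow(f) == 0L) return(NULL)
  out <- purrr::map_dfr(seq_len(nrow(f)), function(i) {
    iv <- f$intervals[[i]]
    rows <- purrr::map_dfr(seq_len(nrow(iv)), function(j) {
      s <- iv[j, 1L]; e <- iv[j, 2L]
      if (s < e) tibble::tibble(start = s, end = e)
      else tibble::tibble(start = c(s, 0L), end = c(n, e))  # wrap split
    })
    rows$feature <- i
    rows$part <- seq_len(nrow(rows))
    rows
  })
  out$name <- f$name[out$feature]
  out$kind <- f$kind[out$feature]
  out$pseudo <- f$pseudo[out$feature]
  out$strand <- f$strand[out$feature]
  out
}

#' Localize the four IR junctions relative to annotation
#'
#' For each junction the nearest feature edge on each side is reported with a
#' signed circular distance (negative = the feature crosses the junction by
#' that many bases), together with any feature whose span contains the
#' junction position.
#'
#' @param plastome A [plastome()] with non-empty annotation.
#' @param partition Its [detect_inverted_repeat()] partition.
#' @return Object of class `junction_profile`: a tibble with one row per
#'   junction (`junction`, `position` 0-based canonical, `left_feature`,
#'   `left_distance`, `right_feature`, `right_distance`,
#'   `overlap_feature`, `overlap_extent`, `class`, `payload_genes`).
#' @export
locate_junctions <- function(plastome, partition) {
  check_partition_match(plastome, partition)
  if (nrow(plastome$features) == 0L)
    ps_abort("junction localization requires annotation", "ps_annotation_required_error")
  can <- canonicalize_plastome(plastome, partition)
  ff <- flat_features(can)
  n <- can$length
  jp <- junction_positions(partition)
  rows <- purrr::map_dfr(names(jp), function(jn) {
    p <- jp[[jn]]
    feats <- can$features
    # whole-feature span crossing (handles introns: between intervals)
    span_cross <- which(vapply(seq_len(nrow(feats)), function(i) {
      iv <- feats$intervals[[i]]
      s0 <- iv[1L, 1L]; e0 <- iv[nrow(iv), 2L]
      if (feats$may_wrap_origin[i] || e0 <= s0) {
        # wrapping span covers [s0, n) + [0, e0')
        sp <- span_of(iv, n)
        in_wrap_span(p, sp$start, sp$end, n)
      } else {
        sp <- span_of(iv, n)
        sp$start < p && p < sp$end
      }
    }, logical(1)))
    ov_i <- if (length(span_cross)) span_cross[1L] else NA_integer_
    # signed distances to nearest feature edge on each side (circular)
    ends <- ff$end; starts <- ff$start
    dist_left <- (p - ends) %% n          # gap if feature ends before p
    dist_right <- (starts - p) %% n       # gap if feature starts after p
    li <- which.min(dist_left)
    ri <- which.min(dist_right)
    left_feature <- ff$name[li]; left_distance <- as.integer(dist_left[li])
    right_feature <- ff$name[ri]; right_distance <- as.integer(dist_right[ri])
    if (!is.na(ov_i)) {
      sp <- span_of(feats$intervals[[ov_i]], n)
      # overlap extents on the two sides of the junction
      up <- (p - sp$start) %% n
      down <- (sp$end - p) %% n
      left_feature <- feats$name[ov_i]; left_distance <- -as.integer(up)
      right_feature <- feats$name[ov_i]; right_distance <- -as.integer(down)
    }
    tibble::tibble(
      junction = jn, position = as.integer(p),
      left_feature = left_feature, left_distance = left_distance,
      right_feature = right_feature, right_distance = right_distance,
      overlap_feature = if (is.na(ov_i)) NA_character_ else feats$name[ov_i],
      overlap_extent = if (is.na(ov_i)) NA_integer_ else
        -min(left_distance, right_distance)
    )
  })
  rows <- dplyr::bind_cols(rows, classify_rows(rows, can, partition))
  structure(rows, class = c("junction_profile", class(tibble::tibble())),
            identifier = plastome$identifier,
            genome_length = n, partition = partition)
}

span_of <- function(iv, n) {
  s0 <- iv[1L, 1L]; e0 <- iv[nrow(iv), 2L]
  list(start = s0, end = if (e0 <= s0) e0 + n else e0)
}

in_wrap_span <- function(p, s, e, n) {
  # span possibly expressed with e > n
  pp <- c(p, p + n)
  any(s < pp & pp < e)
}

# derive classification label + payload genes per junction row
classify_rows <- function(rows, can, partition) {
  feats <- can$features
  n <- can$length
  purrr::map_dfr(seq_len(nrow(rows)), function(r) {
    p <- rows$position[r]
    label <- NA_character_
    if (!is.na(rows$overlap_feature[r])) {
      i <- which(feats$name == rows$overlap_feature[r])[1L]
      iv <- feats$intervals[[i]]
      # re-find the actual overlapping feature index (names can repeat in IR)
      cand <- which(vapply(seq_len(nrow(feats)), function(ii) {
        sp <- span_of(feats$intervals[[ii]], n)
        in_wrap_span(p, sp$start, sp$end, n)
      }, logical(1)))
      i <- cand[1L]
      iv <- feats$intervals[[i]]
      in_exon <- any(vapply(seq_len(nrow(iv)), function(j) {
        s <- iv[j, 1L]; e <- iv[j, 2L]
        if (s < e) s < p && p < e else in_wrap_span(p, s, e + n, n)
      }, logical(1)))
      label <- if (in_exon) paste0("within:", feats$name[i])
               else paste0("within-intron:", feats$name[i])
    } else {
      label <- paste0("between:", rows$left_feature[r], ",",
                      rows$right_feature[r])
    }
    payload <- junction_payload(rows$junction[r], can, partition)
    tibble::tibble(class = label,
                   payload_genes = list(payload))
  })
}

# LSC-origin genes (trnH, psbA and their fragments) captured inside the IR
# copy adjacent to the junction
junction_payload <- function(junction, can, partition,
                             payload_stems = c("trnh", "psba")) {
  if (!junction %in% c("J_LB", "J_LA")) return(character(0))
  n <- can$length
  reg <- if (junction == "J_LB") partition$irb else partition$ira
  ff <- flat_features(can)
  if (is.null(ff)) return(character(0))
  inside <- ff[ff$start >= reg["start"] & ff$end <= reg["end"], ]
  hits <- inside[gene_stem(inside$name) %in% payload_stems, ]
  # genomic order along the canonical rotation
  hits <- hits[order(hits$start), ]
  unique(hits$name)
}

#' Classify one junction
#'
#' @param profile A [locate_junctions()] result.
#' @param junction One of `"J_LB"`, `"J_SB"`, `"J_SA"`, `"J_LA"`.
#' @return One-row tibble with `junction`, `class`
#'   (`within:<gene>`, `within-intron:<gene>`, or `between:<A>,<B>`) and
#'   `payload_genes` (list column, genomic order).
#' @export
classify_junction <- function(profile, junction) {
  hit <- which(profile$junction == junction)
  if (length(hit) == 0L)
    ps_abort(paste0("unknown junction id: ", junction), "ps_key_error")
  tibble::as_tibble(profile[hit, c("junction", "class", "payload_genes")])
}

#' @method tidy junction_profile
#' @export
tidy.junction_profile <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x)[names(x)])
  out$payload_genes <- vapply(out$payload_genes, paste, character(1),
                              collapse = ",")
  out$position <- out$position + 1L   # 1-based report
  out
}

# ---- spacer insertion screening ------------------------------------------

# locate the spacer between two named genes; returns 0-based [start,end)
# instances on the canonical rotation
find_spacer_instances <- function(can, gene_a, gene_b) {
  ff <- flat_features(can)
  n <- can$length
  ia <- which(gene_stem(ff$name) == gene_stem(gene_a))
  ib <- which(gene_stem(ff$name) == gene_stem(gene_b))
  if (length(ia) == 0L || length(ib) == 0L) {
    missing <- c(gene_a, gene_b)[c(length(ia) == 0L, length(ib) == 0L)]
    ps_abort(paste0("spacer undefined: flanking gene(s) missing: ",
                    paste(missing, collapse = ", ")), "ps_spacer_undefined_error")
  }
  # for each copy of gene A, the spacer to its nearest copy of B (either
  # direction); IR symmetry yields mirrored instances of equal length
  spans <- purrr::map_dfr(ia, function(a) {
    d1 <- (ff$start[ib] - ff$end[a]) %% n    # a ... b clockwise
    d2 <- (ff$start[a] - ff$end[ib]) %% n    # b ... a clockwise
    if (min(d1) <= min(d2)) {
      b <- ib[which.min(d1)]
      tibble::tibble(start = ff$end[a] %% n, len = min(d1))
    } else {
      b <- ib[which.min(d2)]
      tibble::tibble(start = ff$end[b] %% n, len = min(d2))
    }
  })
  dplyr::distinct(spans)
}

#' Screen an intergenic spacer for a junction-shift insertion
#'
#' Compares the observed spacer length between two flanking genes against a
#' baseline (an explicit length, or the median of a reference panel of spacer
#' sequences). An insertion is called when the excess is at least
#' `min_excess`. When reference spacer sequences are supplied the insertion
#' interval is localized as the maximal query segment unaligned to the
#' baseline spacer; with a bare numeric baseline the interval is `NA` (a
#' length alone cannot place the insertion) and the insertion length is the
#' length excess. Payload pseudogene fragments (psbA, trnH, trnV, ...) are
#' searched by local alignment (match +1, mismatch -1, gap -2) in both
#' orientations and reported at >= `min_identity` over >= `min_fragment`.
#'
#' @param plastome A [plastome()].
#' @param spacer Character vector of the two flanking gene names, e.g.
#'   `c("trnV-GAC", "rrn16")`.
#' @param payload_library Named character vector of payload reference
#'   sequences (at least psbA, trnH, trnV for the classical survey).
#' @param baseline Numeric baseline spacer length in bases, or a character
#'   vector of reference spacer sequences (panel; median length is the
#'   baseline and the first panel member localizes the insertion).
#' @param partition Optional precomputed partition (detected if omitted).
#' @param min_excess Minimum length excess to call an insertion (default 200).
#' @param min_identity Payload fragment reporting floor, percent (default 70).
#' @param min_fragment Minimum payload fragment length in bases (default 50).
#' @return Object of class `insertion_report`: one-row tibble with spacer id,
#'   observed/baseline lengths, `insertion_present`, insertion interval
#'   (1-based inclusive, genome coordinates on the canonical rotation),
#'   `insertion_length`, and a list column `fragments` (gene, length,
#'   identity, orientation).
#' @export
screen_spacer_insertion <- function(plastome, spacer, payload_library = character(),
                                    baseline, partition = NULL,
                                    min_excess = 200L, min_identity = 70,
                                    min_fragment = 50L) {
  stopifnot(length(spacer) == 2L)
  if (is.null(partition)) partition <- detect_inverted_repeat(plastome)
  can <- canonicalize_plastome(plastome, partition)
  inst <- find_spacer_instances(can, spacer[1], spacer[2])
  n <- can$length
  # IR-symmetric copies collapse to one context: keep distinct lengths
  if (length(unique(inst$len)) > 1L)
    ps_abort("multiple spacer instances with different lengths outside IR symmetry",
             "ps_ambiguity_error")
  sp <- inst[1L, ]
  observed <- as.integer(sp$len)
  spacer_seq <- if (observed > 0L) plastome_subseq(can, sp$start, sp$start + observed) else ""

  if (is.numeric(baseline)) {
    base_len <- as.integer(round(baseline))
    base_seq <- NULL
  } else {
    base_len <- as.integer(round(stats::median(nchar(baseline))))
    base_seq <- toupper(baseline[[1L]])
  }
  present <- (observed - base_len) >= min_excess
  ins_start <- NA_integer_; ins_end <- NA_integer_; ins_len <- 0L
  if (present) {
    if (!is.null(base_seq)) {
      loc <- locate_insertion(spacer_seq, base_seq)
      ins_start <- as.integer(sp$start + loc$start)      # 0-based genome
      ins_end <- as.integer(sp$start + loc$end)
      ins_len <- loc$end - loc$start
    } else {
      ins_len <- observed - base_len
    }
  }
  frags <- tibble::tibble(gene = character(), length = integer(),
                          identity = numeric(), orientation = character())
  if (present && length(payload_library) > 0L && nchar(spacer_seq) > 0L) {
    target <- if (!is.na(ins_start))
      substr(spacer_seq, (ins_start - sp$start) + 1L, ins_end - sp$start)
    else spacer_seq
    frags <- payload_fragments(target, payload_library, min_identity,
                               min_fragment)
  }
  structure(
    tibble::tibble(
      identifier = plastome$identifier,
      spacer = paste(normalize_gene_name(spacer[1]),
                     normalize_gene_name(spacer[2]), sep = "-"),
      observed_length = observed, baseline_length = base_len,
      insertion_present = present,
      insertion_start = if (is.na(ins_start)) NA_integer_ else ins_start + 1L,
      insertion_end = ins_end,
      insertion_length = as.integer(ins_len),
      fragments = list(frags)
    ),
    class = c("insertion_report", class(tibble::tibble()))
  )
}

# maximal query segment absent from a global alignment against the baseline
# (the longest run of baseline gap columns, in query coordinates, 0-based)
locate_insertion <- function(query, baseline) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(baseline),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 0.5)
  qa <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  qpos <- cumsum(qa != "-")       # query coordinate at each alignment column
  gap <- sa == "-" & qa != "-"
  if (!any(gap)) {
    d <- max(0L, nchar(query) - nchar(baseline))
    return(list(start = nchar(query) - d, end = nchar(query)))
  }
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  i <- runs[which.max(r$lengths[runs])]
  list(start = qpos[starts[i]] - 1L, end = qpos[ends[i]])
}

payload_fragments <- function(target, payload_library, min_identity,
                              min_fragment) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  rows <- purrr::map_dfr(names(payload_library), function(gname) {
    best <- NULL
    for (orient in c("+", "-")) {
      q <- if (orient == "+") toupper(payload_library[[gname]])
           else revcomp(toupper(payload_library[[gname]]))
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), Biostrings::DNAString(target),
        type = "local", substitutionMatrix = submat,
        gapOpening = 2, gapExtension = 2)
      alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
      if (alen == 0L) next
      ident <- Biostrings::pid(pa)
      cand <- tibble::tibble(gene = gname, length = as.integer(alen),
                             identity = round(ident, 1), orientation = orient)
      if (is.null(best) || cand$length * cand$identity >
          best$length * best$identity) best <- cand
    }
    best %||% tibble::tibble(gene = character(), length = integer(),
                             identity = numeric(), orientation = character())
  })
  rows[rows$length >= min_fragment & rows$identity >= min_identity, ]
}

#' @method tidy insertion_report
#' @export
tidy.insertion_report <- function(x, ...) {
  tidyr::unnest(tibble::as_tibble(x), "fragments", keep_empty = TRUE,
                names_sep = "_")
}

# ---- in-silico PCR -------------------------------------------------------

#' In-silico PCR on a circular genome
#'
#' Finds all primer binding sites on both strands with at most `max_mismatch`
#' mismatches and none in the 3'-terminal 5 bases, then reports every
#' convergent site pair whose product is at most `max_product` on the circle.
#'
#' @param plastome A [plastome()].
#' @param forward,reverse Primer sequences (>= 15 bp, A/C/G/T only).
#' @param max_mismatch Maximum mismatches per site (default 1).
#' @param max_product Maximum product length in bases (default 5000).
#' @param partition Optional partition; when given, each amplicon reports
#'   which junctions it spans.
#' @return Tibble of amplicons: forward/reverse site positions (1-based,
#'   input coordinates), strands, mismatch counts, `product_length`, and
#'   `spans_junction` (comma-separated or `""`). Zero rows = no amplification.
#' @export
insilico_pcr <- function(plastome, forward, reverse, max_mismatch = 1L,
                         max_product = 5000L, partition = NULL) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (grepl("[^ACGT]", p))
      ps_abort("primer contains non-ACGT characters", "ps_primer_alphabet_error")
    if (nchar(p) < 15L)
      ps_abort("primers must be at least 15 bp", "ps_validation_error")
  }
  s <- seq_chars(plastome$sequence)
  n <- length(s)
  sites <- dplyr::bind_rows(
    primer_sites(s, n, forward, max_mismatch, "forward"),
    primer_sites(s, n, reverse, max_mismatch, "reverse"))
  if (nrow(sites) == 0L) return(empty_amplicons())
  plus <- sites[sites$strand == "+", ]
  minus <- sites[sites$strand == "-", ]
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(empty_amplicons())
  combos <- expand.grid(i = seq_len(nrow(plus)), j = seq_len(nrow(minus)))
  rows <- purrr::map_dfr(seq_len(nrow(combos)), function(r) {
    pl <- plus[combos$i[r], ]; mi <- minus[combos$j[r], ]
    if (pl$primer == mi$primer && pl$start == mi$start) return(NULL)
    # product runs clockwise from the + site start to the - site end
    prod_len <- ((mi$end - pl$start) %% n)
    if (prod_len == 0L) prod_len <- n
    if (prod_len < max(pl$end - pl$start, 0L) + (mi$end - mi$start) ||
        prod_len > max_product) return(NULL)
    # the minus site must lie fully within the product (convergent pair)
    tibble::tibble(
      forward_primer = pl$primer, forward_position = pl$start + 1L,
      forward_mismatches = pl$mismatches,
      reverse_primer = mi$primer, reverse_position = mi$start + 1L,
      reverse_mismatches = mi$mismatches,
      product_length = as.integer(prod_len))
  })
  if (is.null(rows) || nrow(rows) == 0L) return(empty_amplicons())
  rows <- dplyr::distinct(rows)
  rows$spans_junction <- ""
  if (!is.null(partition)) {
    jp <- junction_positions(partition)
    # junction positions are on the canonical rotation; map back to input
    rows$spans_junction <- vapply(seq_len(nrow(rows)), function(r) {
      a0 <- rows$forward_position[r] - 1L
      len <- rows$product_length[r]
      jin <- vapply(jp, function(p) {
        pin <- canonical_to_input(p, partition)
        ((pin - a0) %% n) < len
      }, logical(1))
      paste(names(jp)[jin], collapse = ",")
    }, character(1))
  }
  rows[order(rows$forward_position, rows$product_length), ]
}

empty_amplicons <- function() {
  tibble::tibble(forward_primer = character(), forward_position = integer(),
                 forward_mismatches = integer(), reverse_primer = character(),
                 reverse_position = integer(), reverse_mismatches = integer(),
                 product_length = integer(), spans_junction = character())
}

# map a canonical-rotation position back to input coordinates
canonical_to_input <- function(p, partition) {
  n <- partition$genome_length
  x <- (p + partition$canonical_offset) %% n
  if (partition$flipped) x <- (n - x) %% n
  x
}

# all binding sites of `primer` on both strands; 0-based [start,end) on the
# input sequence; 3'-anchor: no mismatches in the last 5 bases of the primer
primer_sites <- function(s, n, primer, max_mismatch, which_primer) {
  m <- nchar(primer)
  pc <- seq_chars(primer)
  sd <- c(s, s[seq_len(m - 1L)])   # doubled head for circular sites
  hit_rows <- list()
  for (strand in c("+", "-")) {
    tpl <- if (strand == "+") pc else revcomp_chars(pc)
    mism <- integer(n); anchor_bad <- logical(n)
    # positions of the primer 3' end within the template on this strand
    anchor_idx <- if (strand == "+") (m - 4L):m else 1L:5L
    for (t in seq_len(m)) {
      neq <- sd[seq_len(n) + t - 1L] != tpl[t]
      mism <- mism + neq
      if (t %in% anchor_idx) anchor_bad <- anchor_bad | neq
    }
    ok <- which(mism <= max_mismatch & !anchor_bad)
    if (length(ok) > 0L) {
      hit_rows[[strand]] <- tibble::tibble(
        primer = which_primer, strand = strand,
        start = ok - 1L, end = ok - 1L + m,
        mismatches = as.integer(mism[ok]))
    }
  }
  out <- dplyr::bind_rows(hit_rows)
  if (nrow(out) == 0L)
    out <- tibble::tibble(primer = character(), strand = character(),
                          start = integer(), end = integer(),
                          mismatches = integer())
  out
}

# ---- junction depth QC ----------------------------------------------------

#' Junction coverage-depth quality control
#'
#' For each junction, reports the median depth in flanking windows and flags
#' `drop-suspect` when the median of the inner 100-bp window centred on the
#' junction falls below `drop_threshold` times the median of the two flanking
#' windows. Medians (not means) are used for robustness to mapping spikes.
#'
#' @param profile A [locate_junctions()] result (positions on the canonical
#'   rotation must correspond to the depth profile's coordinates).
#' @param depth A [depth_profile()] with length equal to the genome length.
#' @param window Flanking window size in bases (default 500).
#' @param drop_threshold Inner/flanking median ratio below which a junction
#'   is flagged (default 0.3).
#' @return Object of class `junction_qc_report`: tibble with per-junction
#'   medians, `drop_ratio` (= min(left,right)/max(left,right)),
#'   `inner_ratio`, and `flag` in `pass` / `drop-suspect` / `zero-coverage`.
#' @export
junction_depth_qc <- function(profile, depth, window = 500L,
                              drop_threshold = 0.3) {
  n <- attr(profile, "genome_length")
  if (length(depth$depths) != n)
    ps_abort("depth profile length does not match genome length",
             "ps_consistency_error")
  part <- attr(profile, "partition")
  min_region <- min(part$lsc_length, part$ssc_length, part$ir_length)
  if (window > min_region)
    ps_abort(sprintf("window (%d) larger than the smallest region (%d)",
                     window, min_region), "ps_window_too_large_error")
  d <- depth$depths
  half_inner <- 50L
  rows <- purrr::map_dfr(seq_len(nrow(profile)), function(r) {
    p <- profile$position[r]
    inner <- d[circ1(seq(p - half_inner + 1L, length.out = 2L * half_inner), n)]
    left <- d[circ1(seq(p - half_inner - window + 1L, length.out = window), n)]
    right <- d[circ1(seq(p + half_inner + 1L, length.out = window), n)]
    lm <- stats::median(left); rm_ <- stats::median(right)
    im <- stats::median(inner)
    fm <- stats::median(c(left, right))
    if (fm == 0) {
      flag <- "zero-coverage"; ratio <- NA_real_; iratio <- NA_real_
    } else {
      ratio <- min(lm, rm_) / max(lm, rm_)
      iratio <- im / fm
      flag <- if (iratio < drop_threshold) "drop-suspect" else "pass"
    }
    tibble::tibble(junction = profile$junction[r], position = p + 1L,
                   left_median = lm, right_median = rm_, inner_median = im,
                   drop_ratio = ratio, inner_ratio = iratio, flag = flag)
  })
  structure(rows, class = c("junction_qc_report", class(tibble::tibble())),
            identifier = depth$identifier)
}
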