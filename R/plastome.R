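# The annotated circular plastome container shared by all analyses.

#' Construct an annotated plastome
#'
#' A plastome is a circular DNA sequence over \{A,C,G,T,N\} plus a feature
#' table. Feature intervals are 0-based half-open on the stored sequence; a
#' feature whose location crosses the origin carries `may_wrap_origin = TRUE`
#' and is represented either by multiple intervals or by one interval with
#' `start >= end`.
#'
#' @param identifier Accession or name string.
#' @param sequence DNA string; uppercased on construction.
#' @param features Feature tibble as produced by [gene_feature()] /
#'   [feature_table()]; may be empty.
#' @param source File path of origin or `"synthetic"`.
#' @return An object of class `plastome`.
#' @seealso [read_genbank()], [write_genbank()]
#' @export
plastome <- function(identifier, sequence, features = feature_table(),
                     source = "synthetic") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) ps_abort("plastome sequence has zero length", "ps_validation_error")
  if (grepl("[^ACGTN]", sequence))
    ps_abort("plastome sequence contains characters outside {A,C,G,T,N}",
             "ps_validation_error")
  features <- validate_features(features, n)
  structure(
    list(identifier = as.character(identifier), sequence = sequence,
         length = n, features = features, source = source),
    class = "plastome"
  )
}

#' Build one gene feature row
#'
#' @param name Gene symbol (tRNA names are normalized to `trnX-ANT`).
#' @param kind One of `"protein"`, `"trna"`, `"rrna"`.
#' @param start,end 0-based half-open interval bounds; vectors for
#'   multi-interval (intron-containing or origin-wrapping) features.
#' @param strand `"+"` or `"-"`.
#' @param pseudo Is the feature a pseudogene / truncated copy?
#' @param may_wrap_origin Does the location cross the circle origin?
#' @return One-row feature tibble.
#' @export
gene_feature <- function(name, kind, start, end, strand = "+", pseudo = FALSE,
                         may_wrap_origin = FALSE) {
  stopifnot(length(start) == length(end), length(start) >= 1L)
  tibble::tibble(
    name = normalize_gene_name(name),
    kind = match.arg(kind, c("protein", "trna", "rrna")),
    pseudo = isTRUE(pseudo),
    strand = match.arg(strand, c("+", "-")),
    intervals = list(cbind(start = as.integer(start), end = as.integer(end))),
    may_wrap_origin = isTRUE(may_wrap_origin)
  )
}

#' An empty feature table
#' @return Zero-row feature tibble with the canonical columns.
#' @export
feature_table <- function() {
  tibble::tibble(name = character(), kind = character(), pseudo = logical(),
                 strand = character(), intervals = list(),
                 may_wrap_origin = logical())
}

validate_features <- function(features, n) {
  if (nrow(features) == 0L) return(features)
  bad_kind <- setdiff(unique(features$kind), c("protein", "trna", "rrna"))
  if (length(bad_kind) > 0L) {
    offenders <- features$name[features$kind %in% bad_kind]
    ps_abort(paste0("features with unknown kind: ",
                    paste(offenders, collapse = ", ")),
             "ps_classification_error")
  }
  for (i in seq_len(nrow(features))) {
    iv <- features$intervals[[i]]
    if (is.null(dim(iv)) || ncol(iv) != 2L || nrow(iv) < 1L)
      ps_abort(sprintf("feature '%s' has malformed intervals", features$name[i]),
               "ps_validation_error")
    wraps <- iv[, 1L] >= iv[, 2L]
    if (any(wraps) && !features$may_wrap_origin[i])
      ps_abort(sprintf("feature '%s' wraps the origin but is not flagged",
                       features$name[i]), "ps_validation_error")
    if (any(iv < 0L) || any(iv > n))
      ps_abort(sprintf("feature '%s' exceeds genome bounds", features$name[i]),
               "ps_validation_error")
  }
  features
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp (circular), %d features [%s]\n",
              x$identifier, format(x$length, big.mark = ","),
              nrow(x$features), x$source))
  invisible(x)
}

#' @export
length.plastome <- function(x) x$length

# feature span on the circle: first start to last end, lengths per interval
interval_lengths <- function(iv, n) {
  ifelse(iv[, 2L] > iv[, 1L], iv[, 2L] - iv[, 1L],
         (n - iv[, 1L]) + iv[, 2L])
}

feature_length <- function(feature_row, n) {
  sum(interval_lengths(feature_row$intervals[[1L]], n))
}

#' Tidy a plastome's feature table
#'
#' One row per feature interval with 1-based inclusive coordinates, suitable
#' for reports and plotting.
#'
#' @param x A `plastome`.
#' @param ... Unused.
#' @return A tibble with columns `name`, `kind`, `pseudo`, `strand`,
#'   `part`, `start`, `end` (1-based inclusive).
#' @method tidy plastome
#' @export
tidy.plastome <- function(x, ...) {
  if (nrow(x$features) == 0L) {
    return(tibble::tibble(name = character(), kind = character(),
                          pseudo = logical(), strand = character(),
                          part = integer(), start = integer(), end = integer()))
  }
  purrr::map_dfr(seq_len(nrow(x$features)), function(i) {
    iv <- x$features$intervals[[i]]
    tibble::tibble(
      name = x$features$name[i], kind = x$features$kind[i],
      pseudo = x$features$pseudo[i], strand = x$features$strand[i],
      part = seq_len(nrow(iv)),
      start = as.integer(iv[, 1L] + 1L), end = as.integer(iv[, 2L])
    )
  })
}

# ---- geometric transforms -------------------------------------------------

# rotate the circle so that old position `offset` (0-based) becomes 0
rotate_plastome <- function(p, offset) {
  n <- p$length
  offset <- ((offset %% n) + n) %% n
  if (offset == 0L) return(p)
  seq2 <- paste0(substr(p$sequence, offset + 1L, n),
                 substr(p$sequence, 1L, offset))
  feats <- p$features
  if (nrow(feats) > 0L) {
    for (i in seq_len(nrow(feats))) {
      iv <- feats$intervals[[i]]
      s <- (iv[, 1L] - offset) %% n
      e <- (iv[, 2L] - offset) %% n
      e[e == 0L] <- n
      feats$intervals[[i]] <- cbind(start = as.integer(s), end = as.integer(e))
      feats$may_wrap_origin[i] <- any(s >= e)
    }
  }
  out <- p
  out$sequence <- seq2
  out$features <- feats
  out
}

# reverse-complement the whole plastome (positions map x -> n - x)
flip_plastome <- function(p) {
  n <- p$length
  seq2 <- revcomp(p$sequence)
  feats <- p$features
  if (nrow(feats) > 0L) {
    for (i in seq_len(nrow(feats))) {
      iv <- feats$intervals[[i]]
      s <- (n - iv[, 2L]) %% n
      e <- (n - iv[, 1L]) %% n
      e[e == 0L] <- n
      ord <- rev(seq_len(nrow(iv)))
      feats$intervals[[i]] <- cbind(start = as.integer(s[ord]),
                                    end = as.integer(e[ord]))
      feats$may_wrap_origin[i] <- any(s >= e)
      feats$strand[i] <- if (feats$strand[i] == "+") "-" else "+"
    }
  }
  out <- p
  out$sequence <- seq2
  out$features <- feats
  out
}

# extract circular subsequence [start, end) 0-based, possibly wrapping
plastome_subseq <- function(p, start, end) {
  n <- p$length
  start <- ((start %% n) + n) %% n
  end2 <- ((end - 1L) %% n) + 1L  # end as 1..n (end==0 means n)
  if (end > start && end <= n) {
    substr(p$sequence, start + 1L, end)
  } else {
    len <- ((end - start) %% n + n) %% n
    if (len == 0L) len <- n
    circ_substr(p$sequence, start + 1L, len)
  }
}
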