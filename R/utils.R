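# Internal sequence / coordinate helpers. Internal coordinates are 0-based,
# half-open throughout; user-visible reports convert to 1-based inclusive.

#' Reverse complement of DNA strings
#'
#' Vectorised over character strings; understands A/C/G/T/N and the IUPAC
#' ambiguity letters, plus '-' (kept in place).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNRYSWKMBDHVacgtnryswkmbdhv",
                 "TGCANYRSWMKVHDBtgcanyrswmkvhdb", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# complement of a character vector of single bases (no reversal)
comp_chars <- function(ch) {
  unlist(strsplit(chartr("ACGTN", "TGCAN", paste(ch, collapse = "")), "",
                  fixed = TRUE), use.names = FALSE)
}

revcomp_chars <- function(ch) rev(comp_chars(ch))

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_seq <- function(ch) paste(ch, collapse = "")

# circular 1-based index
circ1 <- function(i, n) ((i - 1L) %% n) + 1L

# circular substring (1-based start, length len) out of a character scalar
circ_substr <- function(s, start, len) {
  n <- nchar(s)
  start <- circ1(start, n)
  if (start + len - 1L <= n) return(substr(s, start, start + len - 1L))
  paste0(substr(s, start, n), substr(s, 1L, len - (n - start + 1L)))
}

ps_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "plastshift_error"), ...)
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' GenBank locations are 1-based inclusive; internal arithmetic uses 0-based
#' half-open intervals. These two helpers are exact inverses.
#'
#' @param start,end Interval bounds in the source convention.
#' @return Two-column integer matrix `start`, `end` in the target convention.
#' @export
to_zero_based <- function(start, end) {
  cbind(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) {
  cbind(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Normalize a tRNA/gene name
#'
#' Collapses notational variants such as `trnV(GAC)` / `trnV_GAC` /
#' `TRNV-gac` to the canonical `trnV-GAC`; other gene symbols are returned
#' with their conventional capitalisation untouched apart from whitespace.
#'
#' @param x Character vector of gene names.
#' @return Normalized character vector.
#' @export
normalize_gene_name <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^(trn[A-Za-z])[\\(_-]([A-Za-z]{3})\\)?$", x,
                             ignore.case = TRUE))
  vapply(seq_along(x), function(i) {
    mi <- m[[i]]
    if (length(mi) == 3L) {
      stem <- paste0("trn", toupper(substr(mi[2], 4, 4)))
      paste0(stem, "-", toupper(mi[3]))
    } else {
      x[i]
    }
  }, character(1))
}

# gene stem: 'trnV-GAC' -> 'trnV'; 'psbA' -> 'psbA' (case-insensitive match key)
gene_stem <- function(x) tolower(sub("[\\(_-].*$", "", trimws(x)))

same_gene <- function(a, b) gene_stem(a) == gene_stem(b)

# run RNG-dependent code under a seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
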