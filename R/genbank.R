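# GenBank flat-file reading and writing for single circular plastome records.
# The subset handled is the one plastome submissions use: LOCUS/ACCESSION
# headers, a FEATURES table with gene/CDS/tRNA/rRNA keys, location operators
# complement() and join(), partial markers < and >, and an ORIGIN block.

#' Read a GenBank flat file into a plastome
#'
#' Parses one circular record. Typed features (CDS, tRNA, rRNA) become gene
#' features of kind protein/trna/rrna; `gene` entries are used only where no
#' typed feature covers the same locus (as is usual for pseudogenes annotated
#' with a bare `gene`/`/pseudo` pair), their kind inferred from the symbol.
#' Coordinates are converted from 1-based inclusive to 0-based half-open;
#' join() locations crossing the origin are flagged `may_wrap_origin`.
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @return A [plastome()].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path))
    ps_abort(paste0("no such file: ", path), "ps_format_error")
  lines <- readLines(path, warn = FALSE)
  locus_at <- grep("^LOCUS", lines)
  if (length(locus_at) == 0L)
    ps_abort(sprintf("%s: no LOCUS line; not a GenBank flat file", path),
             "ps_format_error")
  if (length(locus_at) > 1L)
    ps_abort(sprintf("%s: %d records found, expected one", path,
                     length(locus_at)), "ps_ambiguity_error")

  identifier <- {
    acc <- grep("^ACCESSION", lines, value = TRUE)
    if (length(acc) >= 1L && nchar(trimws(sub("^ACCESSION", "", acc[1]))) > 0L)
      strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    else strsplit(trimws(sub("^LOCUS", "", lines[locus_at])), "\\s+")[[1]][1]
  }

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L)
    ps_abort(sprintf("%s: no ORIGIN block", path), "ps_format_error")
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > origin_at[1]][1] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1] + 1L):(end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L)
    ps_abort(sprintf("%s: zero-length sequence", path), "ps_validation_error")

  feats <- parse_genbank_features(lines, origin_at[1], path)
  p <- plastome(identifier, sequence, feature_table(), source = path)
  p$features <- resolve_genbank_features(feats, nchar(sequence))
  p$features <- validate_features(p$features, p$length)
  p
}

# raw feature entries: key, location string, qualifiers, line number
parse_genbank_features <- function(lines, origin_line, path) {
  f_at <- grep("^FEATURES", lines)
  if (length(f_at) == 0L) return(list())
  block <- lines[(f_at[1] + 1L):(origin_line - 1L)]
  lineno <- (f_at[1] + 1L):(origin_line - 1L)
  entries <- list()
  cur <- NULL
  in_location <- FALSE
  for (i in seq_along(block)) {
    ln <- block[i]
    if (grepl("^ {5}\\S", ln)) {             # new feature key
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      key <- trimws(substr(ln, 1, 20))
      loc <- trimws(substring(ln, 22))
      cur <- list(key = key, location = loc, qualifiers = character(),
                  line = lineno[i])
      in_location <- TRUE
    } else if (grepl("^ {21}", ln) && !is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$qualifiers <- c(cur$qualifiers, txt)
        in_location <- FALSE
      } else if (in_location) {
        cur$location <- paste0(cur$location, txt)   # continued location
      } else if (length(cur$qualifiers) > 0L) {
        k <- length(cur$qualifiers)
        cur$qualifiers[k] <- paste(cur$qualifiers[k], txt)
      }
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
  entries
}

parse_location <- function(loc, path, line) {
  loc0 <- gsub("\\s", "", loc)
  strand <- "+"
  body <- loc0
  if (grepl("^complement\\(", body)) {
    strand <- "-"
    body <- sub("^complement\\((.*)\\)$", "\\1", body)
  }
  if (grepl("^join\\(", body)) body <- sub("^join\\((.*)\\)$", "\\1", body)
  if (grepl("^order\\(", body)) body <- sub("^order\\((.*)\\)$", "\\1", body)
  parts <- strsplit(body, ",", fixed = TRUE)[[1]]
  iv <- matrix(NA_integer_, nrow = length(parts), ncol = 2L,
               dimnames = list(NULL, c("start", "end")))
  for (j in seq_along(parts)) {
    pp <- gsub("[<>]", "", parts[j])
    if (grepl("^\\d+\\.\\.\\d+$", pp)) {
      ab <- as.integer(strsplit(pp, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", pp)) {
      ab <- c(as.integer(pp), as.integer(pp))
    } else {
      ps_abort(sprintf("%s: unparsable location '%s' at line %d",
                       path, loc, line), "ps_format_error")
    }
    iv[j, ] <- c(ab[1] - 1L, ab[2])   # 0-based half-open
  }
  list(intervals = iv, strand = strand)
}

qualifier_value <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  gsub('^"|"$', "", sub(paste0("^/", name, "="), "", hit[1]))
}

infer_kind <- function(name) {
  stem <- gene_stem(name)
  if (startsWith(stem, "trn")) "trna"
  else if (startsWith(stem, "rrn")) "rrna"
  else "protein"
}

resolve_genbank_features <- function(entries, n) {
  keep_keys <- c("CDS", "tRNA", "rRNA", "gene")
  entries <- Filter(function(e) e$key %in% keep_keys, entries)
  if (length(entries) == 0L) return(feature_table())
  rows <- purrr::map(entries, function(e) {
    loc <- parse_location(e$location, "genbank", e$line)
    name <- qualifier_value(e$qualifiers, "gene")
    if (is.na(name)) name <- qualifier_value(e$qualifiers, "product")
    if (is.na(name)) name <- tolower(e$key)
    pseudo <- any(grepl("^/pseudo", e$qualifiers))
    kind <- switch(e$key, CDS = "protein", tRNA = "trna", rRNA = "rrna",
                   gene = infer_kind(name))
    iv <- loc$intervals
    wraps <- any(iv[, 1L] >= iv[, 2L]) ||
      (nrow(iv) > 1L && iv[1L, 2L] == n && iv[nrow(iv), 1L] == 0L)
    tibble::tibble(name = normalize_gene_name(name), kind = kind,
                   pseudo = pseudo, strand = loc$strand,
                   intervals = list(iv), may_wrap_origin = wraps,
                   key = e$key)
  })
  tab <- dplyr::bind_rows(rows)
  typed <- tab[tab$key != "gene", ]
  genes <- tab[tab$key == "gene", ]
  # keep bare `gene` entries only when no typed feature shares the symbol and
  # overlaps the same locus
  if (nrow(genes) > 0L) {
    covered <- vapply(seq_len(nrow(genes)), function(i) {
      gi <- genes$intervals[[i]]
      any(vapply(seq_len(nrow(typed)), function(j) {
        if (!same_gene(genes$name[i], typed$name[j])) return(FALSE)
        tj <- typed$intervals[[j]]
        any(outer(seq_len(nrow(gi)), seq_len(nrow(tj)), Vectorize(function(a, b)
          gi[a, 1L] < tj[b, 2L] && tj[b, 1L] < gi[a, 2L])))
      }, logical(1)))
    }, logical(1))
    genes <- genes[!covered, ]
  }
  out <- dplyr::bind_rows(typed, genes)
  out$key <- NULL
  out
}

#' Write a plastome as a GenBank flat file
#'
#' Emits one typed feature line (CDS/tRNA/rRNA) per gene feature so that
#' [read_genbank()] round-trips names, kinds, strands, pseudo flags, and
#' intervals exactly.
#'
#' @param p A [plastome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(p, path) {
  n <- p$length
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl(sprintf("LOCUS       %-17s%11d bp    DNA     circular PLN 01-JAN-2024",
             p$identifier, n))
  wl("DEFINITION  ", p$identifier, " plastid genome.")
  wl("ACCESSION   ", p$identifier)
  wl("FEATURES             Location/Qualifiers")
  wl(sprintf("     %-16s%s", "source", sprintf("1..%d", n)))
  wl(strrep(" ", 21), "/organism=\"", p$identifier, "\"")
  if (nrow(p$features) > 0L) {
    for (i in seq_len(nrow(p$features))) {
      ft <- p$features[i, ]
      key <- switch(ft$kind, protein = "CDS", trna = "tRNA", rrna = "rRNA")
      iv <- ft$intervals[[1L]]
      segs <- character(nrow(iv))
      for (j in seq_len(nrow(iv))) {
        s <- iv[j, 1L]; e <- iv[j, 2L]
        if (s < e) {
          segs[j] <- sprintf("%d..%d", s + 1L, e)
        } else {  # wraps origin: split into two GenBank segments
          segs[j] <- sprintf("%d..%d,%d..%d", s + 1L, n, 1L, e)
        }
      }
      body <- paste(segs, collapse = ",")
      if (grepl(",", body)) body <- sprintf("join(%s)", body)
      if (ft$strand == "-") body <- sprintf("complement(%s)", body)
      wl(sprintf("     %-16s%s", key, body))
      wl(strrep(" ", 21), "/gene=\"", ft$name, "\"")
      if (ft$pseudo) wl(strrep(" ", 21), "/pseudo")
    }
  }
  wl("ORIGIN")
  s <- tolower(p$sequence)
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wl(sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  wl("//")
  invisible(path)
}
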