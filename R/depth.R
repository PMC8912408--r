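# Per-base coverage-depth profiles and junction QC.

#' Construct a depth profile
#'
#' @param identifier Genome id the profile belongs to.
#' @param depths Integer vector of per-base depths (length = genome length).
#' @return Object of class `depth_profile`.
#' @export
depth_profile <- function(identifier, depths) {
  depths <- as.integer(depths)
  if (any(is.na(depths)) || any(depths < 0L))
    ps_abort("depths must be non-negative integers", "ps_validation_error")
  structure(list(identifier = as.character(identifier), depths = depths),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s: %d bp, median depth %g\n", x$identifier,
              length(x$depths), stats::median(x$depths)))
  invisible(x)
}

#' Read a two-column position/depth table
#'
#' Positions are 1-based; positions absent from the table get depth 0.
#'
#' @param path Path to a whitespace/tab-separated position depth table (an
#'   optional non-numeric header line is skipped).
#' @param genome_length Genome length in bases; the profile is padded to it.
#' @param identifier Genome id recorded in the profile.
#' @return A [depth_profile()].
#' @export
read_depth_table <- function(path, genome_length, identifier = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L && !grepl("^\\s*\\d", lines[1]))
    lines <- lines[-1]
  if (length(lines) == 0L)
    return(depth_profile(identifier, integer(genome_length)))
  parts <- strsplit(trimws(lines), "\\s+")
  pos <- as.integer(vapply(parts, `[`, character(1), 1L))
  dep <- as.integer(vapply(parts, `[`, character(1), 2L))
  if (any(is.na(pos)) || any(is.na(dep)))
    ps_abort(paste0(path, ": malformed position/depth rows"), "ps_format_error")
  if (any(pos < 1L) || any(pos > genome_length))
    ps_abort(sprintf("%s: position %d outside genome of length %d", path,
                     pos[which(pos < 1L | pos > genome_length)[1]],
                     genome_length), "ps_bounds_error")
  depths <- integer(genome_length)
  depths[pos] <- dep
  depth_profile(identifier, depths)
}

#' Write a depth profile as a position/depth table
#'
#' @param profile A [depth_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(profile, path) {
  utils::write.table(
    data.frame(position = seq_along(profile$depths), depth = profile$depths),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
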