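# Batch structure reporting: one row per genome with sizes, GC, census and
# junction classes, collecting per-genome failures without aborting.

#' Configuration for a structure-report run
#'
#' @param min_ir_length Minimum IR length passed to
#'   [detect_inverted_repeat()].
#' @param spacers List of 2-vectors of gene names to screen for insertions
#'   (default the classical trnV(GAC)-rrn16 spacer).
#' @param min_excess Insertion call threshold in bases.
#' @param baselines Named numeric vector of baseline spacer lengths keyed by
#'   `"geneA-geneB"`; spacers without a baseline are reported with length
#'   only.
#' @param seed Integer seed recorded in provenance.
#' @param out_dir Optional output directory: the report TSV and a JSON
#'   provenance file (parameters, package version, seed) are written there.
#' @return A `structure_config` list.
#' @export
structure_config <- function(min_ir_length = 1000L,
                             spacers = list(c("trnV-GAC", "rrn16")),
                             min_excess = 200L,
                             baselines = NULL,
                             seed = 1L, out_dir = NULL) {
  structure(list(min_ir_length = min_ir_length, spacers = spacers,
                 min_excess = min_excess, baselines = baselines,
                 seed = seed, out_dir = out_dir),
            class = "structure_config")
}

#' Structure report across plastomes
#'
#' Runs IR detection, region statistics, gene census, junction
#' classification and (optionally) spacer screening on each genome and
#' aggregates one row per genome. Failures are collected per genome and
#' attached as the `failures` attribute rather than aborting the batch.
#'
#' @param genomes Character vector of GenBank file paths, or a list of
#'   [plastome()] objects.
#' @param config A [structure_config()].
#' @return Tibble with one row per successfully processed genome; attribute
#'   `failures` is a tibble of (input, error message) pairs.
#' @export
run_structure_report <- function(genomes, config = structure_config()) {
  if (length(genomes) == 0L)
    ps_abort("no input genomes", "ps_usage_error")
  rows <- list(); fails <- list()
  for (i in seq_along(genomes)) {
    gx <- genomes[[i]]
    label <- if (is.character(gx)) gx else gx$identifier
    res <- tryCatch(structure_report_row(gx, config), error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- tibble::tibble(
        input = label, error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- dplyr::bind_rows(fails) %||%
    tibble::tibble(input = character(), error = character())
  if (!is.null(config$out_dir)) write_report_outputs(out, config)
  out
}

structure_report_row <- function(gx, config) {
  p <- if (is.character(gx)) read_genbank(gx) else gx
  part <- detect_inverted_repeat(p, min_ir_length = config$min_ir_length)
  rs <- region_stats(p, part)
  census <- count_genes(p)
  prof <- locate_junctions(p, part)
  jl <- stats::setNames(prof$class, prof$junction)
  screens <- character(0)
  for (sp in config$spacers) {
    key <- paste(normalize_gene_name(sp[1]), normalize_gene_name(sp[2]),
                 sep = "-")
    base <- if (!is.null(config$baselines) && key %in% names(config$baselines))
      config$baselines[[key]] else NA_real_
    scr <- tryCatch({
      if (is.na(base)) {
        can <- canonicalize_plastome(p, part)
        inst <- find_spacer_instances(can, sp[1], sp[2])
        sprintf("%s:len=%d", key, as.integer(inst$len[1L]))
      } else {
        rep_ <- screen_spacer_insertion(p, sp, baseline = base,
                                        partition = part,
                                        min_excess = config$min_excess)
        sprintf("%s:len=%d;insertion=%s", key, rep_$observed_length,
                ifelse(rep_$insertion_present, "yes", "no"))
      }
    }, error = function(e) sprintf("%s:error", key))
    screens <- c(screens, scr)
  }
  tibble::tibble(
    identifier = p$identifier,
    size = p$length,
    lsc_length = part$lsc_length, ssc_length = part$ssc_length,
    ir_length = part$ir_length,
    gc_overall = rs$gc[rs$region == "overall"],
    total_genes = census$total_genes, protein = census$protein,
    protein_pseudo = census$protein_pseudo, trna = census$trna,
    rrna = census$rrna,
    j_lb = unname(jl["J_LB"]), j_sb = unname(jl["J_SB"]),
    j_sa = unname(jl["J_SA"]), j_la = unname(jl["J_LA"]),
    spacer_screens = paste(screens, collapse = " | ")
  )
}

write_report_outputs <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report, file.path(config$out_dir, "structure_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fails <- attr(report, "failures")
  if (!is.null(fails) && nrow(fails) > 0L)
    utils::write.table(fails, file.path(config$out_dir, "failures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(
    package = "plastshift",
    version = as.character(utils::packageVersion("plastshift")),
    r_version = as.character(getRversion()),
    parameters = list(min_ir_length = config$min_ir_length,
                      min_excess = config$min_excess,
                      spacers = lapply(config$spacers, paste, collapse = "-")),
    seed = config$seed)
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
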