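# File I/O: FASTA/FASTQ via Biostrings, design JSON, TSV sheets, run config.

#' Read a locus from a single-record FASTA file
#'
#' Lowercase sequence is uppercased (with a message); ambiguity codes are
#' rejected; multi-record files are an error directing the user to extract
#' one record.
#'
#' @param path FASTA file.
#' @return A [locus()].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)  # preserves case for the check below
  if (length(ss) != 1L) {
    stop_pegkit(sprintf(
      "locus FASTA '%s' has %d records; extract the single target locus first",
      path, length(ss)), "pegkit_validation_error")
  }
  raw <- as.character(ss[[1]])
  if (grepl("[acgt]", raw)) message("lowercase bases uppercased on load")
  nm <- sub("\\s.*$", "", names(ss)[1])
  locus(nm, raw, origin_note = paste0("loaded from ", path))
}

#' Write a locus to FASTA
#' @param locus A [locus()].
#' @param path Output file.
#' @export
write_fasta <- function(locus, path) {
  ss <- Biostrings::DNAStringSet(locus$sequence)
  names(ss) <- locus$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write reads as FASTQ with uniform quality
#' @param reads Named character vector of sequences.
#' @param path Output file.
#' @param quality Single quality character applied to every base.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  ss <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(quality, n), ""))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read FASTQ into a named character vector (qualities ignored)
#' @param path FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a data.frame as TSV with fixed column order
#' @param df data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

site_to_list <- function(site) unclass(site)
site_from_list <- function(x) {
  new_site(x$strand, x$spacer_start, x$spacer_seq, x$pam_seq, x$nick_pos)
}

#' Serialise a design bundle to JSON
#'
#' The JSON carries the locus, edit, site and pegRNA fields so that
#' simulation and classification can run from the file alone;
#' [read_design_json()] restores an identical [pe_design()].
#'
#' @param design A [pe_design()].
#' @param path Output JSON file.
#' @export
write_design_json <- function(design, path) {
  peg <- design$pegrna
  obj <- list(
    locus = list(name = design$locus$name, sequence = design$locus$sequence,
                 origin_note = design$locus$origin_note),
    edit = unclass(design$edit),
    site = site_to_list(design$site),
    pegrna = list(pbs_len = peg$pbs_len, pbs_seq = peg$pbs_seq,
                  rt_len = peg$rt_len, rt_seq = peg$rt_seq,
                  rt_homology_len = peg$rt_homology_len,
                  rt_edit_span = peg$rt_edit_span,
                  extension_seq = peg$extension_seq,
                  spacer_oligo_seq = peg$spacer_oligo_seq,
                  g_prepended = peg$g_prepended,
                  nick_to_edit = peg$nick_to_edit))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a design bundle from JSON
#' @param path JSON file from [write_design_json()].
#' @return A [pe_design()].
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loc <- locus(obj$locus$name, obj$locus$sequence,
               obj$locus$origin_note %||% "")
  ed <- edit_spec(obj$edit$kind, obj$edit$start,
                  ref = obj$edit$ref %||% "", alt = obj$edit$alt %||% "")
  site <- site_from_list(obj$site)
  peg <- structure(c(list(site = site), obj$pegrna), class = "pegrna")
  peg$pbs_len <- as.integer(peg$pbs_len)
  peg$rt_len <- as.integer(peg$rt_len)
  peg$rt_homology_len <- as.integer(peg$rt_homology_len)
  peg$rt_edit_span <- as.integer(peg$rt_edit_span)
  pe_design(loc, ed, peg)
}

#' Write an outcome report as JSON
#' @param report An `outcome_report` from [summarize_calls()].
#' @param path Output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration
#'
#' Central configuration with the package defaults; values can come from a
#' YAML file and/or a list of overrides. Unknown keys are rejected.
#'
#' @param path Optional YAML file.
#' @param overrides Named list overriding file/defaults.
#' @return List of class `run_config` with the fully resolved configuration.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    adapter_table = NULL,        # path; NULL = shipped defaults
    scaffold = SP_CAS9_SCAFFOLD,
    t7_promoter = T7_PROMOTER,
    sham_guide = SHAM_GUIDE,
    pbs_len = 13L,
    rt_homology_len = 13L,
    max_nick_to_edit = 30L,
    second_nick_window = c(-120L, 120L),
    second_nick_exclude = c(-10L, 10L),
    ptd_min_match = 3L,
    max_mm_window = 2L,
    anneal_len = 20L,
    scaffold_head_len = 15L,
    min_read_len = NULL,
    log_level = "info",
    seed = 1L)
  cfg <- defaults
  apply_keys <- function(cfg, vals, origin) {
    unknown <- setdiff(names(vals), names(defaults))
    if (length(unknown)) {
      stop_pegkit(sprintf("unknown config key(s) from %s: %s", origin,
                          paste(unknown, collapse = ", ")),
                  "pegkit_config_error")
    }
    utils::modifyList(cfg, vals)
  }
  if (!is.null(path)) cfg <- apply_keys(cfg, yaml::read_yaml(path), path)
  cfg <- apply_keys(cfg, overrides, "overrides")
  structure(cfg, class = "run_config")
}
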