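# Core model: loci, edit specifications, and nick-relative edit nomenclature.
#
# Conventions used throughout the package:
#   * internal coordinates are 0-based, half-open, on the given ("top") strand;
#   * human-facing reports are 1-based closed;
#   * nick-relative labels ("+1 CTT ins") count on the PAM strand, +1 being the
#     first base 3' of the nick.

#' Create a reference locus
#'
#' A locus is a named reference sequence (the amplicon or surrounding genomic
#' context of a prime-editing target). The sequence is uppercased on input and
#' restricted to the ACGT alphabet; ambiguity codes are rejected.
#'
#' @param name Identifier for the locus.
#' @param sequence DNA string over A/C/G/T (lowercase accepted, uppercased).
#' @param origin_note Free-text provenance note.
#' @return An object of class `locus` with fields `name`, `sequence`,
#'   `origin_note`.
#' @examples
#' loc <- locus("toy", "GACCTTAACGGATGCAAGTCAGG")
#' @export
locus <- function(name, sequence, origin_note = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- toupper(sequence)
  assert_dna(sequence, sprintf("locus '%s' sequence", name))
  structure(list(name = name, sequence = sequence, origin_note = origin_note),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s (%d bp)\n", x$name, nchar(x$sequence)))
  s <- x$sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
  invisible(x)
}

locus_length <- function(locus) nchar(locus$sequence)

#' Specify an intended edit
#'
#' Describes a substitution, insertion or deletion in top-strand coordinates.
#' Substitutions are equal-length ref/alt replacements; an insertion has an
#' empty `ref` (alt inserted before `start`); a deletion has an empty `alt`.
#'
#' @param kind One of `"substitution"`, `"insertion"`, `"deletion"`.
#' @param start 0-based top-strand position of the first affected base (for an
#'   insertion, the position the new bases are inserted before).
#' @param ref Reference allele (empty for insertion).
#' @param alt Alternate allele (empty for deletion).
#' @return An object of class `edit_spec`.
#' @examples
#' edit_spec("insertion", 5, alt = "CTT")
#' edit_spec("substitution", 9, ref = "G", alt = "C")
#' @export
edit_spec <- function(kind = c("substitution", "insertion", "deletion"),
                      start, ref = "", alt = "") {
  kind <- match.arg(kind)
  start <- assert_scalar_int(start, "start", min = 0)
  ref <- toupper(ref); alt <- toupper(alt)
  assert_dna(ref, "ref_allele", allow_empty = TRUE)
  assert_dna(alt, "alt_allele", allow_empty = TRUE)
  ok <- switch(kind,
    substitution = nchar(ref) > 0 && nchar(ref) == nchar(alt),
    insertion    = nchar(ref) == 0 && nchar(alt) > 0,
    deletion     = nchar(ref) > 0 && nchar(alt) == 0)
  if (!ok) {
    stop_pegkit(sprintf(
      "inconsistent alleles for %s: ref='%s', alt='%s'", kind, ref, alt),
      "pegkit_validation_error")
  }
  structure(list(kind = kind, start = start, ref = ref, alt = alt),
            class = "edit_spec")
}

#' @export
print.edit_spec <- function(x, ...) {
  cat(sprintf("<edit_spec> %s at %d (1-based %d): '%s' -> '%s'\n",
              x$kind, x$start, x$start + 1L, x$ref, x$alt))
  invisible(x)
}

#' Validate an edit against a locus
#'
#' Checks that the reference allele of a substitution or deletion matches the
#' locus sequence at the stated position and that the edit lies within bounds.
#'
#' @param locus A [locus()].
#' @param edit An [edit_spec()].
#' @return Invisibly `TRUE`; errors (class `pegkit_allele_mismatch` or
#'   `pegkit_bounds_error`) otherwise.
#' @export
validate_edit <- function(locus, edit) {
  L <- locus_length(locus)
  end <- edit$start + nchar(edit$ref)
  if (edit$start > L || end > L) {
    stop_pegkit(sprintf("edit [%d, %d) outside locus '%s' (length %d)",
                        edit$start, end, locus$name, L), "pegkit_bounds_error")
  }
  if (nchar(edit$ref) > 0) {
    have <- substr0(locus$sequence, edit$start, end)
    if (have != edit$ref) {
      stop_pegkit(sprintf(
        "ref allele mismatch at position %d (1-based %d) of '%s': expected '%s', locus has '%s'",
        edit$start, edit$start + 1L, locus$name, edit$ref, have),
        "pegkit_allele_mismatch")
    }
  }
  invisible(TRUE)
}

#' Apply an edit to a locus
#'
#' Pure function returning the edited top-strand sequence; the length changes
#' by `nchar(alt) - nchar(ref)`.
#'
#' @inheritParams validate_edit
#' @return DNA string (character scalar).
#' @examples
#' apply_edit(locus("x", "ACGT"), edit_spec("substitution", 1, "C", "G"))
#' @export
apply_edit <- function(locus, edit) {
  validate_edit(locus, edit)
  s <- locus$sequence
  paste0(substr0(s, 0L, edit$start), edit$alt,
         substr0(s, edit$start + nchar(edit$ref), nchar(s)))
}

# ---- PAM-strand view -------------------------------------------------------
# All pegRNA arithmetic happens on the PAM strand: the strand carrying the
# protospacer 5'->3'. For a minus-strand site this is the reverse complement
# of the top strand. `npam` is the nick as a cut point in PAM-strand
# coordinates (cut between PAM indices npam-1 and npam, 0-based).

pam_view <- function(locus, site) {
  L <- locus_length(locus)
  if (site$strand == "+") {
    list(seq = locus$sequence, npam = site$nick_pos, L = L)
  } else {
    list(seq = dna_revcomp(locus$sequence), npam = L - site$nick_pos, L = L)
  }
}

# Convert a top-strand edit to PAM-strand orientation for a given site.
# Returns start (0-based PAM coord of first affected base / insertion point),
# ref and alt written on the PAM strand.
edit_to_pam <- function(locus, edit, site) {
  if (site$strand == "+") {
    list(start = edit$start, ref = edit$ref, alt = edit$alt)
  } else {
    L <- locus_length(locus)
    span <- nchar(edit$ref)
    start <- if (edit$kind == "insertion") L - edit$start else L - (edit$start + span)
    list(start = start, ref = dna_revcomp(edit$ref), alt = dna_revcomp(edit$alt))
  }
}

# Nick-relative offsets of an edit for a site. +1 = first base 3' of the nick
# on the PAM strand. Returns list(start_offset, end_offset, from, to).
edit_offsets <- function(locus, edit, site) {
  pv <- pam_view(locus, site)
  ep <- edit_to_pam(locus, edit, site)
  start_offset <- ep$start - pv$npam + 1L
  span <- if (edit$kind == "insertion") nchar(ep$alt) else nchar(ep$ref)
  list(start_offset = start_offset,
       end_offset = start_offset + span - 1L,
       from = ep$ref, to = ep$alt)
}

#' Nick-relative label for an edit
#'
#' Renders an edit in the nick-relative nomenclature used for prime-editing
#' experiments: insertions as `"+k SEQ ins"`, deletions as `"+a-b SEQ del"`
#' (en dash; single-base `"+k X del"`), substitutions as `"+k X to Y"` or
#' `"+a-b XYZ to ABC"`. Offsets count on the PAM strand, `+1` being the first
#' base 3' of the nick; alleles are reported in PAM-strand orientation.
#'
#' @param edit An [edit_spec()] (top-strand).
#' @param site A protospacer site (see [scan_pam_sites()]).
#' @param locus The [locus()] both refer to.
#' @return An object of class `nick_label`; `as.character()`/`format()` give
#'   the printed label.
#' @seealso [parse_label()] for the inverse.
#' @export
label_edit <- function(edit, site, locus) {
  validate_edit(locus, edit)
  off <- edit_offsets(locus, edit, site)
  if (off$start_offset < 1L) {
    stop_pegkit(sprintf(
      "edit lies 5' of the nick on the PAM strand (offset %d); prime editing cannot write upstream of the nick",
      off$start_offset), "pegkit_unreachable_edit")
  }
  structure(list(start_offset = off$start_offset, end_offset = off$end_offset,
                 kind = edit$kind, from_seq = off$from, to_seq = off$to),
            class = "nick_label")
}

#' @export
format.nick_label <- function(x, ...) {
  dash <- "\u2013"
  rng <- if (x$end_offset > x$start_offset) {
    paste0("+", x$start_offset, dash, x$end_offset)
  } else {
    paste0("+", x$start_offset)
  }
  switch(x$kind,
    insertion    = paste0("+", x$start_offset, " ", x$to_seq, " ins"),
    deletion     = paste0(rng, " ", x$from_seq, " del"),
    substitution = paste0(rng, " ", x$from_seq, " to ", x$to_seq))
}

#' @export
as.character.nick_label <- function(x, ...) format(x)

#' @export
print.nick_label <- function(x, ...) {
  cat("<nick_label>", format(x), "\n")
  invisible(x)
}

#' Parse a nick-relative label into an edit
#'
#' Inverse of [label_edit()]: turns a label such as `"+1 CTT ins"`,
#' `"+1-3 CTT del"` or `"+6 G to A"` into a top-strand [edit_spec()] for the
#' given site. Hyphen, en dash and em dash are accepted as the range
#' separator. For deletions and substitutions the `from` allele is checked
#' against the locus.
#'
#' @param text Label string.
#' @inheritParams label_edit
#' @return An [edit_spec()].
#' @export
parse_label <- function(text, site, locus) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  dash <- "(?:-|\u2013|\u2014)"
  m_ins <- regexec("^\\+([0-9]+) ([ACGTacgt]+) ins$", txt)
  m_del <- regexec(paste0("^\\+([0-9]+)(?:", dash, "([0-9]+))? ([ACGTacgt]+) del$"), txt)
  m_sub <- regexec(paste0("^\\+([0-9]+)(?:", dash, "([0-9]+))? ([ACGTacgt]+) to ([ACGTacgt]+)$"), txt)
  pv <- pam_view(locus, site)
  L <- pv$L

  from_pam <- function(pstart, ref_pam, alt_pam, kind) {
    # map a PAM-strand edit back to top-strand coordinates
    if (site$strand == "+") {
      e <- edit_spec(kind, pstart, ref = ref_pam, alt = alt_pam)
    } else {
      span <- nchar(ref_pam)
      start <- if (kind == "insertion") L - pstart else L - (pstart + span)
      e <- edit_spec(kind, start, ref = dna_revcomp(ref_pam), alt = dna_revcomp(alt_pam))
    }
    validate_edit(locus, e)
    e
  }

  g <- regmatches(txt, m_ins)[[1]]
  if (length(g)) {
    k <- as.integer(g[2])
    return(from_pam(pv$npam + k - 1L, "", toupper(g[3]), "insertion"))
  }
  g <- regmatches(txt, m_del)[[1]]
  if (length(g)) {
    k <- as.integer(g[2]); seq <- toupper(g[4])
    b <- if (nzchar(g[3])) as.integer(g[3]) else k + nchar(seq) - 1L
    if (b - k + 1L != nchar(seq)) {
      stop_pegkit(sprintf("range +%d\u2013%d does not match allele length %d in '%s'",
                          k, b, nchar(seq), txt), "pegkit_parse_error")
    }
    return(from_pam(pv$npam + k - 1L, seq, "", "deletion"))
  }
  g <- regmatches(txt, m_sub)[[1]]
  if (length(g)) {
    k <- as.integer(g[2]); from <- toupper(g[4]); to <- toupper(g[5])
    b <- if (nzchar(g[3])) as.integer(g[3]) else k + nchar(from) - 1L
    if (b - k + 1L != nchar(from) || nchar(from) != nchar(to)) {
      stop_pegkit(sprintf("range/allele lengths disagree in '%s'", txt),
                  "pegkit_parse_error")
    }
    return(from_pam(pv$npam + k - 1L, from, to, "substitution"))
  }
  stop_pegkit(paste0(
    "cannot parse label '", txt, "'; expected one of: '+k SEQ ins', ",
    "'+a\u2013b SEQ del', '+k X to Y' / '+a\u2013b XYZ to ABC'"),
    "pegkit_parse_error")
}
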