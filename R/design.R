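# Design engine: protospacer discovery, pegRNA construction, second-nick
# selection, golden-gate oligo and T7 IVT primer emission.

#' Canonical T7 promoter used for IVT primer design
#' @export
T7_PROMOTER <- "TAATACGACTCACTATAG"

#' SpCas9 sgRNA scaffold (invariant region between spacer and 3' extension)
#' @export
SP_CAS9_SCAFFOLD <- paste0(
  "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGG",
  "CACCGAGTCGGTGC")

#' Default sham (non-targeting) guide for nuclease construct kits
#'
#' Fills the second-guide cassette of nuclease constructs, which take a
#' double-strand break from the pegRNA guide alone and must not receive a
#' genomic second nick. The default is a commonly used non-targeting control
#' spacer; verifying absence from any particular genome is the user's
#' responsibility and can be overridden in the run configuration.
#' @export
SHAM_GUIDE <- "GCACTACCAGAGCTAACTCA"

new_site <- function(strand, spacer_start, spacer_seq, pam_seq, nick_pos) {
  structure(list(strand = strand, spacer_start = as.integer(spacer_start),
                 spacer_seq = spacer_seq, pam_seq = pam_seq,
                 nick_pos = as.integer(nick_pos)),
            class = "protospacer_site")
}

#' @export
print.protospacer_site <- function(x, ...) {
  cat(sprintf("<protospacer_site> %s strand, spacer %s, PAM %s, spacer_start %d, nick %d\n",
              x$strand, x$spacer_seq, x$pam_seq, x$spacer_start, x$nick_pos))
  invisible(x)
}

#' Tabulate protospacer sites
#'
#' @param sites List of protospacer sites as returned by [scan_pam_sites()].
#' @return A data.frame with one row per site.
#' @export
sites_table <- function(sites) {
  data.frame(
    strand = vapply(sites, `[[`, "", "strand"),
    spacer_start = vapply(sites, `[[`, 0L, "spacer_start"),
    spacer_seq = vapply(sites, `[[`, "", "spacer_seq"),
    pam_seq = vapply(sites, `[[`, "", "pam_seq"),
    nick_pos = vapply(sites, `[[`, 0L, "nick_pos"),
    stringsAsFactors = FALSE)
}

#' Enumerate SpCas9 protospacers (20-nt spacer + NGG PAM)
#'
#' Scans both strands of a locus for 20-nt spacers followed by an NGG PAM.
#' The nick is placed between protospacer positions 17 and 18 on the PAM
#' strand (3 nt 5' of the PAM), the standard SpCas9 cut geometry; `nick_pos`
#' reports it as a cut between top-strand indices `nick_pos - 1` and
#' `nick_pos`. Output order is deterministic: top-strand sites 5'->3', then
#' bottom-strand sites by top-strand coordinate.
#'
#' @param locus A [locus()].
#' @param window Optional 0-based half-open interval `c(from, to)` the PAM
#'   must lie within; default is the whole locus.
#' @return List of `protospacer_site` objects (possibly empty).
#' @export
scan_pam_sites <- function(locus, window = NULL) {
  s <- locus$sequence
  L <- nchar(s)
  window <- window %||% c(0L, L)
  if (length(window) != 2L || window[1] < 0 || window[2] > L || window[1] > window[2]) {
    stop_pegkit("window must be a 0-based half-open interval inside the locus",
                "pegkit_bounds_error")
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  sites <- list()
  # + strand: PAM at 0-based q..q+2 with ch[q+2]==G, ch[q+3]==G (1-based idx)
  if (L >= 23) {
    q <- which(ch == "G")  # 1-based positions of G
    gg <- q[(q + 1L) %in% q]            # start of "GG" (1-based)
    pam0 <- gg - 2L                     # 0-based PAM start (N of NGG)
    keep <- pam0 >= 20L & pam0 + 3L <= L & pam0 >= window[1] & pam0 + 3L <= window[2]
    for (p in sort(pam0[keep])) {
      st <- p - 20L
      sites[[length(sites) + 1L]] <- new_site(
        "+", st, substr0(s, st, st + 20L), substr0(s, p, p + 3L), st + 17L)
    }
    # - strand: top-strand CCN at c..c+2, spacer at [c+3, c+23)
    q <- which(ch == "C")
    cc <- q[(q + 1L) %in% q]
    c0 <- cc - 1L                       # 0-based start of "CC" = PAM start
    keep <- c0 + 23L <= L & c0 >= window[1] & c0 + 3L <= window[2]
    for (p in sort(c0[keep])) {
      st <- p + 3L
      sites[[length(sites) + 1L]] <- new_site(
        "-", st, dna_revcomp(substr0(s, st, st + 20L)),
        dna_revcomp(substr0(s, p, p + 3L)), st + 3L)
    }
  }
  sites
}

#' Rank protospacers that can install a given edit
#'
#' Keeps sites whose nick lies 5' of the whole edit on the PAM strand (so the
#' reverse-transcribed flap can write it) and within `max_nick_to_edit` nt,
#' ranked by ascending nick-to-edit distance; ties broken by + strand first,
#' then lower top-strand coordinate. When no site qualifies the returned list
#' is empty and carries a `rejected` attribute tabulating the nearest
#' rejected sites with reasons.
#'
#' @inheritParams validate_edit
#' @param max_nick_to_edit Maximum allowed nick-relative offset of the edit's
#'   last affected base (default 30 nt).
#' @return List of `protospacer_site`, best first; attribute `rejected` holds
#'   a diagnostic data.frame.
#' @export
candidate_pegrna_sites <- function(locus, edit, max_nick_to_edit = 30L) {
  validate_edit(locus, edit)
  sites <- scan_pam_sites(locus)
  keep <- list(); dist <- integer(); strand <- character(); coord <- integer()
  rej <- data.frame(strand = character(), spacer_start = integer(),
                    start_offset = integer(), reason = character(),
                    stringsAsFactors = FALSE)
  for (st in sites) {
    off <- edit_offsets(locus, edit, st)
    if (off$start_offset < 1L) {
      rej <- rbind(rej, data.frame(strand = st$strand, spacer_start = st$spacer_start,
                                   start_offset = off$start_offset,
                                   reason = "edit 5' of nick", stringsAsFactors = FALSE))
    } else if (off$end_offset > max_nick_to_edit) {
      rej <- rbind(rej, data.frame(strand = st$strand, spacer_start = st$spacer_start,
                                   start_offset = off$start_offset,
                                   reason = "beyond max_nick_to_edit", stringsAsFactors = FALSE))
    } else {
      keep[[length(keep) + 1L]] <- st
      dist <- c(dist, off$start_offset)
      strand <- c(strand, st$strand)
      coord <- c(coord, st$spacer_start)
    }
  }
  if (length(keep)) {
    ord <- order(dist, strand != "+", coord)
    keep <- keep[ord]
  }
  if (nrow(rej)) rej <- rej[order(abs(rej$start_offset)), , drop = FALSE]
  attr(keep, "rejected") <- rej
  keep
}

g_prepend <- function(spacer) {
  if (startsWith(spacer, "G")) list(seq = spacer, prepended = FALSE)
  else list(seq = paste0("G", spacer), prepended = TRUE)
}

#' Build a pegRNA for an edit at a chosen protospacer
#'
#' Constructs the primer binding site (PBS: genomic PAM-strand bases
#' immediately 5' of the nick), the RT template (edited PAM-strand bases from
#' the nick through the edit plus `rt_homology_len` nt of downstream
#' homology), and the 3' extension appended to the sgRNA scaffold
#' (`revcomp(rt_seq)` then `revcomp(pbs_seq)`). The spacer for cloning/IVT
#' gets a G prepended when it does not already start with one.
#'
#' @inheritParams validate_edit
#' @param site `protospacer_site` the pegRNA nicks at.
#' @param pbs_len PBS length in nt (default 13; 8-17 recommended, >= 3
#'   enforced).
#' @param rt_homology_len Downstream homology carried by the RT template
#'   beyond the edit, in nt (default 13, >= 1).
#' @return Object of class `pegrna` with fields `site`, `pbs_len`, `pbs_seq`,
#'   `rt_len`, `rt_seq`, `rt_homology_len`, `rt_edit_span`, `extension_seq`,
#'   `spacer_oligo_seq`, `g_prepended`, `nick_to_edit`.
#' @examples
#' loc <- locus("toy", "GACCTTAACGGATGCAAGTCAGGTCAGGA")
#' site <- scan_pam_sites(loc)[[1]]
#' pe <- build_pegrna(loc, parse_label("+1 T ins", site, loc), site,
#'                    pbs_len = 4, rt_homology_len = 5)
#' pe$extension_seq  # "CTGACATTGC"
#' @export
build_pegrna <- function(locus, edit, site, pbs_len = 13L, rt_homology_len = 13L) {
  validate_edit(locus, edit)
  pbs_len <- assert_scalar_int(pbs_len, "pbs_len", min = 3)
  rt_homology_len <- assert_scalar_int(rt_homology_len, "rt_homology_len", min = 1)
  pv <- pam_view(locus, site)
  off <- edit_offsets(locus, edit, site)
  if (off$start_offset < 1L) {
    stop_pegkit(sprintf("edit not reachable from this site (offset %d)",
                        off$start_offset), "pegkit_unreachable_edit")
  }
  if (pv$npam - pbs_len < 0L) {
    stop_pegkit(sprintf("PBS window [%d, %d) extends past the locus start",
                        pv$npam - pbs_len, pv$npam), "pegkit_bounds_error")
  }
  ep <- edit_to_pam(locus, edit, site)
  edited_pam <- paste0(substr0(pv$seq, 0L, ep$start), ep$alt,
                       substr0(pv$seq, ep$start + nchar(ep$ref), pv$L))
  edit_span <- (off$start_offset - 1L) + nchar(ep$alt)  # edited bases from nick
  rt_len <- edit_span + rt_homology_len
  if (pv$npam + rt_len > nchar(edited_pam)) {
    stop_pegkit(sprintf(
      "RT template window would be truncated: needs %d nt past the nick, locus offers %d",
      rt_len, nchar(edited_pam) - pv$npam), "pegkit_truncation_error")
  }
  pbs_seq <- substr0(pv$seq, pv$npam - pbs_len, pv$npam)
  rt_seq <- substr0(edited_pam, pv$npam, pv$npam + rt_len)
  gp <- g_prepend(site$spacer_seq)
  structure(list(
    site = site,
    pbs_len = pbs_len, pbs_seq = pbs_seq,
    rt_len = rt_len, rt_seq = rt_seq,
    rt_homology_len = rt_homology_len, rt_edit_span = edit_span,
    extension_seq = paste0(dna_revcomp(rt_seq), dna_revcomp(pbs_seq)),
    spacer_oligo_seq = gp$seq, g_prepended = gp$prepended,
    nick_to_edit = off$start_offset
  ), class = "pegrna")
}

#' @export
print.pegrna <- function(x, ...) {
  cat("<pegrna>\n")
  cat(sprintf("  spacer     %s (%s strand, G prepended: %s)\n",
              x$site$spacer_seq, x$site$strand, x$g_prepended))
  cat(sprintf("  PBS        %s (%d nt)\n", x$pbs_seq, x$pbs_len))
  cat(sprintf("  RT template %s (%d nt: %d edited + %d homology)\n",
              x$rt_seq, x$rt_len, x$rt_edit_span, x$rt_homology_len))
  cat(sprintf("  3' extension %s\n", x$extension_seq))
  invisible(x)
}

# cut point of a site in the coordinate frame of a reference strand
nick_cut_in_frame <- function(site, L, frame_strand) {
  if (frame_strand == "+") site$nick_pos else L - site$nick_pos
}

#' Select second-nick guides for PE3
#'
#' Finds opposite-strand protospacers whose nick-to-nick signed offset from
#' the pegRNA nick lies inside `offset_window` but outside `exclude_window`.
#' The sign convention follows the usual "+48"/"-60" style: positive when the
#' second nick falls 3' of the pegRNA nick on the pegRNA's PAM strand.
#' Results are sorted by `abs(offset)` (ties: positive first, then
#' coordinate).
#'
#' @param locus A [locus()].
#' @param pegrna A [build_pegrna()] result.
#' @param offset_window Signed closed interval of allowed offsets
#'   (default `c(-120, 120)`).
#' @param exclude_window Closed interval excluded around the pegRNA nick
#'   (default `c(-10, 10)`).
#' @return List of `second_nick` objects (`site`, `signed_offset`); may be
#'   empty.
#' @export
choose_second_nick <- function(locus, pegrna, offset_window = c(-120L, 120L),
                               exclude_window = c(-10L, 10L)) {
  peg_site <- pegrna$site
  L <- locus_length(locus)
  cut1 <- nick_cut_in_frame(peg_site, L, peg_site$strand)
  res <- list(); offs <- integer(); coord <- integer()
  for (st in scan_pam_sites(locus)) {
    if (st$strand == peg_site$strand) next
    off <- nick_cut_in_frame(st, L, peg_site$strand) - cut1
    if (off < offset_window[1] || off > offset_window[2]) next
    if (off >= exclude_window[1] && off <= exclude_window[2]) next
    res[[length(res) + 1L]] <- structure(
      list(site = st, signed_offset = as.integer(off)), class = "second_nick")
    offs <- c(offs, off); coord <- c(coord, st$spacer_start)
  }
  if (length(res)) res <- res[order(abs(offs), offs < 0, coord)]
  res
}

#' Assemble a construct plan
#'
#' Bundles everything needed to emit a cloning kit: the mode (`pe2`, `pe3`
#' with a genomic second nick, or `nuclease` with a sham guide filling the
#' second cassette), the pegRNA, and the adapter dialect.
#'
#' @param mode `"pe2"`, `"pe3"` or `"nuclease"`.
#' @param pegrna A [build_pegrna()] result.
#' @param second_nick A `second_nick` from [choose_second_nick()]; required
#'   for PE3, forbidden otherwise.
#' @param sham_guide Spacer filling the second cassette in nuclease mode.
#' @param dialect Adapter dialect, `"pea1"` or `"pu6"`.
#' @return Object of class `construct_plan`.
#' @export
construct_plan <- function(mode = c("pe3", "pe2", "nuclease"), pegrna,
                           second_nick = NULL, sham_guide = SHAM_GUIDE,
                           dialect = c("pea1", "pu6")) {
  mode <- match.arg(mode)
  dialect <- match.arg(dialect)
  if (mode == "pe3" && is.null(second_nick)) {
    stop_pegkit("PE3 requires a second-nick guide", "pegkit_validation_error")
  }
  if (mode != "pe3" && !is.null(second_nick)) {
    stop_pegkit(sprintf("%s mode must not carry a genomic second nick", mode),
                "pegkit_validation_error")
  }
  if (mode == "nuclease") assert_dna(sham_guide, "sham_guide")
  if (!is.null(second_nick) &&
      second_nick$site$strand == pegrna$site$strand) {
    stop_pegkit("second-nick guide must target the opposite strand",
                "pegkit_validation_error")
  }
  structure(list(mode = mode, pegrna = pegrna, second_nick = second_nick,
                 sham_guide = if (mode == "nuclease") sham_guide else NULL,
                 dialect = dialect),
            class = "construct_plan")
}

#' Load or fetch the golden-gate adapter table
#'
#' The table gives, per dialect and cloning slot (spacer, extension,
#' second_nick), the fixed 4-nt 5' overhangs added to the top and bottom
#' oligos for directional BbsI assembly. Defaults ship in
#' `inst/extdata/adapters.yaml` and can be replaced by any file with the same
#' structure; the table is validated only structurally (4-nt ACGT overhangs,
#' the three slots of one dialect mutually distinct).
#'
#' @param path YAML file; default the shipped table.
#' @return Nested list `dialect -> slot -> list(top_overhang, bottom_overhang)`.
#' @export
load_adapter_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "adapters.yaml", package = "pegkit")
  tab <- yaml::read_yaml(path)
  for (dialect in names(tab)) {
    slots <- tab[[dialect]]
    pairs <- character()
    for (slot in names(slots)) {
      ov <- slots[[slot]]
      for (side in c("top_overhang", "bottom_overhang")) {
        v <- ov[[side]]
        if (is.null(v) || !is_dna(v) || nchar(v) != 4L) {
          stop_pegkit(sprintf(
            "adapter table %s/%s: %s must be a 4-nt ACGT overhang", dialect, slot, side),
            "pegkit_config_error")
        }
      }
      pairs <- c(pairs, paste(ov$top_overhang, ov$bottom_overhang))
    }
    if (anyDuplicated(pairs)) {
      stop_pegkit(sprintf(
        "adapter table dialect '%s': overhang pairs must be mutually distinct for directional assembly",
        dialect), "pegkit_config_error")
    }
  }
  tab
}

#' Default adapter table for one dialect
#' @param dialect `"pea1"` or `"pu6"`.
#' @return `slot -> list(top_overhang, bottom_overhang)`.
#' @export
default_adapter_table <- function(dialect = c("pea1", "pu6")) {
  dialect <- match.arg(dialect)
  load_adapter_table()[[dialect]]
}

oligo_duplex <- function(slot, core, adapters) {
  ad <- adapters[[slot]]
  if (is.null(ad)) {
    stop_pegkit(sprintf("adapter table has no entry for slot '%s'", slot),
                "pegkit_config_error")
  }
  list(slot = slot,
       top_seq = paste0(ad$top_overhang, core),
       bottom_seq = paste0(ad$bottom_overhang, dna_revcomp(core)),
       top_overhang = ad$top_overhang,
       bottom_overhang = ad$bottom_overhang)
}

#' Emit the three golden-gate oligo duplexes for a construct
#'
#' One duplex per cloning slot: the (G-prepended) pegRNA protospacer, the 3'
#' extension (RT template + PBS), and the second cassette, which carries the
#' G-prepended second-nick protospacer for PE3 or the sham guide for nuclease
#' kits (PE2 kits reuse the sham filler so the cassette is never empty).
#' Stripping the two declared 4-nt 5' overhangs leaves exact reverse
#' complements. Emission is pure and deterministic.
#'
#' @param plan A [construct_plan()].
#' @param adapters Slot table as from [default_adapter_table()]; defaults to
#'   the plan's dialect.
#' @return data.frame with columns slot, top_seq, bottom_seq, top_overhang,
#'   bottom_overhang.
#' @export
emit_oligos <- function(plan, adapters = default_adapter_table(plan$dialect)) {
  peg <- plan$pegrna
  second_core <- switch(plan$mode,
    pe3 = g_prepend(plan$second_nick$site$spacer_seq)$seq,
    nuclease = g_prepend(plan$sham_guide)$seq,
    pe2 = g_prepend(SHAM_GUIDE)$seq)
  duplexes <- list(
    oligo_duplex("spacer", peg$spacer_oligo_seq, adapters),
    oligo_duplex("extension", peg$extension_seq, adapters),
    oligo_duplex("second_nick", second_core, adapters))
  do.call(rbind, lapply(duplexes, function(d)
    data.frame(d, stringsAsFactors = FALSE)))
}

#' T7 in vitro transcription primers for a pegRNA
#'
#' The forward primer is the T7 promoter followed by the (G-prepended) spacer
#' and the first `scaffold_head_len` nt of the scaffold; the reverse primer
#' is the reverse complement of the last `anneal_len` nt of
#' `scaffold + extension`, so it always covers the 3' end of the pegRNA. If
#' the extension is shorter than `anneal_len` the reverse primer extends into
#' the scaffold (a warning, not an error). Both primers are reported 5'->3'.
#'
#' @param pegrna A [build_pegrna()] result.
#' @param scaffold Scaffold sequence between spacer and extension.
#' @param anneal_len Reverse-primer annealing length (>= 15).
#' @param scaffold_head_len Scaffold bases appended to the forward primer.
#' @param t7_promoter T7 promoter constant.
#' @return List with `forward`, `reverse`, `t7_promoter`.
#' @export
emit_ivt_primers <- function(pegrna, scaffold = SP_CAS9_SCAFFOLD,
                             anneal_len = 20L, scaffold_head_len = 15L,
                             t7_promoter = T7_PROMOTER) {
  anneal_len <- assert_scalar_int(anneal_len, "anneal_len", min = 15)
  scaffold_head_len <- assert_scalar_int(scaffold_head_len, "scaffold_head_len",
                                         min = 1, max = nchar(scaffold))
  fwd <- paste0(t7_promoter, pegrna$spacer_oligo_seq,
                substr(scaffold, 1L, scaffold_head_len))
  tail_src <- paste0(scaffold, pegrna$extension_seq)
  if (nchar(pegrna$extension_seq) < anneal_len) {
    warn_pegkit(sprintf(
      "extension (%d nt) shorter than anneal_len (%d); reverse primer extends into the scaffold",
      nchar(pegrna$extension_seq), anneal_len), "pegkit_short_extension")
  }
  rev <- dna_revcomp(substr(tail_src, nchar(tail_src) - anneal_len + 1L, nchar(tail_src)))
  list(forward = fwd, reverse = rev, t7_promoter = t7_promoter)
}
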