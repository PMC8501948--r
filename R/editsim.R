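# Outcome simulation: ground-truth alleles (correct prime edit, partial
# template duplication, cut-site indels) and synthetic amplicon reads.

#' Reconstruct the edited allele from a pegRNA (flap resolution oracle)
#'
#' Rebuilds the expected edited sequence purely from the pegRNA fields,
#' mimicking correct flap resolution: the PAM-strand sequence up to the nick,
#' then the reverse-transcribed flap (the RT template read back as DNA), then
#' the genomic remainder located by matching the RT template's downstream
#' homology. Serves as the independent design oracle: for a well-formed
#' pegRNA the result equals [apply_edit()].
#'
#' @param locus A [locus()].
#' @param pegrna A [build_pegrna()] result for this locus.
#' @return Edited top-strand sequence (character scalar).
#' @export
simulate_flap <- function(locus, pegrna) {
  pv <- pam_view(locus, pegrna$site)
  genomic_pbs <- substr0(pv$seq, pv$npam - pegrna$pbs_len, pv$npam)
  if (genomic_pbs != pegrna$pbs_seq) {
    stop_pegkit(sprintf(
      "flap resolution failed: PBS '%s' does not match genomic bases 5' of the nick ('%s')",
      pegrna$pbs_seq, genomic_pbs), "pegkit_flap_error")
  }
  h <- pegrna$rt_homology_len
  hom <- substr(pegrna$rt_seq, pegrna$rt_len - h + 1L, pegrna$rt_len)
  downstream <- substr0(pv$seq, pv$npam, pv$L)
  hit <- regexpr(hom, downstream, fixed = TRUE)
  if (hit < 0) {
    stop_pegkit(sprintf(
      "flap resolution failed: RT homology '%s' not found downstream of the nick",
      hom), "pegkit_flap_error")
  }
  g_end <- pv$npam + (as.integer(hit) - 1L) + h  # 0-based end of genomic homology
  out_pam <- paste0(substr0(pv$seq, 0L, pv$npam), pegrna$rt_seq,
                    substr0(pv$seq, g_end, pv$L))
  if (pegrna$site$strand == "+") out_pam else dna_revcomp(out_pam)
}

new_allele <- function(label, sequence, ptd_dup_len = 0L, junction_del = 0L) {
  structure(list(label = label, sequence = sequence,
                 ptd_dup_len = as.integer(ptd_dup_len),
                 junction_del = as.integer(junction_del)),
            class = "allele_model")
}

#' Construct a partial template duplication (PTD) allele
#'
#' Models the end-joining resolution failure in which the reverse-transcribed
#' flap, instead of annealing to the downstream genomic homology, is joined
#' directly to the distal side of the break: the allele carries the intended
#' edit plus the first `dup_len` nt of the RT template's downstream homology
#' as an extra, template-derived insertion. `junction_del` genomic bases may
#' additionally be lost at the junction. With `junction_del = 0` the allele
#' is strictly longer than the correct allele.
#'
#' @inheritParams simulate_flap
#' @param edit The [edit_spec()] the pegRNA encodes.
#' @param dup_len Number of homology bases duplicated (1 to
#'   `rt_homology_len`).
#' @param junction_del Genomic bases lost at the end-joining junction (>= 0).
#' @return An `allele_model` with label `"PTD"`.
#' @export
make_ptd_allele <- function(locus, edit, pegrna, dup_len, junction_del = 0L) {
  dup_len <- assert_scalar_int(dup_len, "dup_len", min = 1,
                               max = pegrna$rt_homology_len)
  junction_del <- assert_scalar_int(junction_del, "junction_del", min = 0)
  pv <- pam_view(locus, pegrna$site)
  flap_prefix <- substr(pegrna$rt_seq, 1L, pegrna$rt_edit_span + dup_len)
  if (pv$npam + junction_del > pv$L) {
    stop_pegkit("junction_del runs past the end of the locus", "pegkit_bounds_error")
  }
  seq_pam <- paste0(substr0(pv$seq, 0L, pv$npam), flap_prefix,
                    substr0(pv$seq, pv$npam + junction_del, pv$L))
  seq_top <- if (pegrna$site$strand == "+") seq_pam else dna_revcomp(seq_pam)
  new_allele("PTD", seq_top, ptd_dup_len = dup_len, junction_del = junction_del)
}

#' Construct a cut-site indel allele
#'
#' Models the "other indel" outcome class: a deletion of `size` nt centred on
#' the nick, or an insertion of `size` random nt at the nick. Alleles that
#' equal the unmodified or correct sequence, or that contain any sequence in
#' `avoid` (e.g. the edit signature, so an accidental indel is never mistaken
#' for an intended edit), are resampled — insertions by redrawing bases,
#' deletions by jittering the deletion window.
#'
#' @inheritParams make_ptd_allele
#' @param site Protospacer site whose nick the indel is centred on.
#' @param size Indel size in nt (>= 1).
#' @param kind `"deletion"` or `"insertion"`.
#' @param avoid Character vector of sequences the allele must not contain
#'   (checked in both orientations).
#' @param forbid Character vector of full sequences the allele must not equal
#'   or closely resemble: an equal-length candidate within `near_mm`
#'   mismatches of a forbidden sequence is also resampled, so the indel class
#'   stays distinguishable from the intended outcome at classification
#'   tolerance.
#' @param near_mm Mismatch radius of the near-duplicate guard; the default
#'   matches the classifier's in-window mismatch allowance.
#' @param max_tries Resampling budget.
#' @return An `allele_model` with label `"indel"`. Uses the current RNG
#'   stream.
#' @export
make_indel_allele <- function(locus, site, size, kind = c("deletion", "insertion"),
                              avoid = character(), forbid = character(),
                              near_mm = 2L, max_tries = 50L) {
  kind <- match.arg(kind)
  size <- assert_scalar_int(size, "size", min = 1)
  pv <- pam_view(locus, site)
  if (size >= pv$L) {
    stop_pegkit("indel size must be smaller than the locus", "pegkit_bounds_error")
  }
  near_forbidden <- function(s, f) {
    nchar(s) == nchar(f) &&
      sum(utf8ToInt(s) != utf8ToInt(f)) <= near_mm
  }
  avoid_both <- unique(c(avoid, dna_revcomp(avoid)))
  bad <- function(s) {
    any(vapply(forbid, near_forbidden, logical(1), s = s)) ||
      any(vapply(avoid_both, grepl, logical(1), x = s, fixed = TRUE))
  }
  for (try in seq_len(max_tries)) {
    if (kind == "deletion") {
      jitter <- if (try == 1L) 0L else sample(-3L:3L, 1L)
      start <- max(0L, min(pv$L - size, pv$npam - size %/% 2L + jitter))
      seq_pam <- paste0(substr0(pv$seq, 0L, start),
                        substr0(pv$seq, start + size, pv$L))
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                   collapse = "")
      seq_pam <- paste0(substr0(pv$seq, 0L, pv$npam), ins,
                        substr0(pv$seq, pv$npam, pv$L))
    }
    seq_top <- if (site$strand == "+") seq_pam else dna_revcomp(seq_pam)
    if (!bad(seq_top)) return(new_allele("indel", seq_top))
  }
  stop_pegkit(sprintf(
    "could not draw a %s allele avoiding the given sequences in %d tries",
    kind, max_tries), "pegkit_validation_error")
}

#' Configuration for the read simulator
#'
#' @param fractions Named numeric over `correct`, `wt`, `ptd`, `indel`;
#'   must sum to 1 (tolerance 1e-9).
#' @param ptd_dup_range Closed integer range the PTD duplication length is
#'   drawn from, uniformly. Default `c(3, NA)`: from the classifier's
#'   detection threshold up to the full RT homology length (NA = use
#'   `rt_homology_len`).
#' @param junction_del_range Closed range for bases lost at the PTD junction
#'   (default none).
#' @param indel_size_range Closed range for cut-site indel sizes.
#' @param per_base_error Per-base substitution error probability.
#' @param n_reads Number of reads to draw.
#' @param seed Integer seed; all simulator randomness flows from it.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(fractions = c(correct = 0.4, wt = 0.3,
                                            ptd = 0.2, indel = 0.1),
                              ptd_dup_range = c(3L, NA),
                              junction_del_range = c(0L, 0L),
                              indel_size_range = c(1L, 3L),
                              per_base_error = 0.001,
                              n_reads = 1000L,
                              seed = 1L) {
  need <- c("correct", "wt", "ptd", "indel")
  if (!setequal(names(fractions), need)) {
    stop_pegkit("fractions must be named over {correct, wt, ptd, indel}",
                "pegkit_validation_error")
  }
  fractions <- fractions[need]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop_pegkit("fractions must be non-negative and sum to 1 (tolerance 1e-9)",
                "pegkit_validation_error")
  }
  if (per_base_error < 0 || per_base_error > 1) {
    stop_pegkit("per_base_error must be a probability", "pegkit_validation_error")
  }
  structure(list(fractions = fractions,
                 ptd_dup_range = ptd_dup_range,
                 junction_del_range = as.integer(junction_del_range),
                 indel_size_range = as.integer(indel_size_range),
                 per_base_error = per_base_error,
                 n_reads = assert_scalar_int(n_reads, "n_reads", min = 1),
                 seed = assert_scalar_int(seed, "seed")),
            class = "sim_config")
}

apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate amplicon reads from a mixture of editing outcomes
#'
#' Draws `n_reads` full-length amplicon reads from the configured mixture of
#' allele classes (correct prime edit, unmodified, PTD with variable
#' duplication length, cut-site indel), applies uniform substitution errors,
#' and returns the reads together with a per-read truth table. Deterministic
#' given `config$seed`.
#'
#' @inheritParams make_ptd_allele
#' @param config A [simulation_config()].
#' @return List with `reads` (named character vector, names are read ids) and
#'   `truth` (data.frame: read_id, label, ptd_dup_len, junction_del,
#'   indel_size, indel_kind).
#' @export
generate_reads <- function(locus, edit, pegrna, config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reads
  correct <- apply_edit(locus, edit)
  wt <- locus$sequence
  sig <- edit_signature(pegrna, locus, edit)
  dup_max <- config$ptd_dup_range[2]
  if (is.na(dup_max)) dup_max <- pegrna$rt_homology_len
  dup_min <- min(config$ptd_dup_range[1], dup_max)

  labels <- sample(names(config$fractions), n, replace = TRUE,
                   prob = config$fractions)
  seqs <- character(n)
  dup <- rep(NA_integer_, n); jdel <- rep(NA_integer_, n)
  isize <- rep(NA_integer_, n); ikind <- rep(NA_character_, n)
  ptd_cache <- list()
  for (i in seq_len(n)) {
    seqs[i] <- switch(labels[i],
      correct = correct,
      wt = wt,
      ptd = {
        dup[i] <- sample1(seq.int(dup_min, dup_max))
        jdel[i] <- sample1(seq.int(config$junction_del_range[1],
                                   config$junction_del_range[2]))
        key <- paste0(dup[i], "_", jdel[i])
        if (is.null(ptd_cache[[key]])) {
          ptd_cache[[key]] <- make_ptd_allele(locus, edit, pegrna,
                                              dup[i], jdel[i])$sequence
        }
        ptd_cache[[key]]
      },
      indel = {
        # a size/kind combination indistinguishable from the intended edit
        # (e.g. a 1-nt insertion when the edit is a 1-nt insertion) can
        # exhaust its resampling budget; redraw size and kind in that case
        al <- NULL
        for (try in 1:20) {
          isize[i] <- sample1(seq.int(config$indel_size_range[1],
                                      config$indel_size_range[2]))
          ikind[i] <- sample(c("deletion", "insertion"), 1L)
          al <- tryCatch(
            make_indel_allele(locus, pegrna$site, isize[i], ikind[i],
                              avoid = sig, forbid = c(wt, correct)),
            pegkit_error = function(e) NULL)
          if (!is.null(al)) break
        }
        if (is.null(al)) {
          stop_pegkit("could not draw a distinguishable indel allele",
                      "pegkit_validation_error")
        }
        al$sequence
      })
  }
  seqs <- apply_seq_errors(seqs, config$per_base_error)
  ids <- sprintf("read%06d", seq_len(n))
  names(seqs) <- ids
  list(reads = seqs,
       truth = data.frame(read_id = ids, label = labels,
                          ptd_dup_len = dup, junction_del = jdel,
                          indel_size = isize, indel_kind = ikind,
                          stringsAsFactors = FALSE))
}

# ---- synthetic study material ---------------------------------------------

#' Random locus generator
#'
#' Uniform-composition random DNA, used to build synthetic study loci for
#' property tests and the acceptance checks. Uses the current RNG stream.
#'
#' @param length Locus length in bp.
#' @param name Locus name.
#' @return A [locus()].
#' @export
random_locus <- function(length = 240L, name = "synthetic") {
  locus(name, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = ""), origin_note = "random synthetic locus")
}

#' Random reachable edit for a protospacer site
#'
#' Draws a substitution, insertion or deletion whose first affected base lies
#' at a nick-relative offset in `offset_range` (substitution alt differs from
#' ref at every base). Uses the current RNG stream.
#'
#' @param locus A [locus()].
#' @param site Target `protospacer_site`.
#' @param kind Edit kind; default random.
#' @param offset_range Range of nick-relative start offsets (>= 1).
#' @param size_range Range of edit sizes in nt.
#' @return An [edit_spec()].
#' @export
random_edit <- function(locus, site, kind = NULL,
                        offset_range = c(1L, 8L), size_range = c(1L, 3L)) {
  kind <- kind %||% sample(c("substitution", "insertion", "deletion"), 1L)
  pv <- pam_view(locus, site)
  k <- sample1(seq.int(offset_range[1], offset_range[2]))
  size <- sample1(seq.int(size_range[1], size_range[2]))
  pstart <- pv$npam + k - 1L
  bases <- c("A", "C", "G", "T")
  if (kind == "insertion") {
    alt <- paste(sample(bases, size, replace = TRUE), collapse = "")
    ref <- ""
  } else {
    if (pstart + size > pv$L) {
      stop_pegkit("edit window past locus end; choose a more central site",
                  "pegkit_bounds_error")
    }
    ref <- substr0(pv$seq, pstart, pstart + size)
    alt <- if (kind == "deletion") "" else {
      paste(vapply(strsplit(ref, "")[[1]],
                   function(b) sample(setdiff(bases, b), 1L), ""),
            collapse = "")
    }
  }
  if (site$strand == "+") {
    edit_spec(kind, pstart, ref = ref, alt = alt)
  } else {
    span <- nchar(ref)
    start <- if (kind == "insertion") pv$L - pstart else pv$L - (pstart + span)
    edit_spec(kind, start, ref = dna_revcomp(ref), alt = dna_revcomp(alt))
  }
}

#' Random complete design (locus, edit, site, pegRNA)
#'
#' Repeatedly draws a random locus, picks a protospacer with enough flanking
#' room, draws a reachable edit and builds the pegRNA; retries until a valid
#' design emerges. Uses the current RNG stream.
#'
#' @param locus_length Length of the random locus.
#' @param pbs_len,rt_homology_len Passed to [build_pegrna()].
#' @param max_tries Retry budget.
#' @return List with `locus`, `edit`, `site`, `pegrna`.
#' @export
random_design <- function(locus_length = 240L, pbs_len = 13L,
                          rt_homology_len = 13L, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    loc <- random_locus(locus_length)
    sites <- scan_pam_sites(loc)
    if (!length(sites)) next
    room <- vapply(sites, function(st) {
      pv <- pam_view(loc, st)
      pv$npam >= pbs_len + 5L && (pv$L - pv$npam) >= rt_homology_len + 20L
    }, logical(1))
    sites <- sites[room]
    if (!length(sites)) next
    st <- sites[[sample.int(length(sites), 1L)]]
    res <- tryCatch({
      ed <- random_edit(loc, st)
      peg <- build_pegrna(loc, ed, st, pbs_len, rt_homology_len)
      list(locus = loc, edit = ed, site = st, pegrna = peg)
    }, pegkit_error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  stop_pegkit("failed to draw a valid random design", "pegkit_validation_error")
}
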