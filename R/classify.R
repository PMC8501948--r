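# Outcome classification: align amplicon reads, detect the edit signature,
# assign reads to {WT, correct_PE, PTD, indel_other}, and compute the
# standard outcome percentages and their identities.

#' Alignment scoring scheme
#'
#' Affine global-alignment parameters used throughout classification. The
#' defaults (match +2, mismatch -4, gap open -10, gap extend -1) favour
#' compact indel placement near the nick.
#'
#' @param match,mismatch,gap_open,gap_extend Scores; gap penalties given as
#'   positive costs.
#' @return List of class `aln_scoring`.
#' @export
alignment_scoring <- function(match = 2, mismatch = -4, gap_open = 10,
                              gap_extend = 1) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "aln_scoring")
}

subst_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
}

# Convert one gapped pattern/subject string pair into an ops data.frame.
# ref_pos / read_pos are 0-based starts of each op; seq is the read-side
# sequence for ins/mismatch ops.
gapped_to_ops <- function(pat, sub) {
  p <- strsplit(pat, "", fixed = TRUE)[[1]]
  s <- strsplit(sub, "", fixed = TRUE)[[1]]
  op <- ifelse(p == "-", "del", ifelse(s == "-", "ins",
               ifelse(p == s, "match", "mismatch")))
  r <- rle(op)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ref_consumed <- cumsum(s != "-")   # subject bases consumed up to column
  read_consumed <- cumsum(p != "-")
  data.frame(
    op = r$values,
    ref_pos = ifelse(starts == 1L, 0L, ref_consumed[starts - 1L]),
    read_pos = ifelse(starts == 1L, 0L, read_consumed[starts - 1L]),
    length = r$lengths,
    seq = vapply(seq_along(r$values), function(i) {
      if (r$values[i] %in% c("ins", "mismatch"))
        paste(p[starts[i]:ends[i]], collapse = "") else ""
    }, ""),
    stringsAsFactors = FALSE)
}

#' Global alignment of a read against a reference
#'
#' Needleman-Wunsch global alignment with affine gaps (via Biostrings),
#' returned as a run-length list of operations with 0-based reference and
#' read coordinates. Deterministic for identical inputs.
#'
#' @param read,reference Non-empty DNA strings.
#' @param scoring An [alignment_scoring()].
#' @return List with `ops` (data.frame: op, ref_pos, read_pos, length, seq)
#'   and `score`.
#' @export
align_read <- function(read, reference, scoring = alignment_scoring()) {
  if (!nzchar(read) || !nzchar(reference)) {
    stop_pegkit("align_read requires non-empty read and reference",
                "pegkit_validation_error")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = subst_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  ops <- gapped_to_ops(as.character(Biostrings::pattern(al)),
                       as.character(Biostrings::subject(al)))
  list(ops = ops, score = Biostrings::score(al))
}

# batched version: one pairwiseAlignment call for many reads vs one subject
align_many <- function(reads, reference, scoring) {
  if (!length(reads)) return(list())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads), Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = subst_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pats <- as.character(Biostrings::pattern(al))
  subs <- as.character(Biostrings::subject(al))
  lapply(seq_along(reads), function(i)
    list(ops = gapped_to_ops(pats[i], subs[i]), score = Biostrings::score(al)[i]))
}

#' Edit signature used for intended-edit filtering
#'
#' The PAM-strand string whose presence in a read evidences a completed
#' intended edit: the last `flank` nt of the primer binding site followed by
#' the edited segment through the end of the alt allele. For deletion edits
#' (empty alt) the signature is extended by `del_anchor` nt of post-junction
#' homology so the new junction, not just the PBS, is matched. Reads are
#' searched for this string or its reverse complement.
#'
#' @param pegrna A [build_pegrna()] result.
#' @param locus,edit The locus and edit the pegRNA was built for.
#' @param flank PBS bases included (default: the full PBS).
#' @param del_anchor Downstream bases anchoring a deletion junction
#'   (default 3, the PTD match threshold).
#' @param min_len Minimum admissible signature length (guards against
#'   degenerate signatures such as a bare 1-nt substitution).
#' @return DNA string (PAM-strand orientation).
#' @export
edit_signature <- function(pegrna, locus, edit, flank = NULL, del_anchor = 3L,
                           min_len = 4L) {
  flank <- flank %||% pegrna$pbs_len
  flank <- assert_scalar_int(flank, "flank", min = 0, max = pegrna$pbs_len)
  span <- pegrna$rt_edit_span
  extra <- if (edit$kind == "deletion") {
    min(del_anchor, pegrna$rt_homology_len)
  } else 0L
  sig <- paste0(substr(pegrna$pbs_seq, pegrna$pbs_len - flank + 1L, pegrna$pbs_len),
                substr(pegrna$rt_seq, 1L, span + extra))
  if (nchar(sig) < min_len) {
    stop_pegkit(sprintf(
      "edit signature '%s' shorter than %d nt; increase flank", sig, min_len),
      "pegkit_validation_error")
  }
  sig
}

#' Classification parameters
#'
#' @param window Quantification window on the reference, 0-based half-open
#'   top-strand interval; default `[nick - pbs_len, nick + rt_len + 5]`
#'   (PAM-strand arithmetic converted to top strand). Variants outside the
#'   window are ignored.
#' @param ptd_min_match Minimum template-derived insertion match (m, nt) to
#'   call a PTD.
#' @param max_mm_window Substitution mismatches tolerated inside the window
#'   before a read stops looking like WT/correct (sequencing noise
#'   allowance).
#' @param sig_max_mm_ptd Mismatches tolerated when re-locating the signature
#'   for the PTD branch only (`has_signature` itself is exact-match).
#' @param min_read_len Reads shorter than this are filtered out before
#'   classification; default `min(50, 0.8 * amplicon length)`.
#' @param scoring An [alignment_scoring()].
#' @return List of class `classify_params`.
#' @export
classify_params <- function(window = NULL, ptd_min_match = 3L,
                            max_mm_window = 2L, sig_max_mm_ptd = 1L,
                            min_read_len = NULL,
                            scoring = alignment_scoring()) {
  structure(list(window = window, ptd_min_match = as.integer(ptd_min_match),
                 max_mm_window = as.integer(max_mm_window),
                 sig_max_mm_ptd = as.integer(sig_max_mm_ptd),
                 min_read_len = min_read_len, scoring = scoring),
            class = "classify_params")
}

#' Bundle a design for simulation/classification
#'
#' Packs the locus, edit, chosen site and pegRNA (plus optional construct
#' plan) into one object that the simulator, classifier and the design JSON
#' round-trip through.
#'
#' @inheritParams make_ptd_allele
#' @param plan Optional [construct_plan()].
#' @return Object of class `pe_design`.
#' @export
pe_design <- function(locus, edit, pegrna, plan = NULL) {
  validate_edit(locus, edit)
  structure(list(locus = locus, edit = edit, site = pegrna$site,
                 pegrna = pegrna, plan = plan),
            class = "pe_design")
}

# default quantification window in top-strand 0-based half-open coords
default_window <- function(design) {
  pv <- pam_view(design$locus, design$site)
  w_pam <- c(pv$npam - design$pegrna$pbs_len,
             min(pv$L, pv$npam + design$pegrna$rt_len + 5L))
  if (design$site$strand == "+") w_pam else c(pv$L - w_pam[2], pv$L - w_pam[1])
}

# mismatch positions (0-based) between equal-length strings; NULL if lengths
# differ
hamming_positions <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NULL)
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  which(av != bv) - 1L
}

count_in_window <- function(pos, w) sum(pos >= w[1] & pos < w[2])

# does an ops data.frame have an ins/del overlapping window w (ref coords)?
indel_in_window <- function(ops, w) {
  id <- ops[ops$op %in% c("ins", "del"), , drop = FALSE]
  if (!nrow(id)) return(FALSE)
  # an insertion occupies a ref cut point; a deletion a ref range
  any(ifelse(id$op == "ins",
             id$ref_pos >= w[1] & id$ref_pos <= w[2],
             id$ref_pos < w[2] & (id$ref_pos + id$length) > w[1]))
}

mismatch_positions_from_ops <- function(ops) {
  mm <- ops[ops$op == "mismatch", , drop = FALSE]
  if (!nrow(mm)) return(integer(0))
  unlist(lapply(seq_len(nrow(mm)), function(i)
    mm$ref_pos[i] + seq_len(mm$length[i]) - 1L))
}

# read bases aligned to reference columns [from, to) (0-based), given ops;
# returns NA if an indel intersects the range
read_bases_at <- function(read, ops, from, to) {
  # build per-ref-column read index incrementally from ops
  out <- character(0)
  for (i in seq_len(nrow(ops))) {
    o <- ops[i, ]
    if (o$op %in% c("match", "mismatch")) {
      cols <- o$ref_pos + seq_len(o$length) - 1L
      sel <- cols >= from & cols < to
      if (any(sel)) {
        rp <- o$read_pos + which(sel)
        out <- c(out, substring(read, rp, rp))
      }
    } else if (o$op == "del") {
      cols <- o$ref_pos + seq_len(o$length) - 1L
      if (any(cols >= from & cols < to)) return(NA_character_)
    } else if (o$op == "ins") {
      if (o$ref_pos > from && o$ref_pos < to) return(NA_character_)
    }
  }
  paste(out, collapse = "")
}

count_pattern_mm <- function(pattern, subject, max_mm) {
  Biostrings::countPattern(pattern, Biostrings::DNAString(subject),
                           max.mismatch = max_mm) > 0
}

all_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# orientation probes: three exact 12-mers from the reference
orient_probes <- function(reference) {
  L <- nchar(reference)
  k <- min(12L, L)
  starts <- unique(pmax(1L, c(1L, (L - k) %/% 2L + 1L, L - k + 1L)))
  substring(reference, starts, starts + k - 1L)
}

orient_score <- function(read, probes) {
  sum(vapply(probes, function(p) grepl(p, read, fixed = TRUE), logical(1)))
}

#' Classify amplicon reads into prime-editing outcome classes
#'
#' Assigns each read one label with a fixed precedence: (1) `WT` if the read
#' shows no variant inside the quantification window relative to the
#' reference (up to `max_mm_window` substitution mismatches, and for
#' substitution edits the alt allele must be absent); (2) `correct_PE` if the
#' read matches the correct edited allele the same way; (3) `PTD` if the read
#' carries the edit signature and its alignment to the correct allele shows
#' an insertion at the junction matching at least `ptd_min_match` nt of the
#' RT template; (4) `indel_other` otherwise. Variants outside the window are
#' ignored in every branch. Reads are orientation-normalised (both strands
#' searched) and reads shorter than `min_read_len` are filtered, with the
#' count reported in the `filtered` attribute.
#'
#' @param reads Named character vector of read sequences (names = read ids).
#' @param design A [pe_design()].
#' @param params A [classify_params()].
#' @return data.frame with columns read_id, label, has_signature,
#'   extra_ins_len, notes; attribute `filtered` = number of length-filtered
#'   reads.
#' @export
classify_reads <- function(reads, design, params = classify_params()) {
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  reference <- design$locus$sequence
  correct <- apply_edit(design$locus, design$edit)
  w <- params$window %||% default_window(design)
  ldiff <- nchar(correct) - nchar(reference)
  w_cor <- c(w[1], w[2] + ldiff)  # same window on the correct allele
  sig <- edit_signature(design$pegrna, design$locus, design$edit)
  sig_rc <- dna_revcomp(sig)
  min_len <- params$min_read_len %||% min(50L, floor(0.8 * nchar(reference)))
  m <- params$ptd_min_match
  # template-derived k-mers in both orientations (reads are top-strand; the
  # RT template is PAM-strand)
  rt_kmers <- unique(c(all_kmers(design$pegrna$rt_seq, m),
                       all_kmers(dna_revcomp(design$pegrna$rt_seq), m)))
  hom_prefix <- substr(design$pegrna$rt_seq, design$pegrna$rt_edit_span + 1L,
                       design$pegrna$rt_edit_span + m)
  hom_patterns <- unique(c(hom_prefix, dna_revcomp(hom_prefix)))
  probes <- orient_probes(reference)
  scoring <- params$scoring

  # the alt allele occupies columns [estart, estart + nchar(alt)) of the
  # correct allele, and [estart, eend) of the reference
  estart <- design$edit$start
  eend <- estart + nchar(design$edit$ref)
  aend <- estart + nchar(design$edit$alt)
  is_sub <- design$edit$kind == "substitution"

  keep <- nchar(reads) >= min_len
  filtered <- sum(!keep)
  reads_kept <- reads[keep]
  if (!length(reads_kept)) {
    out <- data.frame(read_id = character(0), label = character(0),
                      has_signature = logical(0), extra_ins_len = integer(0),
                      notes = character(0), stringsAsFactors = FALSE)
    attr(out, "filtered") <- filtered
    return(out)
  }

  uniq <- unique(unname(reads_kept))
  idx_of <- match(unname(reads_kept), uniq)
  nu <- length(uniq)

  oriented <- vapply(uniq, function(rd) {
    if (rd == reference || rd == correct) return(rd)
    if (orient_score(rd, probes) < orient_score(dna_revcomp(rd), probes)) {
      dna_revcomp(rd)
    } else rd
  }, "", USE.NAMES = FALSE)
  has_sig <- vapply(oriented, function(rd)
    grepl(sig, rd, fixed = TRUE) || grepl(sig_rc, rd, fixed = TRUE),
    logical(1), USE.NAMES = FALSE)

  label <- rep(NA_character_, nu)
  extra <- integer(nu)
  notes <- character(nu)

  hit <- oriented == reference
  label[hit] <- "WT"; notes[hit] <- "exact reference"
  hit <- is.na(label) & oriented == correct
  label[hit] <- "correct_PE"; notes[hit] <- "exact correct allele"

  # variant info vs a target for every unresolved read: fast hamming path
  # for equal-length near-identical pairs, batched global alignment otherwise
  variant_info <- function(idx, target) {
    out <- vector("list", nu)
    need <- integer(0)
    for (i in idx) {
      hp <- hamming_positions(oriented[i], target)
      if (!is.null(hp) && length(hp) <= 6L) {
        out[[i]] <- list(indel = FALSE, mm = hp, ops = NULL)
      } else {
        need <- c(need, i)
      }
    }
    if (length(need)) {
      als <- align_many(oriented[need], target, scoring)
      for (j in seq_along(need)) {
        ops <- als[[j]]$ops
        out[[need[j]]] <- list(indel = TRUE,
                               mm = mismatch_positions_from_ops(ops), ops = ops)
      }
    }
    out
  }

  # ---- branch 1: WT (no in-window variant vs reference) ----
  todo <- which(is.na(label))
  vref <- variant_info(todo, reference)
  for (i in todo) {
    v <- vref[[i]]
    clean <- if (is.null(v$ops)) TRUE else !indel_in_window(v$ops, w)
    if (!clean || count_in_window(v$mm, w) > params$max_mm_window) next
    carries_alt <- FALSE
    if (is_sub) {
      rb <- if (is.null(v$ops)) substr0(oriented[i], estart, eend)
            else read_bases_at(oriented[i], v$ops, estart, eend)
      carries_alt <- identical(rb, design$edit$alt)
    }
    if (!carries_alt) {
      label[i] <- "WT"; notes[i] <- "no in-window variant vs reference"
    }
  }

  # ---- branch 2: correct_PE (matches correct allele; alt columns exact) ----
  todo <- which(is.na(label))
  vcor <- variant_info(todo, correct)
  for (i in todo) {
    v <- vcor[[i]]
    clean <- if (is.null(v$ops)) TRUE else !indel_in_window(v$ops, w_cor)
    if (!clean || count_in_window(v$mm, w_cor) > params$max_mm_window) next
    carries_alt <- TRUE
    if (nchar(design$edit$alt) > 0) {
      rb <- if (is.null(v$ops)) substr0(oriented[i], estart, aend)
            else read_bases_at(oriented[i], v$ops, estart, aend)
      carries_alt <- identical(rb, design$edit$alt)
    }
    if (carries_alt) {
      label[i] <- "correct_PE"; notes[i] <- "matches correct allele in window"
    }
  }

  # ---- branch 3: PTD ----
  # An exact signature admits any template-matching insertion; a signature
  # found only with mismatches (sequencing noise inside the signature) needs
  # the stronger evidence of the duplicated-homology prefix inside the
  # inserted sequence, so accidental indels never pass.
  todo <- which(is.na(label))
  for (i in todo) {
    sig_approx <- !has_sig[i] &&
      (count_pattern_mm(sig, oriented[i], params$sig_max_mm_ptd) ||
       count_pattern_mm(sig_rc, oriented[i], params$sig_max_mm_ptd))
    if (!has_sig[i] && !sig_approx) next
    ops <- vcor[[i]]$ops
    if (is.null(ops)) next
    ins <- ops[ops$op == "ins" & ops$length >= m, , drop = FALSE]
    if (!nrow(ins)) next
    near <- ins$ref_pos >= w_cor[1] - 2L &
      ins$ref_pos <= w_cor[2] + max(ins$length)
    ins <- ins[near, , drop = FALSE]
    for (r in seq_len(nrow(ins))) {
      ok <- if (has_sig[i]) {
        any(all_kmers(ins$seq[r], m) %in% rt_kmers)
      } else {
        any(vapply(hom_patterns, grepl, logical(1), x = ins$seq[r], fixed = TRUE))
      }
      if (ok) {
        label[i] <- "PTD"
        extra[i] <- ins$length[r]
        notes[i] <- "template-matching insertion at junction"
        break
      }
    }
  }

  # ---- branch 4 ----
  label[is.na(label)] <- "indel_other"

  out <- data.frame(
    read_id = names(reads_kept),
    label = label[idx_of],
    has_signature = has_sig[idx_of],
    extra_ins_len = extra[idx_of],
    notes = notes[idx_of],
    stringsAsFactors = FALSE)
  attr(out, "filtered") <- filtered
  out
}

#' Classify a single read
#'
#' @param read DNA string.
#' @inheritParams classify_reads
#' @return One-row data.frame as in [classify_reads()].
#' @export
classify_read <- function(read, design, params = classify_params()) {
  classify_reads(c(read1 = read), design, params)
}

#' Summarise read calls into an outcome report
#'
#' Computes the standard outcome percentages. `pct_correct`, `pct_wt` and
#' `pct_ptd` come from class counts; `pct_unintended` and `pct_indel` are
#' computed by the defining identities `100 - pct_correct - pct_wt` and
#' `pct_unintended - pct_ptd` (never independently), so the identities hold
#' exactly on every input. `pct_any_intended` is the percentage of reads
#' carrying the full edit signature, with or without extra modifications.
#'
#' @param calls data.frame from [classify_reads()].
#' @return Object of class `outcome_report` with fields n_reads, pct_correct,
#'   pct_wt, pct_unintended, pct_ptd, pct_indel, pct_any_intended.
#' @export
summarize_calls <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    stop_pegkit("cannot summarise an empty set of calls", "pegkit_empty_report")
  }
  n <- nrow(calls)
  pct <- function(k) 100 * sum(calls$label == k) / n
  pct_correct <- pct("correct_PE")
  pct_wt <- pct("WT")
  pct_ptd <- pct("PTD")
  pct_unintended <- 100 - pct_correct - pct_wt
  structure(list(
    n_reads = n,
    pct_correct = pct_correct,
    pct_wt = pct_wt,
    pct_unintended = pct_unintended,
    pct_ptd = pct_ptd,
    pct_indel = pct_unintended - pct_ptd,
    pct_any_intended = 100 * sum(calls$has_signature) / n
  ), class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("<outcome_report> n = %d reads\n", x$n_reads))
  for (f in c("pct_correct", "pct_wt", "pct_unintended", "pct_ptd",
              "pct_indel", "pct_any_intended")) {
    cat(sprintf("  %-17s %6.2f%%\n", sub("pct_", "", f), x[[f]]))
  }
  invisible(x)
}
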