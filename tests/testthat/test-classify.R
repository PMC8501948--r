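test_that("align_read recovers identity and isolated insertions deterministically", {
  al <- align_read("ACGTACGT", "ACGTACGT")
  expect_identical(al$ops$op, "match")
  expect_identical(al$ops$length, 8L)
  # one 3-nt insertion, placement verified against the construction
  read <- paste0("ACGTACGTAC", "TTT", "GTACGTACGT")
  ref <- paste0("ACGTACGTAC", "GTACGTACGT")
  al <- align_read(read, ref)
  ins <- al$ops[al$ops$op == "ins", ]
  expect_identical(nrow(ins), 1L)
  expect_identical(ins$length, 3L)
  expect_identical(ins$seq, "TTT")
  expect_error(align_read("", "ACGT"), class = "pegkit_validation_error")
  # deterministic: identical inputs, identical ops
  expect_identical(align_read(read, ref), align_read(read, ref))
})

test_that("the edit signature joins PBS flank and edited bases, spanning deletions", {
  loc <- toy_locus()
  st <- toy_site(loc)
  ed <- parse_label("+1 T ins", st, loc)
  peg <- build_pegrna(loc, ed, st, pbs_len = 4, rt_homology_len = 5)
  expect_identical(edit_signature(peg, loc, ed, flank = 4), "GCAAT")
  # deletion signature spans the new junction: PBS flank + post-deletion bases
  locB <- label_locus_ctt()
  sB <- first_plus_site(locB, "GACCTTAACGGATGCAACTT")
  edB <- parse_label("+1–3 CTT del", sB, locB)
  pegB <- build_pegrna(locB, edB, sB)
  sigB <- edit_signature(pegB, locB, edB)
  expect_match(apply_edit(locB, edB), sigB, fixed = TRUE)
  expect_false(grepl(sigB, locB$sequence, fixed = TRUE))
  # a degenerate 1-nt signature is rejected
  base <- substr(loc$sequence, st$nick_pos + 1L, st$nick_pos + 1L)
  other <- setdiff(c("A", "C", "G", "T"), base)[1]
  sub1 <- edit_spec("substitution", st$nick_pos, base, other)
  pegS <- build_pegrna(loc, sub1, st)
  expect_error(edit_signature(pegS, loc, sub1, flank = 0),
               class = "pegkit_validation_error")
})

test_that("classification follows the documented precedence on constructed alleles", {
  loc <- toy_locus()
  st <- toy_site(loc)
  ed <- parse_label("+1 CTT ins", st, loc)
  peg <- build_pegrna(loc, ed, st)
  d <- pe_design(loc, ed, peg)
  expect_identical(classify_read(loc$sequence, d)$label, "WT")
  flap <- simulate_flap(loc, peg)
  expect_identical(flap, apply_edit(loc, ed))
  expect_identical(classify_read(flap, d)$label, "correct_PE")
  ptd <- make_ptd_allele(loc, ed, peg, dup_len = 5)
  call <- classify_read(ptd$sequence, d)
  expect_identical(call$label, "PTD")
  expect_identical(call$extra_ins_len, 5L)
  expect_true(call$has_signature)
  set.seed(5001)
  ind <- make_indel_allele(loc, st, 2, "deletion",
                           avoid = edit_signature(peg, loc, ed),
                           forbid = c(loc$sequence, flap))
  expect_identical(classify_read(ind$sequence, d)$label, "indel_other")
})

test_that("classification is orientation-normalised", {
  loc <- toy_locus()
  st <- toy_site(loc)
  ed <- parse_label("+1 CTT ins", st, loc)
  peg <- build_pegrna(loc, ed, st)
  d <- pe_design(loc, ed, peg)
  ptd <- make_ptd_allele(loc, ed, peg, dup_len = 4)$sequence
  fwd <- classify_reads(c(a = loc$sequence, b = apply_edit(loc, ed), c = ptd), d)
  rev <- classify_reads(c(a = dna_revcomp(loc$sequence),
                          b = dna_revcomp(apply_edit(loc, ed)),
                          c = dna_revcomp(ptd)), d)
  expect_identical(fwd$label, rev$label)
})

test_that("short reads are filtered and the count is reported", {
  loc <- toy_locus()
  st <- toy_site(loc)
  ed <- parse_label("+1 CTT ins", st, loc)
  d <- pe_design(loc, ed, build_pegrna(loc, ed, st))
  calls <- classify_reads(c(a = loc$sequence, b = "ACGTACGT"), d)
  expect_identical(nrow(calls), 1L)
  expect_identical(attr(calls, "filtered"), 1L)
})

test_that("per-read labels match the generating truth on error-free mixtures", {
  set.seed(5002)
  for (i in 1:4) {
    des <- random_design()
    d <- pe_design(des$locus, des$edit, des$pegrna)
    sim <- generate_reads(des$locus, des$edit, des$pegrna, simulation_config(
      n_reads = 400, seed = 100 + i, per_base_error = 0))
    calls <- classify_reads(sim$reads, d)
    expect_identical(unname(TRUTH_TO_CALL[sim$truth$label]), calls$label)
  }
})

test_that("every read receives exactly one of the four labels", {
  set.seed(5003)
  des <- random_design()
  d <- pe_design(des$locus, des$edit, des$pegrna)
  sim <- generate_reads(des$locus, des$edit, des$pegrna,
                        simulation_config(n_reads = 600, seed = 42,
                                          per_base_error = 0.003))
  calls <- classify_reads(sim$reads, d)
  expect_identical(nrow(calls), 600L)
  expect_true(all(calls$label %in% c("WT", "correct_PE", "PTD", "indel_other")))
})

test_that("outcome percentages obey the defining identities on arbitrary call sets", {
  mk_calls <- function(n_correct, n_wt, n_ptd, n_indel) {
    lab <- rep(c("correct_PE", "WT", "PTD", "indel_other"),
               c(n_correct, n_wt, n_ptd, n_indel))
    data.frame(read_id = if (length(lab)) sprintf("r%03d", seq_along(lab)) else character(0),
               label = lab,
               has_signature = lab %in% c("correct_PE", "PTD"),
               extra_ins_len = rep(0L, length(lab)),
               notes = rep("", length(lab)), stringsAsFactors = FALSE)
  }
  rep1 <- summarize_calls(mk_calls(50, 30, 15, 5))
  expect_identical(rep1$pct_unintended, 20)
  expect_identical(rep1$pct_indel, 5)
  set.seed(5004)
  for (i in 1:60) {
    counts <- as.integer(stats::rmultinom(1, sample(c(1, 7, 100, 999), 1),
                                          prob = stats::runif(4)))
    if (sum(counts) == 0) next
    rep <- summarize_calls(mk_calls(counts[1], counts[2], counts[3], counts[4]))
    expect_identical(rep$pct_unintended, 100 - rep$pct_correct - rep$pct_wt)
    expect_identical(rep$pct_indel, rep$pct_unintended - rep$pct_ptd)
    expect_gte(rep$pct_any_intended, rep$pct_correct)
    expect_gte(rep$pct_any_intended, rep$pct_ptd)
  }
  # degenerate single-class inputs
  all_wt <- summarize_calls(mk_calls(0, 25, 0, 0))
  expect_identical(all_wt$pct_wt, 100)
  expect_identical(all_wt$pct_correct, 0)
  expect_identical(all_wt$pct_ptd, 0)
  expect_identical(all_wt$pct_indel, 0)
  expect_identical(all_wt$pct_any_intended, 0)
  all_cor <- summarize_calls(mk_calls(40, 0, 0, 0))
  expect_identical(all_cor$pct_correct, 100)
  expect_identical(all_cor$pct_any_intended, 100)
  expect_error(summarize_calls(mk_calls(0, 0, 0, 0)),
               class = "pegkit_empty_report")
})
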