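test_that("scan_pam_sites finds the single site of a minimal 23-nt locus", {
  loc <- locus("mini", paste0("G", strrep("A", 19), "AGG"))
  sites <- scan_pam_sites(loc)
  expect_length(sites, 1L)
  expect_identical(sites[[1]]$strand, "+")
  expect_identical(sites[[1]]$spacer_start, 0L)
  expect_identical(sites[[1]]$pam_seq, "AGG")
  expect_identical(sites[[1]]$nick_pos, 17L)
})

test_that("a locus without GG or CC dinucleotides has no protospacer", {
  loc <- locus("none", strrep("AGAT", 10))
  expect_length(scan_pam_sites(loc), 0L)
})

test_that("scan_pam_sites agrees with a brute-force oracle on random loci", {
  set.seed(3001)
  for (i in 1:40) {
    loc <- random_locus(sample(30:150, 1))
    got <- sites_table(scan_pam_sites(loc))
    want <- oracle_scan(loc)
    expect_identical(nrow(got), length(want))
    if (length(want)) {
      key <- function(strand, start) paste(strand, start)
      expect_setequal(key(got$strand, got$spacer_start),
                      vapply(want, function(h) key(h$strand, h$spacer_start), ""))
      # every emitted spacer re-locates with its PAM by substring search
      for (r in seq_len(nrow(got))) {
        probe <- paste0(got$spacer_seq[r], got$pam_seq[r])
        hay <- if (got$strand[r] == "+") loc$sequence else dna_revcomp(loc$sequence)
        expect_true(grepl(probe, hay, fixed = TRUE))
      }
    }
  }
})

test_that("window restricts sites by PAM location and small windows give empty lists", {
  loc <- toy_locus()
  all_sites <- scan_pam_sites(loc)
  st <- toy_site(loc)
  pam_start <- st$spacer_start + 20L
  only <- scan_pam_sites(loc, c(pam_start, pam_start + 3L))
  expect_true(all(vapply(only, function(s)
    s$strand == "-" || s$spacer_start == st$spacer_start, logical(1))))
  expect_length(scan_pam_sites(loc, c(0L, 2L)), 0L)
  expect_gt(length(all_sites), length(only))
})

test_that("candidate sites are ranked by nick-to-edit distance with deterministic ties", {
  loc <- toy_locus()
  st <- toy_site(loc)
  ed <- parse_label("+2 T ins", st, loc)
  cand <- candidate_pegrna_sites(loc, ed)
  expect_gt(length(cand), 0L)
  offs <- vapply(cand, function(s) pegkit:::edit_offsets(loc, ed, s)$start_offset, 0L)
  expect_identical(offs, sort(offs))
  expect_identical(cand[[1]]$spacer_start, st$spacer_start)
  # an edit upstream of every nick is unreachable, with diagnostics
  far <- edit_spec("substitution", 0L, substr(loc$sequence, 1, 1),
                   setdiff(c("A", "C", "G", "T"), substr(loc$sequence, 1, 1))[1])
  none <- candidate_pegrna_sites(loc, far)
  expect_length(none, 0L)
  expect_true(is.data.frame(attr(none, "rejected")))
  expect_gt(nrow(attr(none, "rejected")), 0L)
})

test_that("build_pegrna reproduces the worked toy design", {
  loc <- toy_locus()
  st <- toy_site(loc)
  ed <- parse_label("+1 T ins", st, loc)
  peg <- build_pegrna(loc, ed, st, pbs_len = 4, rt_homology_len = 5)
  expect_identical(peg$pbs_seq, "GCAA")
  expect_identical(peg$rt_seq, "TGTCAG")
  expect_identical(peg$extension_seq, "CTGACATTGC")
  expect_identical(peg$extension_seq,
                   paste0(dna_revcomp(peg$rt_seq), dna_revcomp(peg$pbs_seq)))
  expect_identical(simulate_flap(loc, peg), apply_edit(loc, ed))
})

test_that("spacers not starting with G get one prepended, G-starting spacers do not", {
  loc <- toy_locus()
  st <- toy_site(loc)
  ed <- parse_label("+1 T ins", st, loc)
  peg <- build_pegrna(loc, ed, st)
  expect_false(peg$g_prepended)
  expect_identical(nchar(peg$spacer_oligo_seq), 20L)
  set.seed(3002)
  repeat {
    des <- random_design()
    if (!startsWith(des$site$spacer_seq, "G")) break
  }
  expect_true(des$pegrna$g_prepended)
  expect_identical(substr(des$pegrna$spacer_oligo_seq, 1, 1), "G")
  expect_identical(nchar(des$pegrna$spacer_oligo_seq), 21L)
})

test_that("build_pegrna reports bounds and truncation errors", {
  loc <- locus("tight", paste0("G", strrep("A", 19), "AGGTT"))
  st <- scan_pam_sites(loc)[[1]]
  ed <- edit_spec("insertion", st$nick_pos, alt = "T")
  expect_error(build_pegrna(loc, ed, st, pbs_len = 30),
               class = "pegkit_bounds_error")
  expect_error(build_pegrna(loc, ed, st, pbs_len = 8, rt_homology_len = 20),
               class = "pegkit_truncation_error")
})

test_that("second-nick guides are opposite-strand, window-bounded, sorted by distance", {
  loc <- toy_locus()
  st <- toy_site(loc)
  peg <- build_pegrna(loc, parse_label("+1 T ins", st, loc), st)
  sn <- choose_second_nick(loc, peg)
  expect_gt(length(sn), 0L)
  offs <- vapply(sn, `[[`, 0L, "signed_offset")
  expect_identical(offs, offs[order(abs(offs))])
  for (g in sn) {
    expect_true(g$site$strand != st$strand)
    expect_true(abs(g$signed_offset) <= 120 && abs(g$signed_offset) > 10)
  }
  # sign convention: the toy carries one opposite-strand guide nicking
  # 39 nt 3' of the pegRNA nick
  expect_true(39L %in% offs)
  expect_length(choose_second_nick(loc, peg, offset_window = c(-5L, 5L)), 0L)
})

test_that("second-nick sign convention is negative 5' of the pegRNA nick", {
  set.seed(3003)
  found_neg <- FALSE
  for (i in 1:60) {
    des <- random_design()
    sn <- choose_second_nick(des$locus, des$pegrna)
    for (g in sn) {
      pv <- pegkit:::pam_view(des$locus, des$site)
      cut2 <- pegkit:::nick_cut_in_frame(g$site, pv$L, des$site$strand)
      expect_identical(g$signed_offset, as.integer(cut2 - pv$npam))
      if (g$signed_offset < 0) found_neg <- TRUE
    }
    if (found_neg && i > 10) break
  }
  expect_true(found_neg)
})

test_that("emit_oligos yields three duplexes whose cores are exact reverse complements", {
  loc <- toy_locus()
  st <- toy_site(loc)
  peg <- build_pegrna(loc, parse_label("+1 T ins", st, loc), st)
  sn <- choose_second_nick(loc, peg)
  for (dialect in c("pea1", "pu6")) {
    plan <- construct_plan("pe3", peg, second_nick = sn[[1]], dialect = dialect)
    oli <- emit_oligos(plan)
    expect_identical(sort(oli$slot), sort(c("spacer", "extension", "second_nick")))
    for (r in seq_len(nrow(oli))) {
      expect_identical(nchar(oli$top_overhang[r]), 4L)
      expect_identical(nchar(oli$bottom_overhang[r]), 4L)
      top_core <- sub(paste0("^", oli$top_overhang[r]), "", oli$top_seq[r])
      bot_core <- sub(paste0("^", oli$bottom_overhang[r]), "", oli$bottom_seq[r])
      expect_identical(top_core, dna_revcomp(bot_core))
    }
    # emission is pure
    expect_identical(oli, emit_oligos(plan))
  }
})

test_that("nuclease kits carry the sham guide and PE3/nuclease plans validate", {
  loc <- toy_locus()
  st <- toy_site(loc)
  peg <- build_pegrna(loc, parse_label("+1 T ins", st, loc), st)
  sn <- choose_second_nick(loc, peg)
  nuc <- construct_plan("nuclease", peg)
  oli <- emit_oligos(nuc)
  second <- oli[oli$slot == "second_nick", ]
  expect_match(second$top_seq, SHAM_GUIDE, fixed = TRUE)
  expect_error(construct_plan("pe3", peg), class = "pegkit_validation_error")
  expect_error(construct_plan("nuclease", peg, second_nick = sn[[1]]),
               class = "pegkit_validation_error")
})

test_that("adapter tables are structurally validated", {
  tab <- load_adapter_table()
  expect_true(all(c("pea1", "pu6") %in% names(tab)))
  bad1 <- tempfile(fileext = ".yaml")
  writeLines(c("pea1:", "  spacer:", "    top_overhang: CAC",
               "    bottom_overhang: AAAC"), bad1)
  expect_error(load_adapter_table(bad1), class = "pegkit_config_error")
  bad2 <- tempfile(fileext = ".yaml")
  writeLines(c("pea1:",
               "  spacer:    {top_overhang: CACC, bottom_overhang: AAAC}",
               "  extension: {top_overhang: CACC, bottom_overhang: AAAC}",
               "  second_nick: {top_overhang: TGTA, bottom_overhang: TAAC}"), bad2)
  expect_error(load_adapter_table(bad2), class = "pegkit_config_error")
  # a missing slot surfaces as a configuration error naming the slot
  loc <- toy_locus(); st <- toy_site(loc)
  peg <- build_pegrna(loc, parse_label("+1 T ins", st, loc), st)
  plan <- construct_plan("nuclease", peg)
  err <- expect_error(emit_oligos(plan, adapters = list(spacer = list(
    top_overhang = "CACC", bottom_overhang = "AAAC"))),
    class = "pegkit_config_error")
  expect_match(conditionMessage(err), "extension")
})

test_that("IVT primers carry the T7 promoter and anneal over the pegRNA 3' end", {
  loc <- toy_locus()
  st <- toy_site(loc)
  peg <- build_pegrna(loc, parse_label("+1 T ins", st, loc), st)
  pr <- emit_ivt_primers(peg)
  expect_true(startsWith(pr$forward, T7_PROMOTER))
  expect_match(pr$forward, peg$spacer_oligo_seq, fixed = TRUE)
  tail_src <- paste0(SP_CAS9_SCAFFOLD, peg$extension_seq)
  expect_true(endsWith(tail_src, dna_revcomp(pr$reverse)))
  expect_identical(nchar(pr$reverse), 20L)
})

test_that("a short extension pushes the reverse IVT primer into the scaffold with a warning", {
  loc <- toy_locus()
  st <- toy_site(loc)
  # pbs 8 + rt (1 edited + 5 homology) = 14-nt extension
  peg <- build_pegrna(loc, parse_label("+1 T ins", st, loc), st,
                      pbs_len = 8, rt_homology_len = 5)
  expect_identical(nchar(peg$extension_seq), 14L)
  expect_warning(pr <- emit_ivt_primers(peg, anneal_len = 20),
                 class = "pegkit_short_extension")
  rc <- dna_revcomp(pr$reverse)
  expect_identical(nchar(rc), 20L)
  expect_true(endsWith(rc, peg$extension_seq))           # all 14 extension nt
  expect_true(endsWith(SP_CAS9_SCAFFOLD, substr(rc, 1, 6)))  # plus 6 scaffold nt
  expect_error(emit_ivt_primers(peg, anneal_len = 10),
               class = "pegkit_validation_error")
})
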