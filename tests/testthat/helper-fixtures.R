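# Shared fixtures, built in code. The toy locus embeds a + strand
# protospacer GACCTTAACGGATGCAAGTC with PAM AGG; flanks are fixed so every
# expected value below is deterministic.

TOY_SPACER <- "GACCTTAACGGATGCAAGTC"

toy_locus <- function() {
  locus("toy", paste0(
    "ATGCTAGCTAGGCTAACTGATTGCAATGCA",
    TOY_SPACER, "AGG",
    "TCAGGATTCGGAATCTTACGCAGGTTACCAGATTCAAGCGTATCGGATCCATTGAAGCTT"))
}

toy_site <- function(loc = toy_locus()) {
  Filter(function(s) s$spacer_seq == TOY_SPACER && s$strand == "+",
         scan_pam_sites(loc))[[1]]
}

# loci whose protospacers realise the canonical label examples:
# spacer ending CAA (so +1..+3 = CAA, +5/+6 = PAM GG) and spacer ending CTT
label_locus_caa <- function() {
  locus("labelA", paste0("ATTGCAATGCA", "GACCTTAACGGATGCAACAA", "AGG",
                         "TCAGTTACGAATCTTACGCATGTTACCAGATTCAAGCGTA"))
}
label_locus_ctt <- function() {
  locus("labelB", paste0("ATTGCAATGCA", "GACCTTAACGGATGCAACTT", "TGG",
                         "TCAGTTACGAATCTTACGCATGTTACCAGATTCAAGCGTA"))
}
first_plus_site <- function(loc, spacer) {
  Filter(function(s) s$spacer_seq == spacer && s$strand == "+",
         scan_pam_sites(loc))[[1]]
}

# independent brute-force protospacer scan: check every 23-mer on both
# strands by direct substring comparison (oracle for scan_pam_sites)
oracle_scan <- function(loc) {
  s <- loc$sequence
  L <- nchar(s)
  hits <- list()
  for (i in seq_len(max(0L, L - 22L))) {        # 1-based window start
    w <- substr(s, i, i + 22L)
    if (substr(w, 22L, 23L) == "GG") {
      hits[[length(hits) + 1L]] <- list(strand = "+", spacer_start = i - 1L,
                                        spacer = substr(w, 1L, 20L),
                                        pam = substr(w, 21L, 23L))
    }
  }
  for (i in seq_len(max(0L, L - 22L))) {
    w <- substr(s, i, i + 22L)
    if (substr(w, 1L, 2L) == "CC") {
      hits[[length(hits) + 1L]] <- list(strand = "-", spacer_start = i + 2L,
                                        spacer = dna_revcomp(substr(w, 4L, 23L)),
                                        pam = dna_revcomp(substr(w, 1L, 3L)))
    }
  }
  hits
}

TRUTH_TO_CALL <- c(correct = "correct_PE", wt = "WT", ptd = "PTD",
                   indel = "indel_other")
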