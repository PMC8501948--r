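---
title: "pegkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pegkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pegkit)
```

## The problem

Prime editing installs small, precise genomic changes — substitutions,
insertions and deletions — using an SpCas9 nickase (or nuclease) fused to a
reverse transcriptase and a prime-editing guide RNA (pegRNA). The pegRNA
carries, beyond the 20-nt spacer, a 3' extension with two functional
segments: the primer binding site (PBS), which anneals to the 3' end of the
nicked DNA strand, and the RT template, which encodes the edit plus
downstream homology and is copied into DNA at the nick. pegkit provides (i)
a design engine that turns a locus and an intended edit into pegRNAs,
second-nick guides and ready-to-order cloning oligos, and (ii) an analysis
path that classifies amplicon-sequencing reads into the standard outcome
classes — correct prime edit, unmodified (WT), partial template duplication
(PTD), and other indels — with a read simulator that generates ground-truth
mixtures so the whole pipeline is testable without sequencing data.

## Coordinate and strand conventions

All internal coordinates are 0-based and half-open on the supplied ("top")
strand; everything user-facing is 1-based closed. SpCas9 recognises a 20-nt
protospacer followed by an NGG PAM and cuts between protospacer positions 17
and 18 on the PAM strand (3 nt 5' of the PAM) — the standard blunt-cut
geometry, which the package assumes throughout. pegRNA arithmetic happens on
the PAM strand: for a minus-strand protospacer the locus is reverse
complemented, the nick cut-point mapped accordingly, and results are mapped
back to top-strand coordinates on output.

Edits are named relative to the nick in the field's nomenclature: `+1` is
the first base 3' of the nick on the PAM strand, insertions print as
`+1 CTT ins`, deletions as `+1–3 CTT del`, and substitutions as `+5 G to C`
or `+1–3 CAA to ACC`. Note that `+4` to `+6` fall inside the PAM, which is
why PAM-killing substitutions are typically written `+5` or `+6`. When the
protospacer lies on the bottom strand the offsets still count on the PAM
strand (the convention of the original prime-editing literature), and
allele strings in labels are PAM-strand oriented. `label_edit()` and
`parse_label()` are exact inverses, which is enforced by round-trip property
tests over randomized edits of every kind.

Multi-base substitutions are modelled as equal-length ref/alt replacements
rather than deletion-plus-insertion, matching the `+1–3 CAA to ACC` phrasing;
edits that span the nick (partially 5' of it) are rejected, since reverse
transcription cannot write upstream of the nick.

## pegRNA construction

`build_pegrna()` assembles, for a chosen protospacer:

* **PBS** — the `pbs_len` genomic PAM-strand bases immediately 5' of the
  nick. Default 13 nt; 8–17 nt is the recommended range and the constructor
  enforces only a hard floor of 3 nt so that deliberately small didactic
  designs remain expressible.
* **RT template** — the edited PAM-strand sequence from the nick through the
  end of the alt allele, plus `rt_homology_len` nt of downstream homology
  (default 13 nt, minimum 1). The template therefore always contains the
  complete alt allele and at least one homology base.
* **3' extension** — `revcomp(RT template)` followed by `revcomp(PBS)`, the
  sequence that is appended after the sgRNA scaffold.
* **spacer oligo** — the spacer with a `G` prepended when it does not
  already start with one (U6 transcription requires a 5' G); the
  `g_prepended` flag records whether this happened.

The central correctness oracle is `simulate_flap()`: it reconstructs the
edited allele *only* from the pegRNA fields, by extending from the nick with
the RT template and re-joining the genomic remainder located by matching the
template's downstream homology (leftmost match at or beyond the nick). For a
well-formed design this must reproduce `apply_edit()` exactly; the test
suite and the acceptance script verify this identity on hundreds of
randomized (locus, edit, protospacer, PBS, homology) draws. A corrupted PBS
or a homology that no longer matches the locus raises a flap-resolution
error rather than returning a plausible-looking sequence.

Candidate protospacers for an edit are ranked by ascending nick-to-edit
distance, with deterministic tie-breaking (plus strand first, then lower
coordinate) so identical inputs always produce identical design sheets. A
`max_nick_to_edit` cap (default 30 nt) excludes sites whose RT template
would become unreasonably long; the cap is configuration, not a claim about
any particular upstream tool.

## Second-nick guides, construct kits and IVT primers

For PE3 the package enumerates opposite-strand protospacers whose
nick-to-nick offset lies within a window (default ±120 nt, excluding ±10 nt
around the pegRNA nick, both configurable) and reports them sorted by
distance with the usual sign convention: positive offsets lie 3' of the
pegRNA nick on the pegRNA's PAM strand, so labels read like "+48" or "−60".
The opposite-strand requirement is structural: nicking the same strand
twice would linearize rather than stimulate repair.

`emit_oligos()` produces the three annealed-duplex inserts used by one-pot
golden-gate (BbsI) assembly: the pegRNA spacer, the 3' extension, and the
second cassette, which holds the second-nick spacer for PE3 or a sham
(non-genome-targeting) guide for nuclease constructs — a nuclease construct
takes a double-strand break from the pegRNA guide alone and must never
receive a genomic second nick. PE2 kits reuse the sham filler so the
cassette is never empty. Each oligo is the core sequence prefixed by a fixed
4-nt 5' overhang; stripping the two declared overhangs must leave exact
reverse complements, and the three slots of a dialect must use mutually
distinct overhang pairs for directional assembly. The overhangs ship as an
editable YAML table (`inst/extdata/adapters.yaml`) with two dialects
(`pea1`, `pu6`); the defaults follow the familiar PX459-lineage spacer
convention (CACC/AAAC) and are validated structurally only — users cloning
into a specific acceptor should substitute its documented overhangs. The
default sham guide is likewise a configuration value; verifying that it
does not target a particular genome is out of scope.

`emit_ivt_primers()` supports pegRNA production by in vitro transcription:
the forward primer is the canonical T7 promoter + the (G-prepended) spacer +
the first 15 nt of the scaffold; the reverse primer is the reverse
complement of the last `anneal_len` nt (default 20, minimum 15) of scaffold
+ extension, so it always covers the pegRNA 3' end and simply reaches into
the scaffold (with a warning) when the extension is shorter than the
annealing length.

## The PTD model

Correct prime editing requires the reverse-transcribed 3' flap to displace
the genomic 5' flap and anneal to the downstream homology. The failure mode
modelled here — dominant with nuclease prime editors — is end-joining of the
flap directly to the distal side of the break: the product carries the
intended edit *plus* the first `dup_len` bases of the RT template's
downstream homology as an extra template-derived insertion, a partial
template duplication. `make_ptd_allele()` constructs exactly this allele:

```
PAM-strand locus[0, nick) + (edited segment + dup_len homology bases)
                          + locus[nick + junction_del, end)
```

With `junction_del = 0` the PTD is strictly longer than the correct allele
by `dup_len` (insertion/substitution edits) and still carries the intended
edit signature; small junction deletions model additional end-processing.
Note that for deletion edits the end-joined product retains the genomic
bases the edit was meant to remove — faithful to the mechanism, and the
reason PTDs at deletion sites are *insertions* relative to the correct
allele.

The simulator draws `dup_len` uniformly from `ptd_dup_range`, by default
`[3, rt_homology_len]`: 3 nt is the classifier's operational detection
threshold (below), so the default mixture contains only operationally
detectable duplications; shorter ones can be requested explicitly. The
empirical duplication-length distribution in real data is not claimed to be
uniform — this is a test-harness default, not a biological estimate.

## The read simulator

`generate_reads()` draws full-length amplicon reads from a configured
mixture over {correct, WT, PTD, indel}, then applies independent
substitution errors at `per_base_error` (default 0.001, a typical
high-quality short-read figure) with uniform base qualities. Cut-site
indels — the "other indel" class — are deletions centred on the nick or
insertions of random bases at the nick, sizes 1–3 by default. Two guards
keep the simulated classes semantically distinct: an indel allele is
resampled if it contains the edit signature (it would then *be* an intended
edit) or if it is within 2 mismatches (the classifier's in-window noise
allowance) of the WT or correct sequence at equal length — e.g. a
wrong-base 1-nt insertion at the nick when the edit is a 1-nt insertion.
When a size/kind combination cannot satisfy the guards, size and kind are
redrawn.

Everything is deterministic given the configuration seed. What the
simulator does **not** model: paired-end structure and merging (reads are
assumed pre-merged), indel sequencing errors, quality-dependent errors,
PCR chimeras, and re-cutting of near-match substitution products by the
nuclease editor. Passing tests therefore demonstrate correctness of the
design arithmetic and classification logic under clean mixtures, not
robustness to every artefact of real libraries.

## Read classification

`classify_reads()` assigns each read exactly one label with a fixed
precedence, evaluating variants only inside a quantification window
(default `[nick − pbs_len, nick + rt_len + 5]` on the reference,
PAM-strand arithmetic mapped to top-strand coordinates; variants outside
the window are ignored in every branch):

1. **WT** — no insertion or deletion inside the window relative to the
   reference, at most `max_mm_window` (default 2) substitution mismatches in
   the window, and (for substitution edits) the alt allele absent.
2. **correct_PE** — the same criteria against the correct edited allele,
   with one sharpening: the alt columns themselves must match exactly — the
   mismatch allowance is for sequencing noise elsewhere in the window, never
   for the edited bases.
3. **PTD** — the read carries the edit signature and its alignment to the
   correct allele contains an insertion at the junction of at least
   `ptd_min_match` (m = 3) nt matching the RT template. With an exact
   signature any template-matching insertion qualifies; if the signature is
   found only with one mismatch (noise inside the signature), the stronger
   evidence of the duplicated-homology prefix inside the inserted sequence
   is required, so accidental indels cannot slip in.
4. **indel_other** — everything else.

The **edit signature** operationalises "contains the primer binding site
and the edit sequence": the last `flank` nt of the PBS (default: all of it)
followed by the edited segment through the end of the alt allele. For
deletion edits that segment is empty — the junction itself is the evidence —
so the signature is extended by 3 nt of post-junction homology. A minimum
signature length guards against degenerate cases such as a bare 1-nt
substitution with no flank. Reads are searched in both orientations;
`has_signature` is an exact-match flag (the filter as defined), which means
a correct read whose only sequencing error falls inside the signature can
be labelled `correct_PE` while `has_signature` is `FALSE` — the per-read
flag is exact, the label is noise-tolerant.

Alignment is global Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment` (match +2, mismatch −4, gap open −10, gap
extend −1 — compact, stable indel placement near the nick). Tie-breaking
among equal-scoring gap placements follows the library's deterministic
convention; the PTD junction test is written to be placement-invariant
(any m-mer of the inserted sequence may match the template, in either
orientation). For throughput, identical reads are collapsed before
classification, equal-length near-identical pairs take a Hamming fast
path, and the remaining reads are aligned in batched calls.

`summarize_calls()` computes the outcome report. Three of its fields are
*defined* by identities rather than counted independently:

* `pct_unintended = 100 − pct_correct − pct_wt`
* `pct_indel = pct_unintended − pct_ptd`
* `pct_any_intended` = percentage of reads carrying the full edit signature,
  with or without extra modifications (so it is ≥ both `pct_correct` and
  `pct_ptd`).

Because the first two are computed by their defining formulas, the
identities hold exactly — to the last floating-point bit — on every input,
including degenerate single-class ones; property tests assert this over
random call multisets.

## Numerical and design choices

* **Problem sizes.** The test suite exercises 200 randomized designs for
  the flap round-trip and rule suite, 5,000 error-free reads for
  classifier/truth equivalence, and 20 seeds × 10,000 reads at error 0.001
  for mixture recovery (each class within ±1.5 percentage points, ≈3σ of
  the binomial sampling noise at n = 10,000, in at least 19 of 20 seeds).
  The acceptance script re-derives the same quantities at 10 seeds.
* **Degenerate inputs.** Identity substitutions (alt = ref) are legal and
  flow through design and flap simulation unchanged; empty windows return
  empty site lists rather than errors; an empty call set is an explicit
  error; multi-record FASTA loci are rejected with guidance.
* **Determinism.** All randomness flows from explicit seeds; design and
  oligo emission are pure functions; ranking ties are broken by fixed rules.
* **Error taxonomy.** Classed conditions (`pegkit_allele_mismatch`,
  `pegkit_unreachable_edit`, `pegkit_flap_error`, `pegkit_bounds_error`,
  `pegkit_truncation_error`, `pegkit_config_error`, `pegkit_parse_error`)
  let callers and the CLI distinguish user error (exit 2) from
  no-design-found (exit 3).

## Known limitations

* The quantification window, PTD match threshold m, and noise allowances
  are operational definitions; published pipelines built on other tools may
  use slightly different internal filters, so absolute percentages on real
  data can differ at the margin even when the class definitions agree.
* PTDs with junction deletions large enough to consume the net insertion
  are not distinguishable from other indels by this (or any sequence-level)
  classifier; the simulator defaults to junction_del = 0.
* PE3b (seed-overlapping second nicks), chemically modified pegRNA motifs,
  off-target scoring and editing-efficiency prediction are out of scope.
* The classifier assumes reads are complete amplicons covering the window;
  partial reads are length-filtered, not salvaged.
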