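Package: pegkit
Title: Prime Editing Design, Read Simulation and Outcome Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design engine and analysis toolkit for CRISPR prime editing.
    Enumerates SpCas9 (NGG) protospacers around an intended edit, builds
    pegRNAs (spacer, primer binding site, reverse-transcriptase template and
    3' extension), selects opposite-strand second-nick guides for PE3, and
    emits golden-gate cloning oligonucleotide duplexes, sham-guide nuclease
    kits and T7 in vitro transcription primers. A companion simulator
    generates amplicon reads from a mixture of editing outcomes, including
    partial template duplications (PTDs) formed by end-joining of the
    reverse-transcribed flap, and a classifier assigns reads to correct
    prime edit, unmodified, PTD or other-indel classes and reports the
    standard outcome percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
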