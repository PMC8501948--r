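# Golden-gate adapter table: per dialect, per cloning slot, the fixed 4-nt
# 5' overhangs added to the top and bottom oligos for directional BbsI
# assembly. These are editable defaults in the PX459-lineage style (spacer
# slot CACC/AAAC); replace with the overhangs of your acceptor plasmid.
# Structure is validated on load: overhangs are 4-nt ACGT and the three
# slots of a dialect are mutually distinct.
pea1:
  spacer:
    top_overhang: CACC
    bottom_overhang: AAAC
  extension:
    top_overhang: GTGC
    bottom_overhang: CGGA
  second_nick:
    top_overhang: TGTA
    bottom_overhang: TAAC
pu6:
  spacer:
    top_overhang: CACC
    bottom_overhang: AAAC
  extension:
    top_overhang: GTGC
    bottom_overhang: AAAA
  second_nick:
    top_overhang: CAAG
    bottom_overhang: TTGC
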