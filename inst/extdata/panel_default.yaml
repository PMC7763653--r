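# Default ten-marker murine STR authentication panel.
#
# Amplicon size of an allele with r repeats: flank_offset_bp + repeat_unit_bp * r.
# Within each multiplex set the size ranges are disjoint, so a sized peak
# identifies its locus by size alone; no set holds more than three loci.
# Amplicons span exactly 130-515 bp. Ladder and internal markers follow the
# DNA-1000 chip convention (sizing range 25-1000 bp, markers 15 / 1500 bp).
# Set 2 pairs the murine 9-2 locus with the human contamination sentinel
# D8S1106; set 3 pairs 15-3 with 6-4. All values may be overridden by a
# user-supplied config of the same shape.
ladder_sizes_bp: [25, 50, 100, 150, 200, 300, 400, 500, 700, 850, 1000]
lower_marker_bp: 15
upper_marker_bp: 1500
loci:
  - name: "18-3"
    species: mouse
    repeat_unit_bp: 4
    flank_offset_bp: 90
    size_range_bp: [130, 198]
    multiplex_set: 1
  - name: "4-2"
    species: mouse
    repeat_unit_bp: 4
    flank_offset_bp: 150
    size_range_bp: [210, 258]
    multiplex_set: 1
  - name: "6-7"
    species: mouse
    repeat_unit_bp: 4
    flank_offset_bp: 220
    size_range_bp: [268, 340]
    multiplex_set: 1
  - name: "9-2"
    species: mouse
    repeat_unit_bp: 4
    flank_offset_bp: 100
    size_range_bp: [148, 200]
    multiplex_set: 2
  - name: "D8S1106"
    species: human
    repeat_unit_bp: 4
    flank_offset_bp: 180
    size_range_bp: [220, 280]
    multiplex_set: 2
  - name: "15-3"
    species: mouse
    repeat_unit_bp: 4
    flank_offset_bp: 84
    size_range_bp: [140, 200]
    multiplex_set: 3
  - name: "6-4"
    species: mouse
    repeat_unit_bp: 4
    flank_offset_bp: 170
    size_range_bp: [218, 282]
    multiplex_set: 3
  - name: "12-1"
    species: mouse
    repeat_unit_bp: 4
    flank_offset_bp: 95
    size_range_bp: [135, 195]
    multiplex_set: 4
  - name: "5-5"
    species: mouse
    repeat_unit_bp: 4
    flank_offset_bp: 200
    size_range_bp: [240, 300]
    multiplex_set: 4
  - name: "X-1"
    species: mouse
    repeat_unit_bp: 4
    flank_offset_bp: 315
    size_range_bp: [355, 515]
    multiplex_set: 4
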