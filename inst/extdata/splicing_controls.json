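{
  "n_positive_controls": 58,
  "n_negative_controls": 99,
  "n_qpcr_junctions": 47,
  "n_tissues": 5,
  "note": "published control counts of the asMIP study design: positive controls are junctions known to be alternatively spliced, negatives are RefSeq-predicted constitutive junctions; qPCR interrogated 47 junctions in 5 tissues"
}
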