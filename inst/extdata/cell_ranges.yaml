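# Canonical cell-class ID ranges of the 950-neuron retina sample.
# Nested entries (the starburst amacrine subranges) name their parent.
ranges:
  - {class: GC,     from: 1,   to: 36}
  - {class: NFac,   from: 37,  to: 226}
  - {class: WFac,   from: 227, to: 389}
  - {class: OffSAC, from: 260, to: 274, parent: WFac}
  - {class: OnSAC,  from: 358, to: 370, parent: WFac}
  - {class: cBC,    from: 390, to: 696}
  - {class: rBC,    from: 697, to: 840}
  - {class: other,  from: 841, to: 950}
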