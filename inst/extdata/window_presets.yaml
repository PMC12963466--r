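# Display window presets (HU). Soft tissue and bone follow common
# urinary-tract NCCT reading practice.
soft_tissue:
  center: 50
  width: 400
bone:
  center: 300
  width: 1120
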