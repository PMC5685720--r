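{
  "gene": "JAK2S",
  "chrom": "JAK2syn",
  "strand": "+",
  "exons": [
    {
      "label": "16",
      "start": 301,
      "end": 375,
      "first_residue": 675
    },
    {
      "label": "20",
      "start": 576,
      "end": 695,
      "first_residue": 750
    },
    {
      "label": "21",
      "start": 896,
      "end": 985,
      "first_residue": 860
    },
    {
      "label": "23",
      "start": 1186,
      "end": 1305,
      "first_residue": 915
    }
  ]
}
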