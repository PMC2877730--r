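{
  "outdir": "akh_day5_run",
  "format": "tsv",
  "standard_nM": 400,
  "matrix_nl": 200,
  "groups": [
    {
      "label": "control",
      "n": 15,
      "mean": {"AKH": 177.25, "AKHGK": 165},
      "sd": {"AKH": 53.3, "AKHGK": 50}
    },
    {
      "label": "amon",
      "n": 16,
      "mean": {"AKH": 21.6, "AKHGK": 12},
      "sd": {"AKH": 9.6, "AKHGK": 6}
    }
  ],
  "pairings": [{"a": "control", "b": "amon"}]
}
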