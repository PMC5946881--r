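{
  "bundle_version": "golden-v1",
  "genome_build": "synthetic",
  "files": {
    "genes.tsv": 4,
    "evidence.tsv": 3,
    "hotspots.tsv": 1,
    "variant_frequencies.tsv": 1,
    "pathogenicity.tsv": 3,
    "signatures.tsv": 96
  },
  "signature_aetiologies": {
    "SIG1": "UV-like",
    "SIG2": "smoking-like"
  }
}
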