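{
  "status": {"name": "drift3"},
  "environments": [{"name": "E1", "frequency": 1}],
  "traits": [],
  "chromosomes": [{"name": "C1", "n_loci": 1}],
  "loci": [
    {
      "name": "L1", "chrom": 1, "pos_cM": 0, "k": 3,
      "is_gene": false, "mutates": true,
      "mutation": [0.0001, 0.0002, 0.0003, 0.0004, 0.0005, 0.0006]
    }
  ]
}
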