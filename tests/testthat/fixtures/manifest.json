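{
  "rows": {
    "mask": 1112,
    "post": 808,
    "a": 380,
    "b": 380
  },
  "qc": {
    "mask": {
      "rows_in": 1112,
      "rows_removed_sigma": 22,
      "rows_removed_precision": 20,
      "rows_removed_photons": 643,
      "rows_out": 427
    },
    "post": {
      "rows_in": 808,
      "rows_removed_sigma": 20,
      "rows_removed_precision": 14,
      "rows_removed_photons": 507,
      "rows_out": 267
    },
    "a": {
      "rows_in": 380,
      "rows_removed_sigma": 5,
      "rows_removed_precision": 7,
      "rows_removed_photons": 216,
      "rows_out": 152
    },
    "b": {
      "rows_in": 380,
      "rows_removed_sigma": 6,
      "rows_removed_precision": 6,
      "rows_removed_photons": 219,
      "rows_out": 149
    }
  },
  "linked_rows": {
    "mask": 324,
    "post": 200,
    "a": 110,
    "b": 101
  },
  "scaffold_clusters": {
    "mask": 2,
    "post": 1
  },
  "specific_clusters": {
    "mask": 1,
    "post": 1
  },
  "candidate_synapses": 1,
  "accepted_synapses": 1,
  "restricted_counts": {
    "a": 67,
    "b": 56,
    "post": 119
  },
  "nanoclusters": {
    "a": 2,
    "b": 2
  }
}
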