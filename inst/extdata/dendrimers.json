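{
  "comment": "Multiporphyrin dendrimer catalog: zinc-porphyrin donors around a free-base porphyrin acceptor. Distances are Gaussian summaries (nm) of molecular-dynamics ensembles; donor-donor pairs fall into short/medium/long classes. tau_da_ps and beta are the measured transient-absorption stretched-exponential fit parameters used for the experimental-efficiency column.",
  "defaults": {
    "d_da_mean_nm": 1.69,
    "d_da_mean_modified_nm": 1.65,
    "d_da_sd_nm": 0.44,
    "r0_da_nm": 2.43,
    "r0_dd_nm": 1.92,
    "donor_lifetime_ps": 1300
  },
  "pair_classes": {
    "short":  { "mean_nm": 1.92, "sd_nm": 0.40 },
    "medium": { "mean_nm": 2.34, "sd_nm": 0.61 },
    "long":   { "mean_nm": 2.85, "sd_nm": 0.76 }
  },
  "dendrimers": [
    { "name": "MD2A",  "n_donors": 2,  "pair_class": "medium",
      "tau_da_ps": 338, "beta": 0.73 },
    { "name": "LD4A",  "n_donors": 4,  "pair_class": "long",
      "tau_da_ps": 302, "beta": 0.83 },
    { "name": "MD4A",  "n_donors": 4,  "pair_class": "medium",
      "tau_da_ps": 273, "beta": 0.75,
      "refined": { "same_linker_mean_nm": 2.34, "cross_linker_mean_nm": 2.44 } },
    { "name": "SD4A",  "n_donors": 4,  "pair_class": "short",
      "tau_da_ps": 248, "beta": 0.76 },
    { "name": "MD8A",  "n_donors": 8,  "pair_class": "medium",
      "tau_da_ps": 238, "beta": 0.85 },
    { "name": "SD16A", "n_donors": 16, "pair_class": "short",
      "tau_da_ps": 194, "beta": 0.72 }
  ]
}
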