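{
  "comment": "Package-default rate-matrix parameters for the site-scaled substitution simulators. Rates are per unit site scale per unit of total phylogeny edge length; tv_rate is the rate to EACH of the two transversion targets, so the transition/transversion event ratio is ti/(2*tv) = 20 at the K2P default, a typical mammalian-mtDNA value.",
  "K2P": {
    "ti_rate": 1.0,
    "tv_rate": 0.025
  },
  "TN93": {
    "ag_rate": 1.1,
    "ct_rate": 0.9,
    "tv_rate": 0.025
  }
}
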