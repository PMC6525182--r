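{
  "required": [
    "substitution_note",
    "anatomy_allometry",
    "sma_slope_comparison",
    "prs_stage",
    "nonlinear_fits",
    "interaction_tests",
    "phylogenetic",
    "data_source"
  ],
  "sections": {
    "nonlinear_fits": {
      "required_unless_skipped": ["RTD", "RN"]
    },
    "phylogenetic": {
      "required_unless_skipped": ["signals", "pic", "n_tips"]
    },
    "data_source": {
      "required_unless_skipped": ["r2", "high_rtd_freq", "freq_gap_points"]
    }
  }
}
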