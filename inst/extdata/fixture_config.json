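{
  "arms": {
    "intervention": {
      "label": "BEV+LOM",
      "median_pfs": 4.2,
      "median_os": 9.1,
      "cost_pfs_per_cycle": 3665.95,
      "cost_pd_per_cycle": 325,
      "printed_probs": {
        "p_pfs_pfs": 0.77,
        "p_pfs_pd": 0.15,
        "p_pfs_death": 0.07,
        "p_pd_pd": 0.87,
        "p_pd_death": 0.13
      }
    },
    "comparator": {
      "label": "LOM",
      "median_pfs": 1.5,
      "median_os": 8.6,
      "cost_pfs_per_cycle": 468.49,
      "cost_pd_per_cycle": 170,
      "printed_probs": {
        "p_pfs_pfs": 0.55,
        "p_pfs_pd": 0.37,
        "p_pfs_death": 0.08,
        "p_pd_pd": 0.91,
        "p_pd_death": 0.09
      }
    }
  },
  "global": {
    "annual_discount_rate": 0.05,
    "horizon_cycles": 120,
    "wtp": 35906,
    "utility_pfs": 0.89,
    "utility_pd": 0.74,
    "utility_death": 0,
    "half_cycle": false,
    "precision": "derived"
  },
  "sensitivity": {
    "n_iter": 1000,
    "cost_sd_frac": 0.25,
    "wtp_grid": { "from": 0, "to": 150000, "by": 1500 },
    "ranges": [
      { "name": "p_pfs_pd_intervention", "base": 0.15, "low": 0.12, "high": 0.18 },
      { "name": "p_pfs_death_intervention", "base": 0.07, "low": 0.06, "high": 0.09 },
      { "name": "p_pd_death_intervention", "base": 0.13, "low": 0.11, "high": 0.16 },
      { "name": "p_pfs_pd_comparator", "base": 0.37, "low": 0.30, "high": 0.44 },
      { "name": "p_pfs_death_comparator", "base": 0.08, "low": 0.06, "high": 0.09 },
      { "name": "p_pd_death_comparator", "base": 0.09, "low": 0.07, "high": 0.11 }
    ]
  }
}
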