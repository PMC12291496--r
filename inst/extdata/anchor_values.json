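{
  "wave1_initial_cn": {
    "value": 0.86,
    "source": "empirical mean P-element copies per haploid genome at generation 0 of the wave-1 experiment"
  },
  "wave2_initial_cn": {
    "value": 6.92,
    "source": "empirical mean P-element copies per haploid genome at generation 0 of the wave-2 experiment"
  },
  "plateau_cn": {
    "value": 15,
    "source": "approximate copy-number plateau per haploid genome reached by both experiments"
  },
  "plateau_generation": {
    "value": 20,
    "source": "approximate generation at which the copy-number plateau is reached"
  },
  "top_ranked_params": {
    "value": {
      "p_carrier": 0.189,
      "f_regulatory": 0.014,
      "u": 0.277,
      "alpha": 0.484,
      "beta": 10.327
    },
    "source": "top-ranked parameter combination from the wave-1-only calibration"
  },
  "ne": {
    "value": 221,
    "source": "average effective population size estimated for the wave-1 experiment"
  },
  "ne_robustness": {
    "value": 442,
    "source": "doubled effective population size used for the robustness check"
  },
  "effective_group_dfe": {
    "value": { "alpha": 0.461, "beta": 10.743 },
    "source": "DFE shape of the overall top-ranked combination (effective-selection group)"
  },
  "neutral_group_dfe": {
    "value": { "alpha": 0.065, "beta": 15.696 },
    "source": "DFE shape of the best combination in the effectively-neutral group"
  },
  "effective_group_summary": {
    "value": {
      "mean_abs_s": 0.041,
      "p95_abs_s": 0.16,
      "neutral_fraction": 0.273,
      "effective_mean_abs_s": 0.056
    },
    "source": "headline DFE summaries for the effective-selection group at Ne = 221, h = 0.5"
  },
  "neutral_group_summary": {
    "value": {
      "mean_abs_s": 0.004,
      "p95_abs_s": 0.024,
      "neutral_fraction": 0.866,
      "effective_mean_abs_s": 0.029
    },
    "source": "headline DFE summaries for the effectively-neutral group at Ne = 221, h = 0.5"
  }
}
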