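{
  "description": "Summary data abstracted from the PFS and OS analyses of a randomized trial of decompressive surgery plus radiotherapy (mS+RT) versus radiotherapy alone (RT-alone) for metastatic epidural spinal cord compression (MESCC). Healthy = ambulatory, ill = non-ambulatory. Times in years.",
  "arms": {
    "rt_alone": {
      "pfs": {"label": "pfs", "n_events": 17, "n_censored": 5,
              "event_time_sum": 7.02, "tau": 2.97, "auc": 0.63},
      "os": {"label": "os", "n_events": 44, "n_censored": 1,
             "event_time_sum": 24.17, "tau": 2.99, "auc": 0.62},
      "n_simul": 10
    },
    "ms_rt": {
      "pfs": {"label": "pfs", "n_events": 31, "n_censored": 6,
              "event_time_sum": 27.22, "tau": 5.25, "auc": 1.16},
      "os": {"label": "os", "n_events": 45, "n_censored": 3,
             "event_time_sum": 35.89, "tau": 5.25, "auc": 0.98},
      "n_simul": 19
    }
  },
  "reference_arm": "rt_alone"
}
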