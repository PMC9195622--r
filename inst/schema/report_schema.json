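{
  "package": "string",
  "version": "string",
  "config": {
    "synthetic": {
      "n_subjects": "number",
      "n_regions": "number",
      "n_volumes": "number",
      "tr": "number",
      "seed": "number"
    },
    "band": "array",
    "fd_threshold": "number",
    "alpha": "number",
    "selection_mode": "string",
    "C": "number",
    "B": "number",
    "perm_seed": "number"
  },
  "qc": {
    "threshold_mm": "number",
    "excluded_subjects": "array",
    "n_retained": "number",
    "fd": "table"
  },
  "feature_counts": {
    "regions_total": "number",
    "stage1": "number",
    "final": "number"
  },
  "selection": {
    "stage1_regions": "array",
    "stage2_regions": "array",
    "accuracy_trace": "array"
  },
  "weights": "table",
  "metrics": {
    "TP": "number",
    "FN": "number",
    "TN": "number",
    "FP": "number",
    "accuracy": "number",
    "sensitivity": "number",
    "specificity": "number",
    "auc": "number"
  },
  "permutation": {
    "observed_accuracy": "number",
    "p_raw": "number",
    "p_add_one": "number",
    "B": "number"
  },
  "behavior_tests": "table",
  "correlations": "table"
}
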