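{
  "title": "catrep report bundle",
  "description": "Field/type contract for report.json. Types are JSON types; data frames serialize as arrays of row objects. z_tests is null when the cohort holds fewer than two conditions; recovery_rate is null without ground-truth agent tags.",
  "required": {
    "metadata": ["object"],
    "counts": ["array"],
    "rmsd_summary": ["array"],
    "block_accuracy": ["array"],
    "block_accuracy_by_verdict": ["array"],
    "recovery_rate": ["number", "null"],
    "z_tests": ["array", "null"]
  }
}
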