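# Demonstration run on the bundled synthetic generator.
# The pipeline writes FAERS-style ASCII bundles under <out>/bundles/ and
# every analysis table as CSV next to a JSON run manifest.
synth:
  n_cases: 4000
  seed: 42
roles: [PS, SS]
scope: narrow
min_n111: 5
top_n: 30
tto_drugs: 5
sensitivity_occupation: LW
out: demo_results
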