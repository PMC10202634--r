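# Demo configuration for posmap::run_pipeline(): a fully simulated run with
# the default study conditions (60 genes, 3 vs 3 samples, usage effect 2,
# ACUAAY planted per the positional rule) and a 50-decoy motif collection.
seed: 1
simulate:
  n_genes: 60
  planted_fraction: 0.8
  usage_effect: 2
n_decoys: 50
tau: 0.2
thresholds:
  min_tpm: 0.5
  min_abs_log2fc: 1.0
  max_padj: 0.05
window:
  intron_window: 200
  exon_window: 10
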