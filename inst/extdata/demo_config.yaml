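# Demo pipeline configuration: simulates a small fosmid-end-like read set
# with planted microsatellites and two interspersed repeat families, then
# runs the full survey.
seed: 42
log_level: info
simulate:
  n_reads: 300
  length_min: 100
  length_max: 861
  length_mean: 531
  gc_background: 0.4588
  ssrs:
    - motif: AG
      copies: 40
      per_base_mutation: 0.02
      n_loci: 25
    - motif: AAT
      copies: 20
      per_base_mutation: 0.05
      n_loci: 15
    - motif: AACCT
      copies: 30
      n_loci: 5
  families:
    - family_id: famA
      consensus_length: 500
      n_copies: 30
      divergence: 0.05
      truncation_fraction: 0.2
    - family_id: famB
      consensus_length: 300
      n_copies: 24
      divergence: 0.10
detector: {}
families: {}
genome:
  genome_bp: 2.17e+9
  n_clones: 288000
  insert_bp: 40000
  coding_fraction: 0.048
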