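# Default pipeline configuration (all values mirror the package defaults).
seed: 42
synthetic:
  n_genes: 500
  network_model: preferential_attachment
  mean_degree: 4
  module_size: 20
  evidence_effect: 3
  noise_sd: 1
  n_sets: 50
  set_size_range: [10, 50]
  n_enriched_sets: 5
  n_diseases: 9
  shared_signal_fraction: 0.5
  tractable_rate: 0.3
rwr:
  restart: 0.75
  tol: 1.0e-10
  max_iter: 10000
enrichment:
  query_fraction: 0.02
  tsea_n_perm: 1000
  weight_exponent: 1
crosstalk:
  theta_quantile: 0.98
  n_perm: 100
  degree_bin_width: 1
  exact_limit: 15
robustness:
  k_min: 1
  k_max: 4
  convention: exclude_removed
repurpose: {}
crossdisease:
  radius: 3
  k_clusters: 4
  epochs: 40
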