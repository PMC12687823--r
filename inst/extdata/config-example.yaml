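# Example pipeline configuration.
# Group refractive indices used for ray bending and OPL conversion.
media:
  n_air: 1.0
  n_cornea: 1.385
  n_aqueous: 1.345
  n_lens: 1.417
zernike_terms: 15
icp:
  max_iter: 100
  tol: 1.0e-8
  trim_fraction: 0.2
  gate_mm: 0.5
eigenlens:
  K: 6
  P: 100
  Q: 100
  n_train: 80
  seed: 20240101
correct_iris: true
rng_seed: 1
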