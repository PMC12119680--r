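# Demonstration run: a coarse 32 x 32 km synthetic region (400 m
# pixels) with 60 enumeration areas and 2,500 admission records.
seed: 1
n_admissions: 2500
decay_tau: 25
p_not_anaemic: 0.36
p_excluded_cause: 0.15
p_missing_hb: 0.06
make_figures: false
verbose: false
landscape:
  nx: 80
  ny: 80
  pixel_size: 400
  n_eas: 60
  n_roads: 6
  barrier_frac: 0.05
truth:
  beta0: -6.2
  matern:
    sigma2: 0.5
    kappa: 0.0002
    nu: 1
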