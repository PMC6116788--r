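# Image-recognition preset. Connectivity, weight-initialization and STDP
# values are the published image-row table defaults; liquid/synthetic
# sizes are the package's desk-scale study conditions.
task: image
duration: 350.0
t_step: 0.5
n_tags: 1
lif_e:
  tau_mem: 100.0
  v_rest: -65.0
  v_reset: -65.0
  theta_base: -52.0
  theta_plus: 0.05
  tau_theta: 1.0e+07
  t_refrac: 5.0
  tau_syn_e: 2.0
  tau_syn_i: 1.0
lif_i:
  tau_mem: 10.0
  v_rest: -65.0
  v_reset: -45.0
  theta_base: -40.0
  theta_plus: 0.0
  tau_theta: 1.0e+07
  t_refrac: 2.0
  tau_syn_e: 2.0
  tau_syn_i: 1.0
stdp:
  eta: 0.005
  tau: 15.0
  stdp_offset: 0.4
  mu: 0.9
  w_max: 1.0
  w_min: 0.0
connectivity:
  ei_ratio: 4
  p_inp_e_single: 30.0
  p_inp_e_ensemble: 50.0
  p_ee: 1.0
  p_ei: 5.0
  p_ie: 30.0
  p_ii: 1.0
weights:
  w_init_min: 0.003
  w_init_max: 0.303
  w_ee: 1.0
  w_ei: 10.0
  w_ie: 1.0
  w_ii: 1.0
liquid:
  n_total: 400
  n_liquids: 1
  scheme: vertical-halves
  overlap: 4
synthetic:
  n_classes: 4
  shape: [12, 12]
  noise_level: 0.1
  samples_per_class: 25
train:
  n_examples: 2000
seed: 7
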