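# Reduced profile for fast end-to-end runs: shorter frozen-noise trials and
# a smaller presynaptic pool at the full 20 kHz sampling rate (sub-ms spike
# waveforms need it). Class archetypes are identical to paper_scale.
profile: test_scale
n_neurons: 40
fn:
  duration: 10000         # ms (10 s)
  dt: 0.05                # ms (20 kHz)
  target_sd: 50
  n_units: 200
  kernel_tau: 5
sh:
  step_min: 40
  step_max: 400
  n_steps: 10
  step_duration: 500
  holding_potential: -70
  pad_pre: 100
  pad_post: 100
kernels:
  support: 500
  n_basis: 10
  first_edge: 5
classes:
  - label: E
    weight: 0.5961538
    tau_fn: 250
    baseline: 200
    params:
      C:       {mean: 200,  sd: 16}
      g_L:     {mean: 10,   sd: 0.8}
      E_L:     {mean: -70,  sd: 1.5}
      V_reset: {mean: -60,  sd: 1.5}
      VT_star: {mean: -45,  sd: 1.5}
      delta_V: {mean: 2.0,  sd: 0.2}
    eta:   {amp: {mean: 60, sd: 12}, tau: 120}
    gamma: {amp: {mean: 4,  sd: 1},  tau: 40}
    template: {peak: 35, rise_ms: 0.5, fall_ms: 0.9, width_sd_frac: 0.08}
  - label: I
    weight: 0.4038462
    tau_fn: 50
    baseline: 160
    params:
      C:       {mean: 100,  sd: 8}
      g_L:     {mean: 10,   sd: 0.8}
      E_L:     {mean: -65,  sd: 1.5}
      V_reset: {mean: -58,  sd: 1.5}
      VT_star: {mean: -47,  sd: 1.5}
      delta_V: {mean: 1.5,  sd: 0.15}
    eta:   {amp: {mean: 12, sd: 3},  tau: 30}
    gamma: {amp: {mean: 2,  sd: 0.5}, tau: 15}
    template: {peak: 35, rise_ms: 0.2, fall_ms: 0.3, width_sd_frac: 0.08}
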