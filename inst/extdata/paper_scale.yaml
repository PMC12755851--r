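# Full-scale synthetic population profile: acquisition settings match the
# experimental protocols (360 s frozen noise at 20 kHz; 10 x 500 ms steps,
# 40-400 pA). Class archetypes are package choices tuned so that the
# broad-spiking class fires below 5 Hz and the narrow-spiking class above
# 10 Hz under the default frozen-noise drive.
profile: paper_scale
n_neurons: 312
fn:
  duration: 360000        # ms
  dt: 0.05                # ms (20 kHz)
  target_sd: 50           # pA
  n_units: 1000
  kernel_tau: 5           # ms
sh:
  step_min: 40            # pA
  step_max: 400
  n_steps: 10
  step_duration: 500      # ms
  holding_potential: -70  # mV
  pad_pre: 100
  pad_post: 100
kernels:
  support: 500            # ms, 10000 samples at 20 kHz
  n_basis: 10
  first_edge: 5
classes:
  - label: E
    weight: 0.5961538     # 186 / 312
    tau_fn: 250           # ms, slow-switching drive for slow responders
    baseline: 200         # pA holding depolarization
    params:
      C:       {mean: 200,  sd: 16}     # pF
      g_L:     {mean: 10,   sd: 0.8}    # nS  (tau_m ~ 20 ms)
      E_L:     {mean: -70,  sd: 1.5}    # mV
      V_reset: {mean: -60,  sd: 1.5}
      VT_star: {mean: -45,  sd: 1.5}
      delta_V: {mean: 2.0,  sd: 0.2}
    eta:   {amp: {mean: 60, sd: 12}, tau: 120}   # pA, strong slow adaptation
    gamma: {amp: {mean: 4,  sd: 1},  tau: 40}    # mV
    template: {peak: 35, rise_ms: 0.5, fall_ms: 0.9, width_sd_frac: 0.08}
  - label: I
    weight: 0.4038462     # 126 / 312
    tau_fn: 50
    baseline: 160
    params:
      C:       {mean: 100,  sd: 8}
      g_L:     {mean: 10,   sd: 0.8}    # tau_m ~ 10 ms
      E_L:     {mean: -65,  sd: 1.5}
      V_reset: {mean: -58,  sd: 1.5}
      VT_star: {mean: -47,  sd: 1.5}
      delta_V: {mean: 1.5,  sd: 0.15}
    eta:   {amp: {mean: 12, sd: 3},  tau: 30}    # weak fast adaptation
    gamma: {amp: {mean: 2,  sd: 0.5}, tau: 15}
    template: {peak: 35, rise_ms: 0.2, fall_ms: 0.3, width_sd_frac: 0.08}
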