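# Default audit configuration: 100 cm iron-amended sand column,
# 0.1 mmol/L toluene feed, two inoculated treatment columns and two
# HgCl2-sterilised controls, monitored on days 1-8 then every 5 days to 43.
column:
  length: 1.0
  inner_diameter: 0.07
  porosity: 0.30
  effective_porosity: 0.25
  hydraulic_conductivity: 10
  hydraulic_gradient: 0.002
  fe_hydroxide_mass_fraction: 0.025
  grain_density: 2.65
  n_ports: 9
  port_spacing: 0.1
scenario:
  treatment_ids: [T1, T2]
  control_ids: [C1, C2]
  overrides: {}
quantify:
  method: trapezoid
  censored_policy: zero
  late_window: [30, 43]
exceedance:
  toluene: 700        # ug/L, GB14848
  fe2_dissolved: 0.3  # mg/L, GB14848
seed: 1
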