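# Tuned final spindle model: all published constants plus the four tuned
# myosin rates (b_f, b_g, c_f, c_g) and k_coop = 1.
geometry:
  length_thin_filament: 1120.0
  length_thick_filament: 815.0
  length_bare_zone: 80.0
  L0: 1300.0
thin:
  k_on: 8.0e+07      # /M/s
  k_off: 200.0       # /s
  k_coop: 1.0
crossbridge:
  cb_density: 6.9e+16    # /m^2
  cb_stiffness: 0.001    # pN/nm
  const_f: 0.072         # pN nm
bag:
  b_f: 600.0             # /s, attachment slope
  b_g: 7.0               # /s, detachment offset
  offset_bag: 0.5        # /s
  passive_stiffness_bag: 90.0    # N/m^2/nm
  length_slack_bag: 1050.0       # nm
chain:
  c_f: 400.0
  c_g: 300.0
  offset_chain: 10.0
  passive_stiffness_chain: 250.0
  length_slack_chain: 1200.0
weights:
  kfb: 0.4
  kfc: 0.5
  kyb: 0.005
  scale: 2.0e+05
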