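# Example depclog run configuration. Every physical quantity carries an
# explicit unit; unknown keys or units are rejected on load.
seed: 42
haematocrit_pct: 25
volume_ul: 0.02
voltage: 20 V
frequency: 1 kHz
duration: 60 s
dt: 0.25 s
noise_cv: 0.1
replicates: 3
network:
  branch_width: 15 um
  depth: 80 um
  n_branches: 50
  inlet_flow: 1 ul/min
adhesion:
  hamaker: 5 zJ
  debye_kappa: 0.159 nm^-1
  temperature: 296.15 K
  zeta_particle: -10.8 mV
  zeta_wall: -13.825 mV
field:
  electrode_gap: 5 um
  electrode_pitch: 10 um
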