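# Canonical simulation cell: large contrast in move persistence between the
# transient and ARS states, GPS-like Gaussian location error.
#   gamma = 0.95 / 0.10, theta = 0 / pi, alpha = 0.90 / 0.10,
#   process SD 5 km per axis, observation SD 0.05 km per axis.
type: scenario
delta_gamma_label: large
error_regime: gps
n_tracks: 5
track_length: 100
seed: 42
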