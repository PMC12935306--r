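# Default two-strain colony-biofilm competition configuration.
# Nondimensional units throughout: carrying capacity = 1, time scale set by
# strain 1's growth rate (r1 = 1). The domain is a disc of radius 60 on a
# 256 x 256 grid (h = 0.5). The time step defaults to 0.5x the explicit
# stability bound when omitted.
grid:
  nx: 256
  ny: 256
  h: 0.5
  radius: 60
strains:
  - name: B1
    r: 1.0
    d: 1.0
  - name: B2
    r: 1.0
    d: 1.0
layout:
  n_per_strain: 50
  inoculum_radius: 5
  spot_radius: 1.0
  b0: 0.5
  seed: 1
t_end: 50
stop_area_frac: 0.9
occupied_threshold: 0.05
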