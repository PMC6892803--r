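# Demo run: two 60-um ink stripes imaged with the modulated lattice
# protocol on a small camera cut-out. Completes in a few seconds.
scene:
  type: stripes
  stripe_width: 60.0   # um
  gap: 60.0            # um
  n_stripes: 2
  pitch: 6.0           # um per ground-truth cell
sample:
  preset: ink          # emissivity 0.8, film-like diffusivity
beam:
  diameter_1e2: 22.0   # um
  power: 15.0          # mW (metadata)
protocol:
  n_x: 12
  n_y: 8
  pixel_size: 10.0     # scan pixel, um
  lattice: [6, 4]      # activation lattice (dx, dy), scan pixels
  tau_on: 0.2          # s
  origin: [120.0, 140.0]
camera:
  format: [10, 8]      # small cut-out of the 320 x 240 sensor
noise: photon
seed: 7
target_dT: 1.5         # degC, camera-fitted amplitude after calibration
rendering:
  dT_min: 0.3          # degC
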