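# Example experiment configuration (all fields optional; package defaults
# mirror the bench conditions: 320 x 256 px camera at 42 um and 500 Hz,
# 4 ms loop latency, +/- 2.5 mm tracking range).
scene:
  frame_width: 320
  frame_height: 256
  pixel_size: 0.042
  pupil_radius: 2
  noise_sigma: 10
calibration:
  mm_per_pixel: 0.042
  deg_per_mm: 0.764
  volts_per_deg: 0.5
  beta: 1
loop:
  camera_rate: 500
  latency: 0.004
  tracking_range: 2.5
mscan:
  alines_per_bscan: 240
  bscan_rate: 416.7
  n_bscans: 1000
  lateral_fov: 8
  speckle_contrast: 0.2
seeds: [1]
output_dir: results
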