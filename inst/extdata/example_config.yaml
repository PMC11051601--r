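# Example pipeline configuration. Any omitted key falls back to the
# package default; unknown keys are rejected.
seed: 11
optics:
  wavelength: 0.642        # um, vacuum
  medium_index: 1.33
  pixel_pitch: 0.703125    # um/px (360 um / 512 px)
  frame_width: 512
  frame_height: 512
  frame_rate: 30           # Hz
  chamber_depth: 280       # um
simulation:
  n_cells: 10
  n_frames: 100
  speed: 20                # um/s
  tumble_rate: 1           # 1/s
  diffusion: 0.4           # um^2/s
  amplitude: 0.15
  noise_sd: 0.002
  artifact: true
  n_validation_frames: 100
tracking:
  max_disp: 30             # um per link
  max_gap: 2               # frames
  min_length: 5
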