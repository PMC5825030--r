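# Example simulation configuration for the ctbolus CLI.
patient:
  height: 166
  weight: 65.0
  cardiac_index: 2.5
agent:
  name: CM-350
  iodine_concentration: 350
  osmolality: 590
  viscosity: 7.0
protocol:
  cm_volume: 45.5
  duration: 8
  flush_volume: 20
settings:
  dt: 0.1
  horizon: 120
rois: [ascending_aorta, abdominal_aorta]
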