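# Example pipeline configuration: simulate a phantom stack and an
# SR-magnitude fiber network, then quantify.
region: SR-sim
seed: 1
simulate:
  stack:
    dims: [192, 192, 48]
    n_junctions: 30
  network:
    volume_um3: 500
segmentation:
  sigma_xy: 1
  sigma_z: 0
  gray_threshold: 100
  min_voxels: 20
  connectivity: 26
frame:
  margin_um: [0.05, 0.05, 0.05]
  exclusion_faces: [x-, y-, z-]
shrinkage:
  volume: 0.87
  surface: 0.91
  linear: 0.96
metrics:
  min_shaft_um: 3
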