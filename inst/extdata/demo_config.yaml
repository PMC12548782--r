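# Demo screen: two simulated plates, control vs ER-expanded conditions.
seed: 1
simulate:
  plates: 2
  fields_per_well: 1
  conditions:
  - name: control
    control: true
    wells: 4
    er_peripheral_fraction: 0.3
  - name: er_expanded
    control: false
    wells: 4
    er_peripheral_fraction: 0.6
  field:
    image_shape: [512, 512]
    n_cells: 10
    cell_radius_range: [28.0, 38.0]
    ridge_density: 3
    hole_density: 3
    noise:
      poisson_scale: 4.0
      gaussian_sd: 25.0
segmentation:
  smoothing: 2.0
  min_area: 80
  split: true
cells:
  threshold: otsu
  method: srg
qc:
  min_area: 400
  max_area: 50000
  focus_threshold: 0.04
features:
  f_pn: 0.25
  f_pe: 0.25
stats:
  stat: mean
  distance: correlation
  linkage: average
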