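# Demo phantom: two tumors and two cysts inside an ellipsoidal liver.
# Field-for-field mirror of phantom_spec(); lesion hu_mean/hu_sd default to
# the kind presets (tumor 91 +/- 23 HU, cyst 17 +/- 22 HU).
shape: [64, 64, 44]
spacing: [1.0, 1.0, 1.5]
liver:
  semi_axes: [26, 24, 26]
  hu_mean: 60
  hu_sd: 10
background_hu: -1000
noise_sd: 5
seed: 42
lesions:
  - center: [23, 26, 16]
    radius: 8
    kind: tumor
  - center: [44, 40, 28]
    radius: 6
    kind: tumor
  - center: [42, 22, 18]
    radius: 6
    kind: cyst
  - center: [24, 44, 28]
    radius: 5
    kind: cyst
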